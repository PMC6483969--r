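#' Construct an undirected simple gene network
#'
#' Edges are stored once as alphabetically ordered pairs; self-edges are
#' disallowed and duplicates collapse.
#'
#' @param nodes character vector of gene IDs.
#' @param edges two-column character matrix (or data.frame) of gene pairs.
#' @return an object of class `gene_network`.
#' @export
gene_network <- function(nodes = character(), edges = NULL) {
  nodes <- sort(unique(as.character(nodes)))
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(character(), ncol = 2,
                    dimnames = list(NULL, c("gene_a", "gene_b")))
  } else {
    edges <- as.matrix(edges)
    storage.mode(edges) <- "character"
    keep <- edges[, 1] != edges[, 2]
    edges <- edges[keep, , drop = FALSE]
    a <- unname(pmin(edges[, 1], edges[, 2]))
    b <- unname(pmax(edges[, 1], edges[, 2]))
    key <- paste(a, b, sep = "\r")
    dedup <- !duplicated(key)
    o <- order(a[dedup], b[dedup])
    edges <- cbind(a[dedup][o], b[dedup][o])
    dimnames(edges) <- list(NULL, c("gene_a", "gene_b"))
  }
  bad <- setdiff(c(edges), nodes)
  if (length(bad))
    stop_arg("edges reference genes absent from the node set: ",
             paste(utils::head(bad, 5), collapse = ", "))
  structure(list(nodes = nodes, edges = edges), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat("gene_network:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Project a metabolic model to its gene-centric network
#'
#' Two genes are connected iff some reaction of one and some reaction of the
#' other (possibly the same reaction) share a metabolite. Equivalently the
#' edge set is the union, over metabolites, of complete graphs on the genes of
#' the reactions incident to that metabolite. Two genes annotated to the same
#' reaction are therefore adjacent whenever that reaction has at least one
#' metabolite. Currency-metabolite removal, if desired, must be applied by the
#' caller beforehand.
#'
#' @param model a `metabolic_model`.
#' @return a `gene_network` over all genes in the model's gene map.
#' @export
project_gene_network <- function(model) {
  genes <- model_genes(model)
  if (length(genes) == 0L) return(gene_network())
  if (nrow(model$incidence) == 0L) return(gene_network(nodes = genes))
  # reaction -> genes lookup
  rg <- split(model$gene_map$gene, model$gene_map$reaction)
  # metabolite -> incident reactions -> union of genes
  mr <- split(model$incidence$reaction, model$incidence$metabolite)
  edge_list <- vector("list", length(mr))
  for (i in seq_along(mr)) {
    gs <- unique(unlist(rg[mr[[i]]], use.names = FALSE))
    if (length(gs) >= 2L) {
      gs <- sort(gs)
      edge_list[[i]] <- t(utils::combn(gs, 2L))
    }
  }
  edges <- do.call(rbind, edge_list)
  gene_network(nodes = genes, edges = edges)
}

#' Restrict a gene network to measured genes
#'
#' Induced subgraph on `nodes` intersected with `measured_genes`. Because the
#' projection rule is pairwise, induction is exact: no edge is rerouted
#' through a removed gene.
#'
#' @param network a `gene_network`.
#' @param measured_genes character vector of gene IDs present in the data.
#' @return a `gene_network`.
#' @export
restrict_to_measured <- function(network, measured_genes) {
  keep <- intersect(network$nodes, as.character(measured_genes))
  e <- network$edges
  e <- e[e[, 1] %in% keep & e[, 2] %in% keep, , drop = FALSE]
  gene_network(nodes = keep, edges = e)
}

#' Dense logical adjacency matrix of a gene network
#' @param network a `gene_network`.
#' @return logical matrix with gene IDs as dimnames.
#' @export
adjacency_matrix <- function(network) {
  n <- length(network$nodes)
  A <- matrix(FALSE, n, n, dimnames = list(network$nodes, network$nodes))
  if (nrow(network$edges)) {
    i <- match(network$edges[, 1], network$nodes)
    j <- match(network$edges[, 2], network$nodes)
    A[cbind(i, j)] <- TRUE
    A[cbind(j, i)] <- TRUE
  }
  A
}

#' Convert a gene network to an igraph object
#' @param network a `gene_network`.
#' @return an undirected `igraph` graph.
#' @export
as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    as.data.frame(network$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = network$nodes))
}

#' Write a gene network to disk
#'
#' @param network a `gene_network`.
#' @param path output path.
#' @param format `"tsv"` (two-column edge list with header) or `"graphml"`.
#' @return the path, invisibly.
#' @export
write_gene_network <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write_tsv(as.data.frame(network$edges, stringsAsFactors = FALSE), path)
  } else {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  }
  invisible(path)
}

#' Read a gene network from an edge-list TSV
#' @param path path to a TSV with columns `gene_a`, `gene_b`.
#' @param nodes optional full node set (isolated nodes are lost by edge lists).
#' @return a `gene_network`.
#' @export
read_gene_network <- function(path, nodes = NULL) {
  df <- read_tsv(path)
  if (is.null(nodes)) nodes <- unique(c(df$gene_a, df$gene_b))
  gene_network(nodes = nodes, edges = as.matrix(df[, c("gene_a", "gene_b")]))
}
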