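# Shared fixtures and independent brute-force oracles.

# Random small metabolic model for property tests.
random_model <- function(seed, n_reactions = 8, n_metabolites = 6,
                         n_genes = 6) {
  withr::with_seed(seed, {
    rxns <- paste0("R", seq_len(n_reactions))
    mets <- paste0("m", seq_len(n_metabolites))
    genes <- paste0("g", seq_len(n_genes))
    inc <- do.call(rbind, lapply(rxns, function(r) {
      k <- sample(0:3, 1)
      if (k == 0) return(NULL)
      data.frame(reaction = r, metabolite = sample(mets, k))
    }))
    gm <- do.call(rbind, lapply(genes, function(g)
      data.frame(reaction = sample(rxns, sample(1:2, 1)), gene = g)))
    suppressWarnings(metabolic_model(metabolites = mets, reactions = rxns,
                                     incidence = inc, gene_map = gm))
  })
}

# O(|R|^2) projection oracle: enumerate reaction pairs sharing a metabolite
# (a reaction shares its metabolites with itself), connect their gene pairs.
brute_force_project <- function(model) {
  rxn_mets <- split(model$incidence$metabolite, model$incidence$reaction)
  rxn_genes <- split(model$gene_map$gene, model$gene_map$reaction)
  rxns <- model$reactions
  edges <- NULL
  for (r1 in rxns) for (r2 in rxns) {
    m1 <- rxn_mets[[r1]]; m2 <- rxn_mets[[r2]]
    if (is.null(m1) || is.null(m2) || !length(intersect(m1, m2))) next
    g1 <- rxn_genes[[r1]]; g2 <- rxn_genes[[r2]]
    if (is.null(g1) || is.null(g2)) next
    for (a in g1) for (b in g2) if (a != b)
      edges <- rbind(edges, c(min(a, b), max(a, b)))
  }
  if (!is.null(edges)) edges <- unique(edges)
  gene_network(nodes = model_genes(model), edges = edges)
}

# Degree-count connectivity oracle on an explicit edge list.
brute_force_connectivity <- function(network, gene_set) {
  nodes <- intersect(unique(gene_set), network$nodes)
  if (!length(nodes)) return(NA_real_)
  e <- network$edges
  connected <- vapply(nodes, function(g) {
    any((e[, 1] == g & e[, 2] %in% nodes) |
          (e[, 2] == g & e[, 1] %in% nodes))
  }, logical(1))
  mean(connected)
}

# Random Erdos-Renyi-ish gene network.
random_network <- function(seed, n_nodes = 12, p_edge = 0.25) {
  withr::with_seed(seed, {
    nodes <- paste0("g", seq_len(n_nodes))
    pairs <- t(utils::combn(nodes, 2))
    keep <- stats::runif(nrow(pairs)) < p_edge
    gene_network(nodes = nodes, edges = pairs[keep, , drop = FALSE])
  })
}

# The worked 4-gene example: three mutually connected genes plus an isolate.
triangle_plus_isolate <- function() {
  gene_network(nodes = c("gA", "gB", "gC", "gD"),
               edges = rbind(c("gA", "gB"), c("gA", "gC"), c("gB", "gC")))
}

# Tiny triple-TSV model file.
write_model_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("kind\treaction\tpartner", rows), path)
  path
}

# Small dosage panel from a dosage matrix.
make_panel <- function(d, chrom = "1", pos = NULL) {
  n_snp <- nrow(d)
  if (is.null(rownames(d))) rownames(d) <- paste0("snp", seq_len(n_snp))
  if (is.null(colnames(d))) colnames(d) <- paste0("S", seq_len(ncol(d)))
  if (is.null(pos)) pos <- seq_len(n_snp) * 1000L
  dosage_panel(d, data.frame(snp = rownames(d), chrom = chrom, pos = pos,
                             minor = "A", major = "G",
                             stringsAsFactors = FALSE))
}
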