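#' Construct a bipartite metabolic model
#'
#' A metabolic model is a bipartite graph of metabolite and reaction nodes
#' (the incidence pairs), plus reaction-to-gene associations. Stoichiometry,
#' reversibility and compartments are deliberately out of scope: the
#' gene-centric projection only needs to know which reactions touch which
#' metabolites and which genes catalyse which reactions.
#'
#' @param metabolites character vector of metabolite IDs.
#' @param reactions character vector of reaction IDs.
#' @param incidence data.frame with columns `reaction`, `metabolite`.
#' @param gene_map data.frame with columns `reaction`, `gene`.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites = character(), reactions = character(),
                            incidence = data.frame(reaction = character(),
                                                   metabolite = character()),
                            gene_map = data.frame(reaction = character(),
                                                  gene = character()),
                            warn_orphans = TRUE) {
  metabolites <- sort(unique(as.character(metabolites)))
  reactions <- sort(unique(as.character(reactions)))
  incidence <- unique(data.frame(reaction = as.character(incidence$reaction),
                                 metabolite = as.character(incidence$metabolite),
                                 stringsAsFactors = FALSE))
  gene_map <- unique(data.frame(reaction = as.character(gene_map$reaction),
                                gene = as.character(gene_map$gene),
                                stringsAsFactors = FALSE))
  m <- structure(list(metabolites = metabolites, reactions = reactions,
                      incidence = incidence, gene_map = gene_map),
                 class = "metabolic_model")
  validate_metabolic_model(m, warn_orphans = warn_orphans)
}

validate_metabolic_model <- function(m, warn_orphans = TRUE) {
  bad_r <- setdiff(c(m$incidence$reaction, m$gene_map$reaction), m$reactions)
  if (length(bad_r))
    stop_arg("incidence/gene_map reference undeclared reactions: ",
             paste(utils::head(bad_r, 5), collapse = ", "))
  bad_m <- setdiff(m$incidence$metabolite, m$metabolites)
  if (length(bad_m))
    stop_arg("incidence references undeclared metabolites: ",
             paste(utils::head(bad_m, 5), collapse = ", "))
  clash <- intersect(unique(m$gene_map$gene), m$metabolites)
  if (length(clash))
    stop_arg("gene and metabolite ID namespaces overlap: ",
             paste(utils::head(clash, 5), collapse = ", "))
  orphan <- setdiff(m$reactions, m$incidence$reaction)
  if (warn_orphans && length(orphan))
    warning(length(orphan), " reaction(s) have no incident metabolite",
            call. = FALSE)
  m
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model:", length(x$metabolites), "metabolites,",
      length(x$reactions), "reactions,",
      length(unique(x$gene_map$gene)), "genes,",
      nrow(x$incidence), "incidence pairs\n")
  invisible(x)
}

#' Genes declared in a metabolic model
#' @param model a `metabolic_model`.
#' @return character vector of gene IDs (sorted, unique).
#' @export
model_genes <- function(model) sort(unique(model$gene_map$gene))

#' Read a metabolic model from disk
#'
#' The canonical format is a "triple TSV" with header and columns
#' `kind` (`RM` = reaction-metabolite incidence, `RG` = reaction-gene
#' association), `reaction`, `partner`. Duplicate rows collapse under set
#' semantics. An SBML Level 3 subset reader is also available: it flattens
#' `listOfSpecies` / `listOfReactions` speciesReferences and any
#' gene-association annotations to plain gene sets, ignoring boolean GPR
#' structure.
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"sbml"`.
#' @return a validated `metabolic_model`.
#' @export
read_metabolic_model <- function(path, format = c("tsv", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_arg("no such file: ", path)
  if (format == "sbml") return(read_model_sbml(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) <= 1L) return(metabolic_model())
  body <- lines[-1L]
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3L))
    stop_arg("malformed row at line ", which(nf != 3L)[1] + 1L,
             ": expected 3 tab-separated fields")
  kind <- vapply(parts, `[[`, "", 1L)
  reaction <- vapply(parts, `[[`, "", 2L)
  partner <- vapply(parts, `[[`, "", 3L)
  bad <- !kind %in% c("RM", "RG")
  if (any(bad))
    stop_arg("malformed row at line ", which(bad)[1] + 1L,
             ": kind must be RM or RG, got '", kind[which(bad)[1]], "'")
  rm_rows <- kind == "RM"
  metabolic_model(
    metabolites = partner[rm_rows],
    reactions = reaction,
    incidence = data.frame(reaction = reaction[rm_rows],
                           metabolite = partner[rm_rows]),
    gene_map = data.frame(reaction = reaction[!rm_rows],
                          gene = partner[!rm_rows]))
}

# Minimal SBML L3/FBC subset: species, reactions with speciesReferences, and
# fbc:geneProductAssociation flattened to the set of referenced gene products.
read_model_sbml <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE))
    stop_arg("SBML input requires the 'xml2' package")
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  species <- xml2::xml_attr(xml2::xml_find_all(doc, ".//listOfSpecies/species"), "id")
  rxn_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  inc <- list(); gm <- list()
  for (rx in rxn_nodes) {
    rid <- xml2::xml_attr(rx, "id")
    sp <- xml2::xml_attr(
      xml2::xml_find_all(rx, ".//speciesReference"), "species")
    if (length(sp))
      inc[[rid]] <- data.frame(reaction = rid, metabolite = sp)
    gp <- xml2::xml_attr(
      xml2::xml_find_all(rx, ".//geneProductRef"), "geneProduct")
    if (length(gp))
      gm[[rid]] <- data.frame(reaction = rid, gene = gp)
  }
  metabolic_model(
    metabolites = species,
    reactions = xml2::xml_attr(rxn_nodes, "id"),
    incidence = do.call(rbind, c(inc, list(data.frame(reaction = character(),
                                                      metabolite = character())))),
    gene_map = do.call(rbind, c(gm, list(data.frame(reaction = character(),
                                                    gene = character())))))
}

#' Write a metabolic model as triple TSV
#' @param model a `metabolic_model`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_metabolic_model <- function(model, path) {
  rm_df <- data.frame(kind = "RM", reaction = model$incidence$reaction,
                      partner = model$incidence$metabolite)
  rg_df <- data.frame(kind = "RG", reaction = model$gene_map$reaction,
                      partner = model$gene_map$gene)
  write_tsv(rbind(rm_df, rg_df), path)
}

#' Metabolite degrees (number of distinct incident reactions)
#' @param model a `metabolic_model`.
#' @return named integer vector over all declared metabolites (0 if isolated).
#' @export
metabolite_degrees <- function(model) {
  deg <- integer(length(model$metabolites))
  names(deg) <- model$metabolites
  if (nrow(model$incidence)) {
    tab <- table(model$incidence$metabolite)
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

#' Remove currency metabolites
#'
#' Deletes the `ceil(fraction * n_metabolites)` highest-degree metabolites
#' (hub metabolites such as ATP) together with their incidence pairs, to avoid
#' implausibly short distances in the downstream gene-centric projection.
#' Degree ties at the cutoff are broken by lexicographic metabolite ID so that
#' removal sets are nested across fractions. Reactions and genes are retained
#' even if left metabolite-free.
#'
#' @param model a `metabolic_model`.
#' @param fraction proportion of metabolites to remove, in `[0, 1)`.
#' @return list with elements `model` (pruned) and `report` (class
#'   `currency_report`: data.frame `removed` with columns metabolite/degree in
#'   removal order, and `fraction`).
#' @export
remove_currency_metabolites <- function(model, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction >= 1)
    stop_arg("fraction must be a single number in [0, 1)")
  deg <- metabolite_degrees(model)
  n_remove <- ceiling(fraction * length(model$metabolites))
  if (n_remove == 0L) {
    report <- structure(list(removed = data.frame(metabolite = character(),
                                                  degree = integer()),
                             fraction = fraction),
                        class = "currency_report")
    return(list(model = model, report = report))
  }
  ord <- order(-deg, names(deg))  # degree desc, then lexicographic ID
  removed <- names(deg)[ord][seq_len(n_remove)]
  keep_met <- setdiff(model$metabolites, removed)
  pruned <- metabolic_model(
    metabolites = keep_met,
    reactions = model$reactions,
    incidence = model$incidence[!model$incidence$metabolite %in% removed, ,
                                drop = FALSE],
    gene_map = model$gene_map,
    warn_orphans = FALSE)  # metabolite-free reactions are expected here
  report <- structure(
    list(removed = data.frame(metabolite = removed,
                              degree = as.integer(deg[removed])),
         fraction = fraction),
    class = "currency_report")
  list(model = pruned, report = report)
}
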