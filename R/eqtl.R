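#' Trans-eQTL Kruskal-Wallis scan
#'
#' For every (gene, SNP) pair, tests expression across hard-called genotype
#' classes (dosage rounded to 0/1/2) with a Kruskal-Wallis rank test (tie
#' corrected, chi-square approximation). Empty classes are dropped; pairs with
#' fewer than 2 classes (e.g. monomorphic SNPs) get a missing p.
#'
#' @param expr numeric genes x samples expression matrix.
#' @param panel a `dosage_panel` sharing samples with `expr`.
#' @return genes x SNPs matrix of p-values (class `eqtl_matrix`), attribute
#'   `n` holding the shared sample count.
#' @export
trans_eqtl <- function(expr, panel) {
  samples <- intersect(colnames(expr), colnames(panel$dosage))
  if (!length(samples)) stop_arg("no shared samples between expression and panel")
  e <- expr[, samples, drop = FALSE]
  g <- round(panel$dosage[, samples, drop = FALSE])
  out <- matrix(NA_real_, nrow(e), nrow(g),
                dimnames = list(rownames(e), panel$info$snp))
  for (j in seq_len(nrow(g))) {
    geno <- g[j, ]
    ok_g <- !is.na(geno)
    classes <- unique(geno[ok_g])
    if (length(classes) < 2) next  # monomorphic: whole column missing
    f <- factor(geno[ok_g])
    for (i in seq_len(nrow(e))) {
      x <- e[i, ok_g]
      ok <- !is.na(x)
      if (length(unique(f[ok])) < 2) next
      out[i, j] <- suppressWarnings(
        stats::kruskal.test(x[ok], f[ok])$p.value)
    }
  }
  attr(out, "n") <- length(samples)
  class(out) <- c("eqtl_matrix", class(out))
  out
}

#' Bonferroni thresholds for an eQTL matrix
#'
#' Per-SNP-corrected threshold `alpha / m_eff` (LD-effective SNP count) and
#' study-wide threshold `alpha / (m_eff * n_genes)`, plus the boolean hit
#' matrices at each.
#'
#' @param eqtl an `eqtl_matrix` (genes x SNPs p-values).
#' @param m_eff LD-effective number of SNPs (>= 1).
#' @param n_genes number of genes tested (>= 1).
#' @param alpha nominal level (default 0.05).
#' @return list with `per_snp_threshold`, `study_wide_threshold`,
#'   `hits_per_snp`, `hits_study_wide`.
#' @export
eqtl_significance <- function(eqtl, m_eff, n_genes, alpha = 0.05) {
  stopifnot(m_eff >= 1, n_genes >= 1)
  thr1 <- alpha / m_eff
  thr2 <- alpha / (m_eff * n_genes)
  list(per_snp_threshold = thr1, study_wide_threshold = thr2,
       hits_per_snp = !is.na(eqtl) & eqtl < thr1,
       hits_study_wide = !is.na(eqtl) & eqtl < thr2)
}

#' Gene-wise minimum eQTL p-values
#'
#' Row-wise minimum over non-missing entries; genes with no usable p are
#' dropped with a warning.
#'
#' @param eqtl an `eqtl_matrix`.
#' @return named numeric vector over the retained genes.
#' @export
min_p_per_gene <- function(eqtl) {
  n_ok <- rowSums(!is.na(eqtl))
  if (any(n_ok == 0))
    warning(sum(n_ok == 0), " gene(s) with no usable p-value dropped",
            call. = FALSE)
  m <- eqtl[n_ok > 0, , drop = FALSE]
  apply(m, 1, min, na.rm = TRUE)
}

#' Asymmetric binary distance between salience profiles
#'
#' `d(g, h)` = (#samples where exactly one of g, h is salient) / (#samples
#' where at least one is salient) — joint absences are ignored, matching the
#' asymmetric "binary" dissimilarity convention. Gene pairs that are never
#' salient have `d = 0` (they are indistinguishable under the support
#' convention); a warning flags the presence of such genes.
#'
#' @param sal binary genes x samples matrix.
#' @return a `dist` object over genes.
#' @export
binary_distance <- function(sal) {
  m <- as.matrix(sal)
  if (any(rowSums(m) == 0))
    warning(sum(rowSums(m) == 0),
            " never-salient gene(s): pairwise distance defined as 0 among them",
            call. = FALSE)
  stats::dist(m, method = "binary")
}

#' Ward hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative clustering by the Lance-Williams recurrence with Ward
#' coefficients applied directly to the supplied dissimilarities (not squared
#' first, i.e. the classic 'ward.D' variant). Merge heights are
#' non-decreasing; a 2-leaf tree merges at the input distance.
#'
#' @param dist a `dist` object or symmetric nonnegative matrix with zero
#'   diagonal.
#' @return an `hclust` dendrogram.
#' @export
ward_cluster <- function(dist) {
  d <- stats::as.dist(dist)
  if (attr(d, "Size") < 2) stop_arg("need >= 2 genes to cluster")
  stats::hclust(d, method = "ward.D")
}

#' Significance-driven sub-cluster decomposition
#'
#' Gradually lowers the dendrogram height threshold — equivalently, cuts the
#' tree into k = 2, 3, ... groups at successive merge heights — and at each k
#' runs a Kruskal-Wallis test of the gene-wise minimum eQTL p-values across
#' the emerging sub-clusters. Stops at the first k whose test is nominally
#' significant (`p < alpha`). Only genes with a non-missing minimum p enter
#' the tests.
#'
#' @param dendro an `hclust` over genes (labels required).
#' @param gene_min_p named numeric vector of gene-wise minimum p-values.
#' @param alpha nominal stopping level (default 0.05).
#' @param k_max largest split count tried (default 10).
#' @return object of class `cluster_decomposition`: list with `decomposed`
#'   (logical), `k`, `labels` (named integer vector over all dendrogram
#'   genes), `medians` (per-sub-cluster median minimum p), `sizes`, and
#'   `p_by_k` (KW p at every k tried, in increasing k order).
#' @export
decompose_subclusters <- function(dendro, gene_min_p, alpha = 0.05,
                                  k_max = 10L) {
  if (k_max < 2) stop_arg("k_max must be >= 2")
  genes <- dendro$labels
  if (is.null(genes)) stop_arg("dendrogram must carry gene labels")
  p_use <- gene_min_p[intersect(genes, names(gene_min_p))]
  p_use <- p_use[!is.na(p_use)]
  k_max <- min(k_max, length(genes))
  p_by_k <- stats::setNames(rep(NA_real_, max(0, k_max - 1L)),
                            as.character(seq_len(k_max)[-1]))
  for (k in 2:k_max) {
    labels <- stats::cutree(dendro, k = k)
    grp <- labels[names(p_use)]
    if (length(unique(grp)) < 2) next
    if (length(unique(p_use)) == 1) { p_by_k[as.character(k)] <- 1; next }
    pk <- suppressWarnings(stats::kruskal.test(p_use, factor(grp))$p.value)
    p_by_k[as.character(k)] <- pk
    if (!is.na(pk) && pk < alpha) {
      med <- tapply(p_use, factor(grp, levels = sort(unique(labels))),
                    stats::median)
      sizes <- as.integer(table(factor(labels, levels = sort(unique(labels)))))
      return(structure(list(decomposed = TRUE, k = k, labels = labels,
                            medians = med, sizes = sizes,
                            p_by_k = p_by_k[seq_len(k - 1L)]),
                       class = "cluster_decomposition"))
    }
  }
  structure(list(decomposed = FALSE, k = NA_integer_, labels = NULL,
                 medians = NULL, sizes = NULL, p_by_k = p_by_k),
            class = "cluster_decomposition")
}

#' @export
print.cluster_decomposition <- function(x, ...) {
  if (x$decomposed) {
    cat("cluster_decomposition: k =", x$k, "sub-clusters; KW p =",
        signif(unname(x$p_by_k[as.character(x$k)]), 3), "\n")
    cat("sizes:", paste(x$sizes, collapse = ", "), "| medians:",
        paste(signif(x$medians, 3), collapse = ", "), "\n")
  } else cat("cluster_decomposition: no decomposition up to k_max\n")
  invisible(x)
}

#' Select the target sub-cluster of a decomposition
#'
#' Returns the member genes of the sub-cluster with the smallest median
#' gene-wise minimum p; ties are broken by smaller cluster size, then by
#' lower cluster label.
#'
#' @param decomp a `cluster_decomposition`.
#' @return character vector of gene IDs; errors if no decomposition exists.
#' @export
select_target_subcluster <- function(decomp) {
  if (!isTRUE(decomp$decomposed)) stop_arg("no decomposition available")
  ids <- as.integer(names(decomp$medians))
  ord <- order(decomp$medians, decomp$sizes[ids], ids)
  target <- ids[ord[1]]
  names(decomp$labels)[decomp$labels == target]
}

#' Hypergeometric enrichment of a gene set against term annotations
#'
#' One-sided hypergeometric tail p per term with Bonferroni correction over
#' the tested terms; terms overlapping the gene set in fewer than
#' `min_overlap` genes are excluded (generic plumbing standing in for
#' external enrichment services).
#'
#' @param gene_set character vector, subset of `background`.
#' @param annotation named list: term -> character vector of genes.
#' @param background character vector of background genes.
#' @param min_overlap minimum gene-set overlap per tested term (default 10).
#' @return data.frame `term`, `n_term`, `n_overlap`, `p`, `p_bonferroni`,
#'   sorted by p.
#' @export
hypergeometric_enrichment <- function(gene_set, annotation, background,
                                      min_overlap = 10L) {
  background <- unique(as.character(background))
  if (!length(background)) stop_arg("empty background")
  gene_set <- unique(as.character(gene_set))
  if (length(setdiff(gene_set, background)))
    stop_arg("gene_set must be a subset of background")
  N <- length(background); n <- length(gene_set)
  rows <- list()
  for (term in names(annotation)) {
    tg <- intersect(unique(annotation[[term]]), background)
    k <- length(intersect(tg, gene_set))
    if (k < min_overlap) next
    p <- stats::phyper(k - 1, length(tg), N - length(tg), n,
                       lower.tail = FALSE)
    rows[[term]] <- data.frame(term = term, n_term = length(tg),
                               n_overlap = k, p = p,
                               stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(term = character(), n_term = integer(),
                      n_overlap = integer(), p = numeric(),
                      p_bonferroni = numeric()))
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  out
}

#' Read a two-column term/gene annotation TSV into a term -> genes list
#' @param path TSV with columns `term`, `gene`.
#' @return named list of character vectors.
#' @export
read_annotation_tsv <- function(path) {
  df <- read_tsv(path)
  split(df$gene, df$term)
}

#' Export an hclust dendrogram as Newick
#' @param dendro an `hclust`.
#' @param path output path.
#' @export
write_newick <- function(dendro, path) {
  build <- function(i) {
    if (i < 0) return(dendro$labels[-i])
    mr <- dendro$merge[i, ]
    paste0("(", build(mr[1]), ",", build(mr[2]), "):",
           format(dendro$height[i], digits = 8))
  }
  writeLines(paste0(build(nrow(dendro$merge)), ";"), path)
  invisible(path)
}
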