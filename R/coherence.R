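#' Connectivity of an induced subnetwork
#'
#' The connectivity of a gene set is the proportion of nodes of the induced
#' subgraph that are connected to at least one other node of the subgraph
#' (nodes of non-zero induced degree / total nodes). Genes absent from the
#' network are dropped before evaluation.
#'
#' @param network a `gene_network`, or a precomputed logical adjacency matrix.
#' @param gene_set character vector of gene IDs (or integer node indices when
#'   `network` is an adjacency matrix).
#' @return a proportion in `[0, 1]`; `NA_real_` when the evaluation set is
#'   empty (undefined value).
#' @export
subnetwork_connectivity <- function(network, gene_set) {
  if (inherits(network, "gene_network")) {
    A <- adjacency_matrix(network)
    idx <- match(intersect(unique(gene_set), network$nodes), network$nodes)
  } else {
    A <- network
    idx <- if (is.character(gene_set)) match(intersect(unique(gene_set), rownames(A)), rownames(A)) else unique(gene_set)
  }
  connectivity_idx(A, idx)
}

# Fast path: connectivity from adjacency matrix + integer indices.
connectivity_idx <- function(A, idx) {
  k <- length(idx)
  if (k == 0L) return(NA_real_)
  if (k == 1L) return(0)
  sub <- A[idx, idx]
  sum(.rowSums(sub, k, k) > 0L) / k
}

#' Simulated null distribution of subnetwork connectivity
#'
#' Draws `n_draws` uniform without-replacement gene sets of size `k` from the
#' network's node set and records the connectivity of each. The sampling frame
#' is the measured, restricted network that observed salient sets live in, so
#' that the null matches the observation space.
#'
#' @param network a `gene_network` or logical adjacency matrix.
#' @param k set size, `2 <= k <= n_nodes`.
#' @param n_draws number of random sets (default 2000).
#' @param seed integer RNG seed.
#' @return object of class `null_distribution`: list with `set_size`, `draws`,
#'   `n_draws`, `seed`, `mean`, `sd` (n-1 denominator).
#' @export
null_connectivity <- function(network, k, n_draws = 2000L, seed = 1L) {
  A <- if (inherits(network, "gene_network")) adjacency_matrix(network) else network
  n <- nrow(A)
  if (!is.numeric(k) || length(k) != 1L || k < 2 || k > n)
    stop_arg("k must satisfy 2 <= k <= ", n)
  if (n_draws < 2) stop_arg("n_draws must be >= 2")
  k <- as.integer(k)
  draws <- with_seed(seed, {
    vapply(seq_len(n_draws),
           function(i) connectivity_idx(A, sample.int(n, k)),
           numeric(1))
  })
  structure(list(set_size = k, draws = draws, n_draws = as.integer(n_draws),
                 seed = as.integer(seed),
                 mean = mean(draws), sd = stats::sd(draws)),
            class = "null_distribution")
}

#' Metabolic network coherence score of one salient gene set
#'
#' The MC value is the z-score of the observed subnetwork connectivity with
#' respect to the simulated null for sets of the same size:
#' `z = (observed - null mean) / null sd`. The score is missing (with a reason
#' code) when fewer than 2 salient genes map onto the network, or when the
#' null is degenerate (sd = 0).
#'
#' @param network a `gene_network` or logical adjacency matrix.
#' @param salient_genes character vector of salient gene IDs.
#' @param n_draws,seed passed to [null_connectivity()].
#' @param null optional precomputed `null_distribution` for the matching set
#'   size (cache support).
#' @return list with `mc` (numeric or NA), `k`, `observed`, `reason`
#'   (`"ok"`, `"too_few_mapped"` or `"degenerate_null"`).
#' @export
mc_score <- function(network, salient_genes, n_draws = 2000L, seed = 1L,
                     null = NULL) {
  A <- if (inherits(network, "gene_network")) adjacency_matrix(network) else network
  idx <- match(intersect(unique(as.character(salient_genes)), rownames(A)),
               rownames(A))
  k <- length(idx)
  if (k < 2L)
    return(list(mc = NA_real_, k = k, observed = NA_real_,
                reason = "too_few_mapped"))
  if (is.null(null)) null <- null_connectivity(A, k, n_draws, seed)
  stopifnot(null$set_size == k)
  obs <- connectivity_idx(A, idx)
  if (!is.finite(null$sd) || null$sd == 0)
    return(list(mc = NA_real_, k = k, observed = obs,
                reason = "degenerate_null"))
  list(mc = (obs - null$mean) / null$sd, k = k, observed = obs, reason = "ok")
}

#' Per-sample MC profile of a salience matrix
#'
#' Computes one MC z-score per sample from its salient gene set. Null
#' distributions are cached per set size k within the run, each drawn under a
#' deterministic per-k seed derived from the master seed, so samples with
#' equal k share a null and the whole profile is bit-reproducible.
#'
#' @param network a `gene_network` already restricted to the measured genes.
#' @param sal binary genes x samples `salience_matrix`.
#' @param n_draws draws per null distribution (default 2000).
#' @param seed master integer seed.
#' @return a data.frame of class `mc_profile` with columns `sample`, `mc`,
#'   `k`, `reason`; configuration recorded in `attr(, "config")`.
#' @export
mc_profile <- function(network, sal, n_draws = 2000L, seed = 1L) {
  A <- adjacency_matrix(network)
  genes <- rownames(sal)
  samples <- colnames(sal)
  gene_idx <- match(genes, rownames(A))  # NA for unmeasured/off-network genes
  null_cache <- new.env(parent = emptyenv())
  res <- vector("list", length(samples))
  for (s in seq_along(samples)) {
    idx <- gene_idx[sal[, s] == 1L]
    idx <- idx[!is.na(idx)]
    k <- length(idx)
    if (k < 2L) {
      res[[s]] <- list(mc = NA_real_, k = k, reason = "too_few_mapped")
      next
    }
    key <- as.character(k)
    if (is.null(null_cache[[key]]))
      null_cache[[key]] <- null_connectivity(
        A, k, n_draws, derive_seed(seed, paste0("null_k", k)))
    sc <- mc_score(A, rownames(A)[idx], null = null_cache[[key]])
    res[[s]] <- sc[c("mc", "k", "reason")]
  }
  out <- data.frame(sample = samples,
                    mc = vapply(res, `[[`, numeric(1), "mc"),
                    k = vapply(res, `[[`, integer(1), "k"),
                    reason = vapply(res, `[[`, character(1), "reason"),
                    stringsAsFactors = FALSE)
  attr(out, "config") <- list(n_draws = as.integer(n_draws),
                              seed = as.integer(seed))
  class(out) <- c("mc_profile", class(out))
  out
}

#' Sensitivity sweep over currency fraction and salience quantile
#'
#' Re-runs the full model -> network -> dichotomization -> MC pipeline over
#' the cross-product of currency-removal fractions and salience quantiles
#' (defaults mirror the conventional sweep: fractions 3-8% in 1% steps,
#' quantiles 1-3%).
#'
#' @param model a `metabolic_model` (currency metabolites NOT yet removed).
#' @param expr numeric genes x samples log-expression matrix.
#' @param currency_fractions numeric vector of removal fractions.
#' @param quantiles numeric vector of salience quantiles.
#' @param n_draws,seed as in [mc_profile()].
#' @return long-format data.frame with columns `fraction`, `q`, `sample`,
#'   `mc`, `k`, `reason`.
#' @export
sensitivity_sweep <- function(model, expr,
                              currency_fractions = seq(0.03, 0.08, by = 0.01),
                              quantiles = c(0.01, 0.02, 0.03),
                              n_draws = 2000L, seed = 1L) {
  if (!length(currency_fractions) || !length(quantiles))
    stop_arg("currency_fractions and quantiles must be nonempty")
  cells <- list()
  for (f in currency_fractions) {
    pruned <- remove_currency_metabolites(model, f)$model
    net <- restrict_to_measured(project_gene_network(pruned), rownames(expr))
    for (q in quantiles) {
      sal <- dichotomize(expr, q)
      prof <- mc_profile(net, sal, n_draws = n_draws, seed = seed)
      cells[[length(cells) + 1L]] <-
        data.frame(fraction = f, q = q, prof, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  out
}

#' Write an MC profile as TSV
#' @param profile an `mc_profile`.
#' @param path output path.
#' @export
write_mc_profile <- function(profile, path) write_tsv(profile, path)
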