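#' Preprocess a raw count matrix
#'
#' Drops genes with a zero fraction strictly greater than `max_zero_fraction`
#' (the conventional "zero in > 50% of samples" filter) and log-transforms the
#' remaining values as `log2(x + 1)`.
#'
#' @param raw nonnegative numeric genes x samples matrix with dimnames.
#' @param max_zero_fraction maximum tolerated fraction of zero counts per
#'   gene; genes exceeding it (strictly) are removed. Default 0.5.
#' @return numeric matrix of log2-transformed values, same column order,
#'   filtered rows.
#' @export
preprocess_counts <- function(raw, max_zero_fraction = 0.5) {
  raw <- as.matrix(raw)
  if (any(raw < 0, na.rm = TRUE))
    stop_arg("raw counts must be nonnegative")
  zero_frac <- rowMeans(raw == 0, na.rm = TRUE)
  keep <- zero_frac <= max_zero_fraction
  log2(raw[keep, , drop = FALSE] + 1)
}

#' Dichotomize expression into normal vs salient states
#'
#' Per gene, a value is salient iff it lies at or below the lower empirical
#' `q`-quantile or at or above the upper `(1 - q)`-quantile of that gene's
#' values across samples (both tails simultaneously, capturing concordant and
#' discordant co-regulation). Quantiles use the linear-interpolation
#' convention (type 7); ties at a threshold are salient. The rule is invariant
#' under strictly monotone transforms of a gene's values.
#'
#' Constant genes are never salient. Genes with fewer than `min_samples`
#' non-missing values are set all-zero with a warning, since extreme-tail
#' quantiles are meaningless at tiny n.
#'
#' @param expr numeric genes x samples matrix with dimnames.
#' @param q tail probability in (0, 0.5); default 0.02.
#' @param min_samples minimum non-missing values per gene; default 10.
#' @return integer 0/1 matrix of the same shape (class `salience_matrix`).
#' @export
dichotomize <- function(expr, q = 0.02, min_samples = 10L) {
  expr <- as.matrix(expr)
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 0.5)
    stop_arg("q must be a single number in (0, 0.5)")
  states <- matrix(0L, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  too_few <- 0L
  for (g in seq_len(nrow(expr))) {
    x <- expr[g, ]
    ok <- !is.na(x)
    if (sum(ok) < min_samples) { too_few <- too_few + 1L; next }
    xs <- x[ok]
    if (max(xs) == min(xs)) next  # constant gene: no signal
    thr <- stats::quantile(xs, c(q, 1 - q), type = 7, names = FALSE)
    states[g, ok] <- as.integer(xs <= thr[1] | xs >= thr[2])
  }
  if (too_few > 0L)
    warning(too_few, " gene(s) with < ", min_samples,
            " non-missing values set to all-zero salience", call. = FALSE)
  class(states) <- c("salience_matrix", class(states))
  states
}

#' Number of salient samples per tail implied by the quantile convention
#'
#' For distinct values, the inclusive type-7 rule flags exactly
#' `floor((n - 1) * q + 1)` samples in each tail. Used by the synthetic-data
#' generator to plant exactly recoverable salience matrices.
#'
#' @param n_samples number of samples.
#' @param q tail probability.
#' @return integer count per tail.
#' @export
salient_count_per_tail <- function(n_samples, q) {
  as.integer(floor((n_samples - 1) * q + 1))
}

#' Read / write an expression (or generic genes x samples) TSV matrix
#'
#' First column holds gene IDs, header holds sample IDs.
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression_tsv
#' @param mat matrix to write.
#' @param id_col name for the gene-ID column (default `"gene"`).
#' @export
write_expression_tsv <- function(mat, path, id_col = "gene") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}
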