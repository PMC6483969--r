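#' Single-SNP linear-model scan of MC on dosage genotypes
#'
#' Fits, for each SNP, an ordinary least squares model of the continuous MC
#' phenotype on the SNP's minor-allele dosage plus covariates (one SNP at a
#' time), on complete cases. Samples with missing MC are excluded; categorical
#' covariates are expanded to reference-coded indicators (reference =
#' lexicographically first level). Monomorphic SNPs are skipped; dosages
#' collinear with the covariates yield a flagged result with missing p.
#'
#' @param mc an [mc_profile()] data.frame (columns `sample`, `mc`), or any
#'   data.frame with those columns.
#' @param panel a `dosage_panel`.
#' @param covars optional data.frame with a `sample` column plus covariate
#'   columns (e.g. population, sex); character/factor columns are treated as
#'   categorical.
#' @param condition_on optional SNP ID whose dosage is appended to the
#'   covariates (the SNP itself is skipped) — the conditional scan used to
#'   hunt for independent signals.
#' @param region optional `list(chrom=, start=, end=)` restricting the scan to
#'   a closed interval.
#' @return data.frame with columns `snp`, `chrom`, `pos`, `beta`, `se`, `t`,
#'   `p`, `n`, `flag` (`"ok"`, `"monomorphic"`, `"collinear"`,
#'   `"too_few_samples"`).
#' @export
gwas_scan <- function(mc, panel, covars = NULL, condition_on = NULL,
                      region = NULL) {
  stopifnot(all(c("sample", "mc") %in% names(mc)))
  if (!is.null(region)) {
    sel <- panel$info$chrom == as.character(region$chrom) &
      panel$info$pos >= region$start & panel$info$pos <= region$end
    panel <- panel[which(sel), ]
  }
  cond_dose <- NULL
  if (!is.null(condition_on)) {
    ci <- match(condition_on, panel$info$snp)
    if (is.na(ci)) stop_arg("condition_on SNP not in panel: ", condition_on)
    cond_dose <- panel$dosage[ci, ]
  }
  samples <- intersect(mc$sample[!is.na(mc$mc)], colnames(panel$dosage))
  if (!is.null(covars)) samples <- intersect(samples, covars$sample)
  y_all <- mc$mc[match(samples, mc$sample)]
  X_cov <- matrix(1, length(samples), 1, dimnames = list(samples, "(Intercept)"))
  if (!is.null(covars)) {
    cv <- covars[match(samples, covars$sample), setdiff(names(covars), "sample"),
                 drop = FALSE]
    for (nm in names(cv)) {
      if (is.character(cv[[nm]]) || is.factor(cv[[nm]]) || is.logical(cv[[nm]]))
        cv[[nm]] <- factor(as.character(cv[[nm]]), levels = sort(unique(as.character(cv[[nm]]))))
    }
    mm <- stats::model.matrix(~ ., data = cv)
    X_cov <- mm[, , drop = FALSE]
    rownames(X_cov) <- samples
  }
  if (!is.null(cond_dose)) {
    X_cov <- cbind(X_cov, cond_snp = cond_dose[samples])
  }
  dmat <- panel$dosage[, samples, drop = FALSE]
  res <- vector("list", nrow(panel$info))
  for (i in seq_len(nrow(panel$info))) {
    snp <- panel$info$snp[i]
    if (!is.null(condition_on) && snp == condition_on) next
    g <- dmat[i, ]
    ok <- !is.na(g) & stats::complete.cases(X_cov) & !is.na(y_all)
    n_used <- sum(ok)
    p_par <- ncol(X_cov) + 1L
    if (n_used < p_par + 2L) {
      res[[i]] <- list(snp = snp, beta = NA_real_, se = NA_real_, t = NA_real_,
                       p = NA_real_, n = n_used, flag = "too_few_samples")
      next
    }
    gv <- g[ok]
    if (stats::var(gv) == 0) {
      res[[i]] <- list(snp = snp, beta = NA_real_, se = NA_real_, t = NA_real_,
                       p = NA_real_, n = n_used, flag = "monomorphic")
      next
    }
    X <- cbind(X_cov[ok, , drop = FALSE], dosage = gv)
    fit <- stats::lm.fit(X, y_all[ok])
    if (fit$rank < ncol(X) || is.na(fit$coefficients["dosage"])) {
      res[[i]] <- list(snp = snp, beta = NA_real_, se = NA_real_, t = NA_real_,
                       p = NA_real_, n = n_used, flag = "collinear")
      next
    }
    df_res <- n_used - fit$rank
    sigma2 <- sum(fit$residuals^2) / df_res
    XtXinv <- chol2inv(qr.R(fit$qr))
    # variance of the dosage coefficient (last pivoted column)
    piv <- fit$qr$pivot[seq_len(fit$rank)]
    vpos <- which(colnames(X)[piv] == "dosage")
    se <- sqrt(sigma2 * XtXinv[vpos, vpos])
    beta <- unname(fit$coefficients["dosage"])
    tval <- beta / se
    pval <- 2 * stats::pt(abs(tval), df_res, lower.tail = FALSE)
    res[[i]] <- list(snp = snp, beta = beta, se = se, t = tval, p = pval,
                     n = n_used, flag = "ok")
  }
  res <- res[!vapply(res, is.null, logical(1))]
  out <- data.frame(
    snp = vapply(res, `[[`, "", "snp"),
    beta = vapply(res, `[[`, numeric(1), "beta"),
    se = vapply(res, `[[`, numeric(1), "se"),
    t = vapply(res, `[[`, numeric(1), "t"),
    p = vapply(res, `[[`, numeric(1), "p"),
    n = vapply(res, function(r) as.integer(r$n), integer(1)),
    flag = vapply(res, `[[`, "", "flag"),
    stringsAsFactors = FALSE)
  m <- match(out$snp, panel$info$snp)
  out <- cbind(out[, "snp", drop = FALSE],
               chrom = panel$info$chrom[m], pos = panel$info$pos[m],
               out[, -1, drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Conditional association scan adjusted for a top SNP
#'
#' Same model as [gwas_scan()] with the top SNP's dosage appended to the
#' covariates; the top SNP itself is skipped.
#'
#' @inheritParams gwas_scan
#' @param top_snp SNP ID to condition on.
#' @return as [gwas_scan()].
#' @export
conditional_scan <- function(mc, panel, covars = NULL, top_snp, region = NULL) {
  gwas_scan(mc, panel, covars, condition_on = top_snp, region = region)
}

#' Significance thresholds for genome-wide and regional testing
#'
#' The genome-wide threshold is the conventional fixed 5e-8 regardless of
#' inputs; the regional threshold is Bonferroni over the LD-effective number
#' of tests, `0.05 / m_eff`.
#'
#' @param n_snps_genomewide number of genome-wide SNPs (recorded only).
#' @param m_eff_region LD-effective SNP count in the region (>= 1).
#' @param alpha nominal level (default 0.05).
#' @return list with `genomewide` (5e-8) and `regional` (`alpha / m_eff`).
#' @export
significance_thresholds <- function(n_snps_genomewide = NULL, m_eff_region,
                                    alpha = 0.05) {
  stopifnot(m_eff_region >= 1)
  list(genomewide = 5e-8, regional = alpha / m_eff_region,
       n_snps_genomewide = n_snps_genomewide, m_eff_region = m_eff_region)
}

#' Nonparametric group heterogeneity test
#'
#' Two groups: two-sided Wilcoxon rank-sum (exact enumeration below 50
#' observations per group when tie-free, normal approximation with continuity
#' correction otherwise). More than two groups: Kruskal-Wallis with tie
#' correction.
#'
#' @param values numeric vector.
#' @param labels group labels, same length.
#' @return p-value.
#' @export
group_heterogeneity <- function(values, labels) {
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- as.character(labels[ok])
  groups <- split(values, labels)
  if (length(groups) < 2) stop_arg("need >= 2 groups with non-missing values")
  if (length(groups) == 2) {
    exact <- all(lengths(groups) < 50) && !anyDuplicated(values)
    suppressWarnings(stats::wilcox.test(groups[[1]], groups[[2]],
                                        exact = exact, correct = TRUE)$p.value)
  } else {
    stats::kruskal.test(values, factor(labels))$p.value
  }
}

#' Plot-ready Manhattan / QQ tables and genomic inflation
#'
#' @param results a [gwas_scan()] result (non-missing p rows used).
#' @return list with `manhattan` (chrom, pos, p, neg_log10_p), `qq`
#'   (expected, observed on -log10 scale, expected strictly increasing) and
#'   `lambda` (median chi-square inflation factor).
#' @export
manhattan_qq_export <- function(results) {
  r <- results[!is.na(results$p), , drop = FALSE]
  if (!nrow(r)) stop_arg("no usable p-values")
  manhattan <- data.frame(snp = r$snp, chrom = r$chrom, pos = r$pos, p = r$p,
                          neg_log10_p = -log10(r$p))
  obs <- sort(r$p)
  n <- length(obs)
  expd <- (seq_len(n) - 0.5) / n
  qq <- data.frame(expected = -log10(rev(expd)), observed = -log10(rev(obs)))
  lambda <- stats::median(stats::qchisq(r$p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1, lower.tail = FALSE)
  list(manhattan = manhattan, qq = qq, lambda = lambda)
}
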