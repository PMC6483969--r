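#' Construct a dosage panel
#'
#' SNPs x samples minor-allele dosages in `[0, 2]` (fractional after
#' imputation; missing allowed) plus per-SNP metadata.
#'
#' @param dosage numeric snps x samples matrix, rownames = SNP IDs.
#' @param info data.frame with columns `snp`, `chrom`, `pos` (1-based bp),
#'   `minor`, `major`; rows aligned with `dosage`.
#' @return object of class `dosage_panel`.
#' @export
dosage_panel <- function(dosage, info) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  info <- as.data.frame(info, stringsAsFactors = FALSE)
  stopifnot(all(c("snp", "chrom", "pos", "minor", "major") %in% names(info)),
            nrow(info) == nrow(dosage))
  if (anyDuplicated(info$snp)) stop_arg("duplicate SNP IDs")
  if (any(info$pos < 0)) stop_arg("negative SNP positions")
  rng <- range(dosage, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    stop_arg("dosages must lie in [0, 2]")
  rownames(dosage) <- info$snp
  info$chrom <- as.character(info$chrom)
  structure(list(info = info, dosage = dosage), class = "dosage_panel")
}

#' @export
print.dosage_panel <- function(x, ...) {
  cat("dosage_panel:", nrow(x$dosage), "SNPs x", ncol(x$dosage), "samples\n")
  invisible(x)
}

#' @export
`[.dosage_panel` <- function(x, i, j) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  if (is.character(i)) i <- match(i, x$info$snp)
  dosage_panel(x$dosage[i, j, drop = FALSE], x$info[i, , drop = FALSE])
}

#' Default genotype QC criteria
#'
#' Conventional array-QC thresholds: call rate >= 0.99, autosomal location,
#' MAF > 0.05, >= 5 minor-allele homozygotes, Hardy-Weinberg p >= 0.001.
#'
#' @param min_call_rate,min_maf,min_minor_homs,min_hwe_p thresholds.
#' @return a `qc_criteria` list.
#' @export
qc_criteria <- function(min_call_rate = 0.99, min_maf = 0.05,
                        min_minor_homs = 5L, min_hwe_p = 0.001) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf < 0.5,
            min_minor_homs >= 0, min_hwe_p >= 0, min_hwe_p <= 1)
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 min_minor_homs = as.integer(min_minor_homs),
                 min_hwe_p = min_hwe_p),
            class = "qc_criteria")
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit of observed genotype counts against
#' the HWE expectations p^2, 2pq, q^2 with the allele frequency estimated from
#' the data. Monomorphic markers return p = 1 by convention.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (major hom, het, minor hom).
#' @return p-value.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop_arg("at least one genotype required")
  p <- (2 * n_AA + n_Aa) / (2 * n)  # major-allele frequency
  if (p == 0 || p == 1) return(1)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((c(n_AA, n_Aa, n_aa) - expected)^2 / expected)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

# Re-polarize so dosages count the minor allele; flip where freq > 0.5.
polarize_panel <- function(panel) {
  f <- rowMeans(panel$dosage, na.rm = TRUE) / 2
  flip <- !is.na(f) & f > 0.5
  if (any(flip)) {
    panel$dosage[flip, ] <- 2 - panel$dosage[flip, ]
    tmp <- panel$info$minor[flip]
    panel$info$minor[flip] <- panel$info$major[flip]
    panel$info$major[flip] <- tmp
  }
  panel
}

#' Genotype quality control
#'
#' Applies, in order: call rate, autosomal location, MAF, minor-homozygote
#' count, and Hardy-Weinberg filters; the report records the first failing
#' criterion per removed SNP. The panel is first re-polarized so dosages count
#' the minor allele (MAF = mean dosage / 2). Homozygote and HWE checks need
#' hard genotypes; SNPs whose dosages are materially fractional
#' (|d - round(d)| > 0.1 in > 10% of non-missing samples) are flagged `soft`
#' and those two checks are skipped for them.
#'
#' @param panel a `dosage_panel`.
#' @param criteria a [qc_criteria()] list.
#' @param autosomes_only apply the autosome filter (default TRUE); autosomes
#'   are chromosome labels `1..22`, optionally `chr`-prefixed.
#' @return list with `panel` (filtered, polarized), `report` (data.frame
#'   `snp`, `kept`, `reason`, `maf`, `soft`).
#' @export
snp_qc <- function(panel, criteria = qc_criteria(), autosomes_only = TRUE) {
  panel <- polarize_panel(panel)
  d <- panel$dosage
  n_samp <- ncol(d)
  call_rate <- 1 - rowMeans(is.na(d))
  maf <- rowMeans(d, na.rm = TRUE) / 2   # post-polarization: freq = MAF
  maf <- pmin(maf, 1 - maf)
  chrom <- sub("^chr", "", panel$info$chrom)
  autosomal <- chrom %in% as.character(1:22)
  hard <- round(d)
  soft <- rowMeans(abs(d - hard) > 0.1, na.rm = TRUE) > 0.1
  reason <- rep(NA_character_, nrow(d))
  for (i in seq_len(nrow(d))) {
    if (call_rate[i] < criteria$min_call_rate) { reason[i] <- "call_rate"; next }
    if (autosomes_only && !autosomal[i]) { reason[i] <- "autosome"; next }
    if (is.na(maf[i]) || maf[i] <= criteria$min_maf) { reason[i] <- "maf"; next }
    if (!soft[i]) {
      g <- hard[i, ]
      n2 <- sum(g == 2, na.rm = TRUE)
      if (n2 < criteria$min_minor_homs) { reason[i] <- "min_minor_homs"; next }
      p_hwe <- hwe_test(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE), n2)
      if (p_hwe < criteria$min_hwe_p) { reason[i] <- "hwe"; next }
    }
  }
  kept <- is.na(reason)
  report <- data.frame(snp = panel$info$snp, kept = kept, reason = reason,
                       maf = maf, soft = soft, stringsAsFactors = FALSE)
  list(panel = panel[which(kept), ], report = report)
}

#' Linkage disequilibrium r-squared between two dosage vectors
#'
#' Squared Pearson correlation over pairwise-complete entries; symmetric and
#' invariant to allele flips of either SNP.
#'
#' @param x,y numeric dosage vectors of equal length.
#' @return r^2 in `[0, 1]`, or `NA_real_` when undefined (zero variance or
#'   fewer than 2 complete pairs).
#' @export
ld_r2 <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])^2
}

#' Greedy LD pruning
#'
#' Position-sorted left-to-right scan within each chromosome: a SNP is dropped
#' when its r^2 with any retained SNP at most `window_bp` upstream exceeds
#' `r2_max`. `window_bp = 0` compares nothing and retains everything.
#'
#' @param panel a `dosage_panel`.
#' @param r2_max maximum tolerated r^2 (default 0.8).
#' @param window_bp window size in base pairs (default 500000).
#' @return the pruned `dosage_panel`.
#' @export
ld_prune <- function(panel, r2_max = 0.8, window_bp = 500000L) {
  ord <- order(panel$info$chrom, panel$info$pos)
  panel <- panel[ord, ]
  keep <- logical(nrow(panel$info))
  for (chr in unique(panel$info$chrom)) {
    idx <- which(panel$info$chrom == chr)
    retained <- integer()
    for (i in idx) {
      drop <- FALSE
      if (window_bp > 0 && length(retained)) {
        near <- retained[panel$info$pos[i] - panel$info$pos[retained] <= window_bp]
        for (j in near) {
          r2 <- ld_r2(panel$dosage[i, ], panel$dosage[j, ])
          if (!is.na(r2) && r2 > r2_max) { drop <- TRUE; break }
        }
      }
      if (!drop) { retained <- c(retained, i); keep[i] <- TRUE }
    }
  }
  panel[which(keep), ]
}

#' Principal component analysis of genotype dosages
#'
#' Per-SNP centred and unit-variance scaled dosages (missing values imputed to
#' the SNP mean, i.e. 0 after centring; zero-variance SNPs dropped), then the
#' top principal components of the sample covariance.
#'
#' @param panel a `dosage_panel` (ideally LD-pruned).
#' @param n_components number of components (default 10, truncated to rank
#'   with a warning when larger).
#' @return list with `scores` (samples x components), `var_explained`
#'   (fractions, non-increasing, summing to <= 1).
#' @export
genotype_pca <- function(panel, n_components = 10L) {
  d <- panel$dosage
  if (nrow(d) < 2 || ncol(d) < 2) stop_arg("need >= 2 SNPs and >= 2 samples")
  mu <- rowMeans(d, na.rm = TRUE)
  sdv <- apply(d, 1, stats::sd, na.rm = TRUE)
  keep <- !is.na(sdv) & sdv > 0
  if (!any(keep)) {
    warning("all SNPs have zero variance; returning zero scores", call. = FALSE)
    sc <- matrix(0, ncol(d), n_components,
                 dimnames = list(colnames(d), paste0("PC", seq_len(n_components))))
    return(list(scores = sc, var_explained = rep(0, n_components)))
  }
  z <- (d[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  z[is.na(z)] <- 0
  pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  rank <- sum(pc$sdev > 1e-12)
  if (n_components > rank) {
    warning("n_components truncated to rank ", rank, call. = FALSE)
    n_components <- rank
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       var_explained = ve[seq_len(n_components)])
}

#' LD-effective number of independent tests
#'
#' Eigenvalue-based effective test count of Li & Ji (2005) on the SNP dosage
#' correlation matrix: `m_eff = sum_i [ I(lambda_i >= 1) + (lambda_i -
#' floor(lambda_i)) ]`. Undefined correlations (zero-variance SNPs) are
#' imputed to 0 with a warning.
#'
#' @param panel a `dosage_panel`.
#' @return list with `m_eff` (real, in `[1, n_snps]`) and `method` tag.
#' @export
effective_tests <- function(panel) {
  d <- panel$dosage
  if (nrow(d) < 1) stop_arg("need >= 1 SNP")
  if (nrow(d) == 1) return(list(m_eff = 1, method = "liji2005"))
  cc <- suppressWarnings(stats::cor(t(d), use = "pairwise.complete.obs"))
  if (anyNA(cc)) {
    warning("undefined correlations imputed to 0", call. = FALSE)
    cc[is.na(cc)] <- 0
    diag(cc) <- 1
  }
  lambda <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
  lambda[lambda < 0] <- 0
  m_eff <- sum(as.numeric(lambda >= 1) + (lambda - floor(lambda)))
  list(m_eff = max(1, min(m_eff, nrow(d))), method = "liji2005")
}

#' Read / write a dosage panel as TSV
#'
#' Columns: `snp`, `chrom`, `pos`, `minor`, `major`, then one column per
#' sample holding dosages (empty/NA allowed).
#'
#' @param path file path.
#' @return a `dosage_panel`.
#' @export
read_dosage_tsv <- function(path) {
  df <- read_tsv(path)
  meta <- c("snp", "chrom", "pos", "minor", "major")
  stopifnot(all(meta %in% names(df)))
  d <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  storage.mode(d) <- "double"
  dosage_panel(d, df[, meta])
}

#' @rdname read_dosage_tsv
#' @param panel a `dosage_panel` to write.
#' @export
write_dosage_tsv <- function(panel, path) {
  write_tsv(cbind(panel$info, as.data.frame(panel$dosage)), path)
}

#' Read a dosage panel from a (plain-text) VCF
#'
#' Reads the fixture-scale VCF subset this package writes: the `DS` FORMAT
#' field when present, otherwise `GT` hard calls converted to 0/1/2 counts of
#' the ALT allele. ALT is taken as the minor allele (re-polarized downstream
#' by [snp_qc()] if needed).
#'
#' @param path path to an uncompressed VCF.
#' @return a `dosage_panel`.
#' @export
read_dosage_vcf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop_arg("no #CHROM header line in ", path)
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  if (!length(body))
    return(dosage_panel(matrix(numeric(), 0, length(samples),
                               dimnames = list(NULL, samples)),
                        data.frame(snp = character(), chrom = character(),
                                   pos = integer(), minor = character(),
                                   major = character())))
  parts <- strsplit(body, "\t", fixed = TRUE)
  get <- function(i) vapply(parts, `[[`, "", i)
  fmt <- strsplit(get(9), ":", fixed = TRUE)
  d <- matrix(NA_real_, length(body), length(samples))
  for (r in seq_along(parts)) {
    ds_i <- match("DS", fmt[[r]])
    gt_i <- match("GT", fmt[[r]])
    fields <- strsplit(parts[[r]][-(1:9)], ":", fixed = TRUE)
    if (!is.na(ds_i)) {
      d[r, ] <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", ds_i)))
    } else if (!is.na(gt_i)) {
      gt <- vapply(fields, `[[`, "", gt_i)
      alt_count <- function(g) {
        if (grepl("\\.", g)) return(NA_real_)
        sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
      }
      d[r, ] <- vapply(gt, alt_count, numeric(1))
    } else stop_arg("VCF row ", r, " has neither DS nor GT")
  }
  colnames(d) <- samples
  dosage_panel(d, data.frame(snp = get(3), chrom = get(1),
                             pos = as.integer(get(2)),
                             minor = get(5), major = get(4),
                             stringsAsFactors = FALSE))
}

#' Write a dosage panel as a plain-text VCF with a DS FORMAT field
#' @param panel a `dosage_panel`.
#' @param path output path.
#' @export
write_dosage_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Minor allele dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(panel$dosage)),
                     collapse = "\t")), con)
  for (i in seq_len(nrow(panel$info))) {
    ds <- ifelse(is.na(panel$dosage[i, ]), ".",
                 formatC(panel$dosage[i, ], format = "g", digits = 8))
    writeLines(paste(c(panel$info$chrom[i], panel$info$pos[i],
                       panel$info$snp[i], panel$info$major[i],
                       panel$info$minor[i], ".", "PASS", ".", "DS", ds),
                     collapse = "\t"), con)
  }
  invisible(path)
}
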