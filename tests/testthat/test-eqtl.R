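test_that("trans_eqtl: planted shift detected, monomorphic column missing, calibration", {
  withr::with_seed(1, {
    n <- 300
    g <- rbinom(n, 2, 0.4)
    expr <- rbind(shifted = 2 * g + rnorm(n),   # 2 SD per allele
                  flat = rnorm(n))
    colnames(expr) <- paste0("S", 1:n)
    panel <- make_panel(rbind(snp1 = g, mono = rep(1, n)))
    eq <- trans_eqtl(expr, panel)
    expect_lt(eq["shifted", "snp1"], 1e-6)
    expect_true(all(is.na(eq[, "mono"])))
    expect_equal(eq["flat", "snp1"],
                 kruskal.test(expr["flat", ], factor(g))$p.value)
  })
  expect_error(
    trans_eqtl(matrix(1, 1, 2, dimnames = list("g", c("a", "b"))),
               make_panel(matrix(1, 1, 3))),
    "no shared samples")
})

test_that("trans_eqtl p-values are calibrated under the null", {
  withr::with_seed(2, {
    n <- 150
    expr <- matrix(rnorm(40 * n), 40, n,
                   dimnames = list(paste0("g", 1:40), paste0("S", 1:n)))
    d <- t(vapply(runif(5, 0.2, 0.5), function(f) rbinom(n, 2, f), numeric(n)))
    eq <- trans_eqtl(expr, make_panel(d))
    p <- as.vector(eq)
    p <- p[!is.na(p)]
    expect_gt(ks.test(p, "punif")$p.value, 0.01)
  })
})

test_that("eqtl_significance reproduces the Bonferroni thresholds", {
  eq <- matrix(c(1e-8, 0.01, 0.5, NA), 2, 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  class(eq) <- c("eqtl_matrix", class(eq))
  sig <- eqtl_significance(eq, m_eff = 45, n_genes = 1348)
  expect_equal(signif(sig$per_snp_threshold, 2), 1.1e-3)
  expect_equal(signif(sig$study_wide_threshold, 2), 8.2e-7)
  expect_true(sig$hits_per_snp["g1", "s1"])
  expect_false(sig$hits_per_snp["g2", "s1"])
  expect_false(sig$hits_study_wide["g2", "s2"])  # NA never hits
  both <- eqtl_significance(eq, 1, 1)
  expect_equal(both$per_snp_threshold, 0.05)
  expect_equal(both$study_wide_threshold, 0.05)
})

test_that("min_p_per_gene equals a brute-force row scan and drops empty rows", {
  expect_equal(unname(min_p_per_gene(
    matrix(c(0.2, 0.01, 0.5), 1, dimnames = list("g", NULL)))), 0.01)
  withr::with_seed(3, {
    m <- matrix(runif(60), 10, 6,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
    m[2, c(1, 4)] <- NA
    got <- min_p_per_gene(m)
    want <- vapply(seq_len(10),
                   function(i) min(m[i, ], na.rm = TRUE), numeric(1))
    expect_equal(unname(got), want)
    m[5, ] <- NA
    expect_warning(got2 <- min_p_per_gene(m), "dropped")
    expect_false("g5" %in% names(got2))
  })
})

test_that("binary distance: identities, hand count, disjoint supports, invariances", {
  s <- rbind(g1 = c(1, 0, 1), g2 = c(1, 1, 0), g3 = c(1, 0, 1),
             g4 = c(0, 1, 0), g5 = c(0, 0, 0), g6 = c(0, 0, 0))
  expect_warning(d <- binary_distance(s), "never-salient")
  dm <- as.matrix(d)
  expect_equal(dm["g1", "g3"], 0)            # identical rows
  expect_equal(dm["g1", "g2"], 2 / 3)        # a=1, b=1, c=1
  expect_equal(dm["g1", "g4"], 1)            # disjoint supports
  expect_equal(dm["g5", "g6"], 0)            # never salient: defined 0
  expect_true(all(dm >= 0 & dm <= 1))
  expect_true(all(diag(dm) == 0))
  expect_equal(dm, t(dm))
  # invariant to sample reordering
  expect_equal(as.matrix(suppressWarnings(binary_distance(s[, c(3, 1, 2)]))), dm)
})

test_that("ward clustering: 2-gene height, k-cut counts, planted partition, relabeling", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  h2 <- ward_cluster(d2)
  expect_equal(h2$height, 0.4)  # single merge at the input distance
  expect_error(ward_cluster(matrix(0, 1, 1)), ">= 2 genes")

  withr::with_seed(4, {
    s <- rbind(
      matrix(rbinom(20 * 12, 1, c(0.9, 0.9, 0.9, 0.9, 0.05, 0.05, 0.05,
                                  0.05, 0.05, 0.05, 0.05, 0.05)),
             20, 12, byrow = TRUE),
      matrix(rbinom(20 * 12, 1, c(0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05,
                                  0.05, 0.9, 0.9, 0.9, 0.9)),
             20, 12, byrow = TRUE))
    rownames(s) <- paste0("g", 1:40)
    hc <- ward_cluster(suppressWarnings(binary_distance(s)))
    for (k in 2:10) expect_equal(length(unique(cutree(hc, k))), k)
    cut2 <- cutree(hc, 2)
    expect_equal(length(unique(cut2[1:20])), 1)
    expect_equal(length(unique(cut2[21:40])), 1)
    # label permutation changes nothing but the names
    perm <- sample(40)
    hc_p <- ward_cluster(suppressWarnings(binary_distance(s[perm, ])))
    cut_p <- cutree(hc_p, 2)[rownames(s)]
    expect_equal(length(unique(paste(cut2, cut_p))), 2)
  })
})

test_that("decomposition stopping rule follows the gradual height-reduction contract", {
  # 1-D geometry engineered so cuts emerge in the order {AB|CD}, {A|B}, {C|D};
  # the enriched branch D only separates at k = 4. Low-p genes in D are
  # balanced by high-p genes in C so earlier cuts stay non-significant.
  pts <- c(seq(0, 0.5, length.out = 10), seq(1.5, 2.0, length.out = 10),
           seq(10, 10.5, length.out = 10), seq(10.8, 11.1, length.out = 6))
  names(pts) <- paste0("g", seq_along(pts))
  hc <- ward_cluster(dist(pts))
  minp <- c(seq(0.30, 0.70, length.out = 10),
            seq(0.35, 0.75, length.out = 10),
            seq(0.40, 0.80, length.out = 10),
            seq(0.15, 0.20, length.out = 6))
  names(minp) <- names(pts)
  dec <- decompose_subclusters(hc, minp, alpha = 0.05, k_max = 8)
  expect_true(dec$decomposed)
  expect_equal(dec$k, 4)
  expect_true(all(dec$p_by_k[c("2", "3")] >= 0.05))
  expect_lt(dec$p_by_k["4"], 0.05)
  target <- select_target_subcluster(dec)
  expect_setequal(target, paste0("g", 31:36))
  expect_equal(min(dec$medians), median(minp[31:36]))

  # monotone in alpha: larger alpha stops at the same or smaller k
  dec_hi <- decompose_subclusters(hc, minp, alpha = 0.2, k_max = 8)
  expect_lte(dec_hi$k, dec$k)
})

test_that("decomposition edge cases: identical min-p, k_max exhausted, errors", {
  pts <- setNames(c(1:6), paste0("g", 1:6))
  hc <- ward_cluster(dist(pts))
  same <- setNames(rep(0.5, 6), names(pts))
  dec <- decompose_subclusters(hc, same, k_max = 5)
  expect_false(dec$decomposed)
  expect_true(all(dec$p_by_k == 1, na.rm = TRUE))
  expect_error(select_target_subcluster(dec), "no decomposition")
  expect_error(decompose_subclusters(hc, same, k_max = 1), "k_max")
})

test_that("target sub-cluster tie-breaks deterministically", {
  dec <- structure(list(decomposed = TRUE, k = 3,
                        labels = setNames(c(1, 1, 2, 3, 3, 3),
                                          paste0("g", 1:6)),
                        medians = setNames(c(0.5, 0.2, 0.2), 1:3),
                        sizes = c(2L, 1L, 3L),
                        p_by_k = c("2" = 0.5, "3" = 0.01)),
                   class = "cluster_decomposition")
  expect_equal(select_target_subcluster(dec), "g3")  # tie -> smaller cluster
})

test_that("hypergeometric enrichment matches brute-force tail enumeration", {
  bg <- paste0("g", 1:40)
  gs <- paste0("g", 1:10)
  ann <- list(hit = paste0("g", c(1:12)),          # strong overlap
              miss = paste0("g", 30:40),           # disjoint from gene set
              tiny = paste0("g", 1:3))             # below min_overlap
  res <- hypergeometric_enrichment(gs, ann, bg, min_overlap = 5)
  expect_false("tiny" %in% res$term)
  expect_false("miss" %in% res$term)               # 0 overlap < min_overlap
  # brute-force tail: P(overlap >= 10) summing hypergeometric pmf
  k_obs <- 10; K <- 12; N <- 40; n <- 10
  brute <- sum(vapply(k_obs:min(K, n), function(k)
    choose(K, k) * choose(N - K, n - k) / choose(N, n), numeric(1)))
  expect_equal(res$p[res$term == "hit"], brute, tolerance = 1e-12)

  res0 <- hypergeometric_enrichment(gs, ann, bg, min_overlap = 0)
  expect_equal(res0$p[res0$term == "miss"], 1)  # disjoint term
  expect_equal(res0$p_bonferroni, pmin(1, res0$p * nrow(res0)))
  expect_error(hypergeometric_enrichment(gs, ann, character()), "empty")
  expect_error(hypergeometric_enrichment("absent", ann, bg), "subset")
})

test_that("newick export parses back with matching leaves", {
  pts <- setNames(c(1, 2, 5, 9), c("a", "b", "c", "d"))
  hc <- ward_cluster(dist(pts))
  p <- tempfile(fileext = ".nwk")
  write_newick(hc, p)
  tree <- ape::read.tree(p)
  expect_setequal(tree$tip.label, names(pts))
})
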