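#' Simulation configuration
#'
#' Defaults describe a desk-scale but structurally realistic world: a
#' hub-heavy bipartite model (a few currency-metabolite hubs touched by most
#' reactions), a few hundred metabolic genes measured in a few hundred
#' samples, 2% salience tails, Hardy-Weinberg genotypes with one planted QTL
#' that shifts the per-sample coherence propensity.
#'
#' @param n_metabolites,n_reactions,n_genes model dimensions.
#' @param currency_hub_count number of planted hub (currency) metabolites.
#' @param mean_metabolites_per_reaction mean metabolites drawn per reaction.
#' @param n_samples number of individuals.
#' @param q_salience salience tail probability.
#' @param coherence_base baseline coherence propensity c0 in `[0, 1]`.
#' @param qtl_effect additive effect of one minor-allele dose on the
#'   coherence propensity (`c0 + 2 * qtl_effect` must stay in `[0, 1]`).
#' @param qtl_maf minor allele frequency of the causal SNP, in (0, 0.5].
#' @param n_null_snps number of null SNPs besides the causal one.
#' @param c_noise sd of the Gaussian noise on the coherence propensity.
#' @param module_affinity probability scale tying genes of a sample's
#'   coherent module to that sample: a module gene is salient in sample i
#'   with probability `module_affinity * c_i` (quota permitting), so the
#'   expected amount of network-coherent salience scales absolutely with the
#'   coherence propensity.
#' @param currency_fraction currency-removal fraction used when a fixture is
#'   built end to end.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_metabolites = 200L, n_reactions = 150L,
                       n_genes = 200L, currency_hub_count = 10L,
                       mean_metabolites_per_reaction = 2,
                       n_samples = 300L, q_salience = 0.02,
                       coherence_base = 0.25, qtl_effect = 0.15,
                       qtl_maf = 0.3, n_null_snps = 49L,
                       c_noise = 0.10, module_affinity = 0.6,
                       currency_fraction = 0.05) {
  cfg <- list(n_metabolites = as.integer(n_metabolites),
              n_reactions = as.integer(n_reactions),
              n_genes = as.integer(n_genes),
              currency_hub_count = as.integer(currency_hub_count),
              mean_metabolites_per_reaction = mean_metabolites_per_reaction,
              n_samples = as.integer(n_samples),
              q_salience = q_salience,
              coherence_base = coherence_base,
              qtl_effect = qtl_effect, qtl_maf = qtl_maf,
              n_null_snps = as.integer(n_null_snps),
              c_noise = c_noise, module_affinity = module_affinity,
              currency_fraction = currency_fraction)
  with(cfg, {
    stopifnot(n_metabolites > 0, n_reactions >= 0, n_genes > 0,
              currency_hub_count >= 0, n_samples > 0,
              q_salience > 0, q_salience < 0.5,
              qtl_maf > 0, qtl_maf <= 0.5, n_null_snps >= 0,
              module_affinity >= 0, module_affinity <= 1)
    if (currency_hub_count > n_metabolites)
      stop_arg("more hub metabolites than metabolites")
    if (coherence_base + 2 * qtl_effect > 1 || coherence_base < 0)
      stop_arg("coherence_base + 2 * qtl_effect must lie in [0, 1]")
  })
  structure(cfg, class = "sim_config")
}

#' Simulate a hub-heavy bipartite metabolic model
#'
#' Each reaction draws `1 + Pois(mean - 1)` metabolites; with probability 0.9
#' one of them is a uniformly chosen planted hub, the rest follow mild
#' preferential attachment among non-hub metabolites. Hubs therefore acquire
#' degree far above the non-hub median, emulating currency metabolites. Every
#' metabolite ends up incident to at least one reaction, and every gene is
#' assigned to at least one reaction (round-robin) plus occasional extra
#' associations (isoenzymes / promiscuous genes).
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return a `metabolic_model`; planted hub IDs in `attr(, "hubs")`.
#' @export
simulate_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  mets <- sprintf("M%03d", seq_len(cfg$n_metabolites))
  hubs <- mets[seq_len(cfg$currency_hub_count)]
  rxns <- sprintf("R%03d", seq_len(cfg$n_reactions))
  genes <- sprintf("G%03d", seq_len(cfg$n_genes))
  if (cfg$n_reactions == 0L)
    return(structure(metabolic_model(metabolites = mets), hubs = hubs))
  model <- with_seed(seed, {
    nonhub <- setdiff(mets, hubs)
    deg <- stats::setNames(rep(0, length(nonhub)), nonhub)
    inc <- vector("list", length(rxns))
    for (r in seq_along(rxns)) {
      n_met <- 1L + stats::rpois(1, max(0, cfg$mean_metabolites_per_reaction - 1))
      picked <- character()
      if (length(hubs) && stats::runif(1) < 0.9) {
        picked <- sample(hubs, 1L)
        n_met <- n_met - 1L
      }
      if (n_met > 0 && length(nonhub)) {
        n_met <- min(n_met, length(nonhub))
        extra <- sample(nonhub, n_met, prob = deg + 3)  # mild rich-get-richer
        deg[extra] <- deg[extra] + 1
        picked <- c(picked, extra)
      }
      if (length(picked))
        inc[[r]] <- data.frame(reaction = rxns[r], metabolite = picked)
    }
    # every metabolite participates somewhere (and the triple-TSV format,
    # which only records incidence, can then represent the model losslessly)
    unused <- setdiff(mets, unlist(lapply(inc, `[[`, "metabolite")))
    if (length(unused))
      inc[[length(inc) + 1L]] <-
        data.frame(reaction = sample(rxns, length(unused), replace = TRUE),
                   metabolite = unused)
    gm <- data.frame(reaction = rxns[(seq_along(genes) - 1L) %% length(rxns) + 1L],
                     gene = genes)
    extra_gene <- stats::runif(length(genes)) < 0.3
    if (any(extra_gene))
      gm <- rbind(gm, data.frame(reaction = sample(rxns, sum(extra_gene),
                                                   replace = TRUE),
                                 gene = genes[extra_gene]))
    metabolic_model(metabolites = mets, reactions = rxns,
                    incidence = do.call(rbind, inc), gene_map = gm,
                    warn_orphans = FALSE)
  })
  attr(model, "hubs") <- hubs
  model
}

#' Simulate Hardy-Weinberg dosage genotypes with one causal SNP
#'
#' `n_null_snps + 1` biallelic SNPs on one synthetic chromosome, positions
#' 5 kb apart. Null SNP MAFs are drawn uniformly from `[0.1, 0.5]` (safely
#' inside default QC bounds); the causal SNP sits mid-panel at `qtl_maf`.
#' Genotypes are independent `Binomial(2, maf)` hard calls, i.e. exact HWE
#' sampling.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return list with `panel` (a `dosage_panel`) and `causal` (SNP ID).
#' @export
simulate_genotypes <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  n_snp <- cfg$n_null_snps + 1L
  snps <- sprintf("rs%04d", seq_len(n_snp))
  causal <- snps[(n_snp + 1L) %/% 2L]
  samples <- sprintf("S%04d", seq_len(cfg$n_samples))
  sim <- with_seed(seed, {
    maf <- stats::runif(n_snp, 0.1, 0.5)
    maf[snps == causal] <- cfg$qtl_maf
    d <- vapply(maf, function(f) stats::rbinom(cfg$n_samples, 2L, f),
                numeric(cfg$n_samples))
    list(maf = maf, dosage = t(d))
  })
  dimnames(sim$dosage) <- list(snps, samples)
  info <- data.frame(snp = snps, chrom = "1",
                     pos = 100000L + 5000L * (seq_len(n_snp) - 1L),
                     minor = "A", major = "G", stringsAsFactors = FALSE)
  list(panel = dosage_panel(sim$dosage, info), causal = causal)
}

# Connected gene module grown by breadth-first expansion from a random seed
# node; tops up from unvisited nodes if the component is exhausted.
grow_module <- function(adj_list, size) {
  nodes <- names(adj_list)
  visited <- character()
  frontier <- sample(nodes, 1L)
  while (length(visited) < size) {
    if (!length(frontier)) {
      rest <- setdiff(nodes, visited)
      if (!length(rest)) break
      frontier <- sample(rest, 1L)
    }
    nxt <- frontier[1L]; frontier <- frontier[-1L]
    if (nxt %in% visited) next
    visited <- c(visited, nxt)
    nb <- setdiff(adj_list[[nxt]], c(visited, frontier))
    if (length(nb)) frontier <- c(frontier, sample(nb))
  }
  visited
}

#' Simulate expression with planted, coherence-structured salience
#'
#' Per sample, a coherence propensity `c_i = clamp(c0 + beta * dosage_i +
#' noise, 0, 1)` is drawn from the causal SNP, and a connected gene module is
#' grown on the network by breadth-first expansion. Salience is then planted
#' gene-major so the quantile dichotomization round-trips exactly: every gene
#' receives exactly `floor((n-1)q + 1)` salient samples per tail. Samples
#' whose module contains the gene are included with absolute probability
#' `module_affinity * c_i` (subsampled if they exceed the quota); remaining
#' quota slots are filled uniformly. Coherent samples thus accumulate
#' network-adjacent salient genes at a rate proportional to their own c_i.
#' Continuous values are synthesized on a clamped standard-normal background
#' with the planted tails injected beyond it, so `dichotomize(values, q)`
#' recovers the planted matrix exactly.
#'
#' @param network a `gene_network` (nonempty) over the genes to simulate.
#' @param panel a `dosage_panel` containing the causal SNP.
#' @param causal_snp SNP ID driving coherence.
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return list with `expr` (genes x samples matrix), `salience` (the planted
#'   binary matrix) and `truth` (`simulated_truth`: per-sample `c`,
#'   `causal_snp`, per-sample `modules`).
#' @export
simulate_expression <- function(network, panel, causal_snp, cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"), length(network$nodes) > 0)
  ci <- match(causal_snp, panel$info$snp)
  if (is.na(ci)) stop_arg("causal SNP not in panel: ", causal_snp)
  genes <- network$nodes
  samples <- colnames(panel$dosage)
  n <- length(samples)
  dose <- panel$dosage[ci, ]
  m_tail <- salient_count_per_tail(n, cfg$q_salience)
  if (2L * m_tail > n)
    stop_arg("salience budget exceeds sample count; lower q or raise n")
  adj_list <- lapply(stats::setNames(genes, genes), function(g) {
    e <- network$edges
    c(e[e[, 1] == g, 2], e[e[, 2] == g, 1])
  })
  module_size <- max(3L, round(length(genes) * 2 * m_tail / n))
  if (module_size > length(genes)) {
    warning("module size capped at network size", call. = FALSE)
    module_size <- length(genes)
  }
  out <- with_seed(seed, {
    c_i <- pmin(1, pmax(0, cfg$coherence_base + cfg$qtl_effect * dose +
                          stats::rnorm(n, 0, cfg$c_noise)))
    modules <- lapply(seq_len(n), function(i) grow_module(adj_list, module_size))
    in_module <- matrix(FALSE, length(genes), n,
                        dimnames = list(genes, samples))
    for (i in seq_len(n)) in_module[modules[[i]], i] <- TRUE
    sal <- matrix(0L, length(genes), n, dimnames = list(genes, samples))
    expr <- matrix(pmin(6, pmax(-6, stats::rnorm(length(genes) * n))),
                   length(genes), n, dimnames = list(genes, samples))
    for (g in seq_along(genes)) {
      quota <- 2L * m_tail
      mod_idx <- which(in_module[g, ])
      keep <- mod_idx[stats::runif(length(mod_idx)) <
                        cfg$module_affinity * c_i[mod_idx]]
      if (length(keep) > quota) keep <- sample(keep, quota)
      fill <- setdiff(seq_len(n), keep)
      chosen <- c(keep, sample(fill, quota - length(keep)))
      chosen <- sample(chosen)  # random low/high split
      sal[g, chosen] <- 1L
      lo <- chosen[seq_len(m_tail)]
      hi <- chosen[(m_tail + 1L):(2L * m_tail)]
      expr[g, lo] <- -9 - stats::runif(m_tail)
      expr[g, hi] <- 9 + stats::runif(m_tail)
    }
    # snap to 6-decimal text values: exact round-trip through the TSV writer
    expr[] <- as.numeric(sprintf("%.6f", expr))
    list(c_i = c_i, modules = modules, sal = sal, expr = expr)
  })
  truth <- structure(list(c = stats::setNames(out$c_i, samples),
                          causal_snp = causal_snp,
                          modules = stats::setNames(out$modules, samples)),
                     class = "simulated_truth")
  class(out$sal) <- c("salience_matrix", class(out$sal))
  list(expr = out$expr, salience = out$sal, truth = truth)
}

#' Write a complete synthetic dataset bundle to disk
#'
#' Simulates model, genotypes and expression under one master seed and writes
#' `model.tsv` (triple TSV), `expression.tsv`, `genotypes.vcf`,
#' `covariates.tsv` (sample, sex, population) and `truth.json`. All files
#' parse back bit-identically through the package readers.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @param seed master integer seed.
#' @return named character vector of file paths, invisibly.
#' @export
make_fixture <- function(cfg, dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- simulate_model(cfg, derive_seed(seed, "model"))
  geno <- simulate_genotypes(cfg, derive_seed(seed, "genotypes"))
  pruned <- remove_currency_metabolites(model, cfg$currency_fraction)$model
  network <- project_gene_network(pruned)
  sim <- simulate_expression(network, geno$panel, geno$causal, cfg,
                             derive_seed(seed, "expression"))
  covars <- with_seed(derive_seed(seed, "covariates"), {
    data.frame(sample = colnames(geno$panel$dosage),
               sex = sample(c("F", "M"), cfg$n_samples, replace = TRUE),
               population = sample(c("POP1", "POP2"), cfg$n_samples,
                                   replace = TRUE),
               stringsAsFactors = FALSE)
  })
  paths <- c(model = file.path(dir, "model.tsv"),
             expression = file.path(dir, "expression.tsv"),
             genotypes = file.path(dir, "genotypes.vcf"),
             covariates = file.path(dir, "covariates.tsv"),
             truth = file.path(dir, "truth.json"))
  write_metabolic_model(model, paths["model"])
  write_expression_tsv(sim$expr, paths["expression"])
  write_dosage_vcf(geno$panel, paths["genotypes"])
  write_tsv(covars, paths["covariates"])
  jsonlite::write_json(
    list(causal_snp = geno$causal,
         c = as.list(sim$truth$c),
         config = unclass(cfg), seed = seed),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
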