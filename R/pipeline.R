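#' Default pipeline parameters
#'
#' All analysis thresholds in one place, with the conventional defaults:
#' 2% salience quantile, 5% currency metabolites, 2000 null draws, call rate
#' 0.99, MAF 0.05, 5 minor homozygotes, HWE p 0.001, genome-wide 5e-8,
#' nominal alpha 0.05.
#' @return named list of parameters.
#' @export
pipeline_defaults <- function() {
  list(currency_fraction = 0.05, q_salience = 0.02, n_draws = 2000L,
       min_call_rate = 0.99, min_maf = 0.05, min_minor_homs = 5L,
       min_hwe_p = 0.001, genomewide = 5e-8, alpha = 0.05, k_max = 10L)
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_arg("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop_arg("config must be a list or a JSON file path")
  if (is.null(config$seed)) stop_arg("config requires a 'seed'")
  if (is.null(config$simulate) && is.null(config$inputs))
    stop_arg("config requires either a 'simulate' block or an 'inputs' block")
  if (!is.null(config$inputs)) {
    needed <- c("model", "expression", "genotypes")
    miss <- needed[!vapply(config$inputs[needed], function(p)
      !is.null(p) && file.exists(p), logical(1))]
    if (length(miss)) stop_arg("missing input file(s): ",
                               paste(miss, collapse = ", "))
  }
  params <- utils::modifyList(pipeline_defaults(),
                              as.list(config$params %||% list()))
  stages <- utils::modifyList(
    list(qc = TRUE, gwas = TRUE, conditional = FALSE, eqtl = TRUE,
         decomposition = TRUE),
    as.list(config$stages %||% list()))
  list(seed = as.integer(config$seed), simulate = config$simulate,
       inputs = config$inputs, params = params, stages = stages)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full coherence pipeline
#'
#' Executes, in order: model parsing (or simulation), currency-metabolite
#' removal and gene-centric projection, dichotomization, per-sample MC,
#' genotype QC, GWAS (optionally a conditional scan on the top SNP),
#' trans-eQTL, and the Ward sub-cluster decomposition. Each stage's output is
#' written as TSV/JSON under `out_dir` together with a run manifest (config
#' snapshot, master seed, per-stage derived seeds, input/output checksums,
#' timestamps). The pipeline output is a pure function of (inputs, config,
#' seed).
#'
#' @param config path to a JSON config file, or an equivalent list. Required:
#'   `seed`; one of `simulate` (a [sim_config()]-shaped block) or `inputs`
#'   (paths `model`, `expression`, `genotypes` (VCF or dosage TSV),
#'   optionally `covariates`). Optional: `params` (overrides of
#'   [pipeline_defaults()]), `stages` (logical gates `qc`, `gwas`,
#'   `conditional`, `eqtl`, `decomposition`).
#' @param out_dir output directory.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- cfg$params
  seed <- cfg$seed
  stages_run <- character()
  t0 <- Sys.time()
  stage <- function(name) stages_run <<- c(stages_run, name)

  input_checksums <- list()
  if (!is.null(cfg$simulate)) {
    stage("simulate")
    sim_cfg <- do.call(sim_config, cfg$simulate[names(cfg$simulate) %in%
                                                  names(formals(sim_config))])
    model <- simulate_model(sim_cfg, derive_seed(seed, "model"))
    geno <- simulate_genotypes(sim_cfg, derive_seed(seed, "genotypes"))
    panel <- geno$panel
    pruned0 <- remove_currency_metabolites(model, p$currency_fraction)$model
    net0 <- project_gene_network(pruned0)
    sim <- simulate_expression(net0, panel, geno$causal, sim_cfg,
                               derive_seed(seed, "expression"))
    expr <- sim$expr
    covars <- NULL
  } else {
    stage("load_inputs")
    model <- read_metabolic_model(cfg$inputs$model)
    expr <- read_expression_tsv(cfg$inputs$expression)
    panel <- if (grepl("\\.vcf$", cfg$inputs$genotypes))
      read_dosage_vcf(cfg$inputs$genotypes) else
        read_dosage_tsv(cfg$inputs$genotypes)
    covars <- if (!is.null(cfg$inputs$covariates))
      read_tsv(cfg$inputs$covariates) else NULL
    input_checksums <- as.list(tools::md5sum(unlist(cfg$inputs)))
  }

  stage("network")
  pruned <- remove_currency_metabolites(model, p$currency_fraction)
  network <- restrict_to_measured(project_gene_network(pruned$model),
                                  rownames(expr))
  write_gene_network(network, file.path(out_dir, "network.tsv"))

  stage("salience")
  sal <- dichotomize(expr, p$q_salience)

  stage("mc")
  mc <- mc_profile(network, sal, n_draws = p$n_draws,
                   seed = derive_seed(seed, "mc"))
  write_mc_profile(mc, file.path(out_dir, "mc.tsv"))

  gwas <- conditional <- eqtl <- decomp <- NULL
  if (isTRUE(cfg$stages$qc)) {
    stage("qc")
    qc <- snp_qc(panel, qc_criteria(p$min_call_rate, p$min_maf,
                                    p$min_minor_homs, p$min_hwe_p))
    write_tsv(qc$report, file.path(out_dir, "qc_report.tsv"))
    panel <- qc$panel
  }
  if (isTRUE(cfg$stages$gwas)) {
    stage("gwas")
    gwas <- gwas_scan(mc, panel, covars)
    write_tsv(gwas, file.path(out_dir, "gwas.tsv"))
    if (isTRUE(cfg$stages$conditional) && any(!is.na(gwas$p))) {
      stage("conditional")
      top <- gwas$snp[which.min(gwas$p)]
      conditional <- conditional_scan(mc, panel, covars, top_snp = top)
      write_tsv(conditional, file.path(out_dir, "conditional.tsv"))
    }
  }
  if (isTRUE(cfg$stages$eqtl)) {
    stage("eqtl")
    eqtl <- trans_eqtl(expr, panel)
    write_expression_tsv(unclass(eqtl), file.path(out_dir, "eqtl.tsv"))
    if (isTRUE(cfg$stages$decomposition)) {
      stage("decomposition")
      minp <- min_p_per_gene(eqtl)
      dendro <- ward_cluster(suppressWarnings(binary_distance(sal)))
      decomp <- decompose_subclusters(dendro, minp, alpha = p$alpha,
                                      k_max = p$k_max)
      write_newick(dendro, file.path(out_dir, "dendrogram.nwk"))
      if (decomp$decomposed) {
        write_tsv(data.frame(gene = names(decomp$labels),
                             subcluster = decomp$labels),
                  file.path(out_dir, "subclusters.tsv"))
        jsonlite::write_json(
          list(k = decomp$k, medians = as.list(decomp$medians),
               sizes = decomp$sizes, p_by_k = as.list(decomp$p_by_k),
               target = select_target_subcluster(decomp)),
          file.path(out_dir, "decomposition.json"), auto_unbox = TRUE)
      } else {
        jsonlite::write_json(list(k = NULL, p_by_k = as.list(decomp$p_by_k)),
                             file.path(out_dir, "decomposition.json"),
                             auto_unbox = TRUE)
      }
    }
  }

  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    config = list(params = p, stages = cfg$stages,
                  simulate = cfg$simulate, inputs = cfg$inputs),
    master_seed = seed,
    stage_seeds = stats::setNames(
      lapply(c("model", "genotypes", "expression", "mc"),
             function(s) derive_seed(seed, s)),
      c("model", "genotypes", "expression", "mc")),
    stages = stages_run,
    input_checksums = input_checksums,
    output_checksums = as.list(tools::md5sum(outputs)),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("mcnet")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(network = network, salience = sal, mc = mc, gwas = gwas,
                 conditional = conditional, eqtl = eqtl,
                 decomposition = decomp, manifest = manifest))
}
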