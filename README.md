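# mcnet — metabolic network coherence of transcriptomes

`mcnet` turns a whole transcriptome into a single quantitative,
network-contextualized phenotype — its **metabolic network coherence (MC)** —
and provides the downstream genetic machinery to treat that phenotype as a
GWAS trait: genotype QC, dosage linear models, conditional scans, trans-eQTL
rank tests, and a significance-driven decomposition of the metabolic genes
into sub-clusters. It is aimed at statistical geneticists and systems
biologists who want to ask whether *how coherently* an individual's metabolic
genes are co-regulated — not the expression of any single gene — is under
genetic control.

## The statistic

Given a genome-scale metabolic model (a bipartite graph of metabolites and
reactions plus reaction–gene associations), `mcnet`:

1. removes the top 5% highest-degree **currency metabolites** (ATP-like hubs
   that would otherwise create spurious shortcuts), then projects the model
   onto genes: genes *g* and *h* are adjacent iff reactions associated with
   them share a metabolite;
2. dichotomizes each gene's expression across samples into *normal* vs
   *salient* (values in the gene-specific upper or lower 2% tail — both tails,
   so concordant and discordant co-regulation both count);
3. maps each sample's salient gene set onto the network and computes the
   **connectivity** of the induced subnetwork: the fraction of its nodes with
   at least one neighbour inside the set;
4. standardizes that connectivity against a simulated null of 2000 random
   gene sets of the same size drawn from the measured network:

   MC_i = (conn(S_i) − mean(conn(R_k))) / sd(conn(R_k)),  |R_k| = |S_i|.

High MC means the sample's extreme expression concentrates on
metabolically adjacent genes — the cell is responding coherently to metabolic
demand; low MC means the extremes scatter over the network.

MC is then regressed on minor-allele dosage genotypes (one SNP at a time,
covariate-adjusted OLS) with the conventional 5×10⁻⁸ genome-wide threshold,
and regional follow-up corrected by the Li–Ji eigenvalue-based LD-effective
test count (0.05 / m_eff).

## Worked example (synthetic data, fully reproducible)

Everything below runs offline: the `synthetic data` module generates a
hub-heavy metabolic model, HWE dosage genotypes with one planted coherence
QTL, and expression whose planted salience dichotomizes back exactly.

```r
library(mcnet)
cfg   <- sim_config(n_samples = 300)        # 200 genes, 50 SNPs, planted QTL
model <- simulate_model(cfg, seed = 1)
geno  <- simulate_genotypes(cfg, seed = 2)
pruned <- remove_currency_metabolites(model, 0.05)
head(pruned$report$removed, 3)
#>   metabolite degree
#> 1       M007     21
#> 2       M005     17
#> 3       M001     16
net <- project_gene_network(pruned$model)
net
#> gene_network: 200 nodes, 414 edges
sim  <- simulate_expression(net, geno$panel, geno$causal, cfg, seed = 3)
prof <- mc_profile(net, sim$salience, n_draws = 2000, seed = 4)
summary(prof$mc)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#> -1.2946 -0.5790  0.4523  0.4869  1.3023  4.4189
res <- gwas_scan(prof, snp_qc(geno$panel)$panel)
head(res[order(res$p), c("snp", "beta", "se", "p")], 3)
#>       snp   beta     se        p
#> 25 rs0025  0.415 0.1015 5.59e-05
#> 41 rs0041 -0.274 0.0961 4.65e-03
#> 9  rs0009 -0.279 0.1036 7.44e-03
geno$causal
#> [1] "rs0025"
```

The planted QTL (`rs0025`) tops the scan: each copy of its minor allele adds
≈0.4 MC standard-normal units. At the calibrated default effect
(dosage explaining ≈4% of MC variance) and n = 1000, the causal SNP reaches
p < 10⁻⁴ and rank 1 in ≥90% of replicates — that is one of the acceptance
criteria in `tests/testthat/test-acceptance.R`.

The whole pipeline (simulate or load inputs → network → salience → MC → QC →
GWAS → trans-eQTL → Ward sub-cluster decomposition) can also be driven from a
JSON config:

```r
run_pipeline(list(seed = 7,
                  simulate = list(n_samples = 300),
                  stages = list(conditional = TRUE)),
             out_dir = "run1")
```

or from the command line via `Rscript inst/cli/mc.R run --config run.json
--out run1` (subcommands: `compute`, `qc`, `gwas`, `simulate`, `run`).

## Layout

- `R/metabolic-model.R`, `R/gene-network.R` — model parsing (triple TSV /
  SBML subset), currency removal, gene-centric projection.
- `R/salience.R` — count preprocessing, tail-quantile dichotomization.
- `R/coherence.R` — connectivity, permutation null, MC profiles,
  sensitivity sweep.
- `R/genetics.R` — dosage panels (TSV/VCF), HWE, QC, LD r², pruning, PCA,
  LD-effective test count.
- `R/association.R` — GWAS/conditional scans, thresholds, rank tests,
  Manhattan/QQ export.
- `R/eqtl.R` — trans-eQTL KW matrix, binary distance, Ward clustering,
  sub-cluster decomposition, enrichment plumbing.
- `R/simulate.R` — the synthetic-data generator (first-class, tested).
- `R/pipeline.R` — orchestration with manifest/provenance.
- `vignettes/metabolic-network-coherence.Rmd` — the methods vignette.
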