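---
title: "Metabolic network coherence: model, estimator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic network coherence: model, estimator, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcnet)
```

## The phenotype

Metabolic network coherence (MC) compresses a transcriptome into one number
by asking how much of a sample's *extreme* expression is explicable by
metabolic adjacency. The ingredients are a genome-scale metabolic
reconstruction — formally a bipartite graph of metabolite and reaction nodes
plus reaction-to-gene associations — and a genes × samples expression matrix.

**Gene-centric projection.** Two genes are connected iff reactions associated
with them share a metabolite. The projection is the union, over metabolites,
of complete graphs on the genes of that metabolite's reactions. Two
consequences follow from this pairwise definition and are exploited by the
code and tests: (i) restricting the network to measured genes equals
projecting the model with unmeasured genes' associations deleted (induction
is exact, no rerouting); and (ii) isoenzymes of a single reaction are
adjacent whenever the reaction touches any metabolite, because a reaction
trivially shares metabolites with itself.

**Currency metabolites.** Ubiquitous carriers (ATP, water, NAD⁺...) touch so
many reactions that they would connect nearly everything. The highest-degree
5% of metabolites (degree = number of distinct incident reactions) are
removed before projection. Ties at the cutoff break by lexicographic
metabolite ID, which makes removal sets nested across fractions and the
edge set monotonically shrinking — a property the tests assert. We count the
cutoff against *all declared* metabolites, including never-used ones; the
alternative (counting only incident metabolites) was rejected because it
makes the removed count depend on bookkeeping rather than biology.

**Salience.** Each gene is dichotomized against its own empirical
distribution across samples: a value is *salient* if it lies at or below the
lower q-quantile or at or above the upper (1−q)-quantile, with q = 0.02 by
default. Both tails are pooled because coherent co-regulation includes both
concordant and discordant extremes. Quantiles use the linear-interpolation
(type 7) convention with inclusive comparisons; this is deterministic and —
the property the suite checks — invariant under any strictly monotone
transform of a gene's values, so log-scaling choices upstream cannot change
salience calls. Constant genes are never salient; genes with fewer than 10
non-missing values are excluded (all-zero) with a warning, because 2% tails
are meaningless at tiny n. For distinct values the rule flags exactly
`floor((n−1)q + 1)` samples per tail.

**The MC score.** For sample *i* with salient set S_i mapped onto the
measured network, the subnetwork connectivity is the fraction of induced
nodes with induced degree ≥ 1. The score is the z-transformation against a
simulated null: 2000 uniform without-replacement draws of |S_i| nodes,

$$\mathrm{MC}_i = \frac{\mathrm{conn}(S_i) - \widehat\mu_{k}}{\widehat\sigma_{k}},
\qquad k = |S_i \cap V|.$$

Missingness is explicit, never coerced to zero: a sample with fewer than two
mapped salient genes gets reason `too_few_mapped`, a degenerate null
(σ = 0, e.g. on a complete graph) gets `degenerate_null`. Downstream
regressions drop these samples.

### Null sampling frame

The null draws come from the *measured, restricted* network's node set, not
the full model gene list. The observed subnetwork can only ever contain
measured genes, so a null drawn from the full model would mix a
missingness effect into the coherence effect. This was a genuinely open
design point (the alternative is defensible for cross-cohort comparability);
the chosen frame matches the sampling space of the observation and is the
package default.

### Null caching and seeds

Within one profile run, null distributions are cached per set size k, each
drawn under a seed derived deterministically from the master seed and k
(`derive_seed(seed, "null_k<k>")`). Samples with equal k share a null, which
is statistically equivalent to redrawing (the null does not depend on the
sample) and makes a 1000-sample profile ~100× cheaper. Identical inputs and
seed give bit-identical profiles; the test suite asserts this.

## Tunable parameters

| parameter | default | units / range | why this value |
|---|---|---|---|
| salience quantile q | 0.02 | tail probability | sensitivity/specificity compromise for calling extremes; swept 0.01–0.03 |
| currency fraction | 0.05 | proportion of metabolites | removes ATP-like hubs; swept 0.03–0.08 |
| null draws | 2000 | draws per set size | σ̂ relative error ≈ 1.6%; doubling changes MC by < 1% |
| QC: call rate | ≥ 0.99 | per SNP | array-era convention |
| QC: MAF | > 0.05 | dosage-estimated | excludes rare SNPs a 457-sample-scale GWAS cannot test |
| QC: minor homozygotes | ≥ 5 | hard calls | stabilizes the dosage slope |
| QC: HWE p | ≥ 0.001 | chi-square 1 df | genotyping-error screen |
| genome-wide α | 5×10⁻⁸ | fixed | convention |
| regional α | 0.05 / m_eff | Li–Ji eigenvalue count | LD-aware Bonferroni |

The sensitivity sweep (`sensitivity_sweep()`) re-runs the full pipeline over
the cross-product of currency fractions and quantiles and returns a long
table; adjacent cells should be (and on synthetic data are) positively
rank-correlated.

## Genetics layer

Dosages encode the minor allele in [0, 2]; panels are re-polarized on load so
the encoding is canonical (MAF = mean dosage / 2 after flipping). Hard-call
criteria (homozygote count, HWE) are skipped, with a report flag, for SNPs
whose dosages are materially fractional (|d − round(d)| > 0.1 in > 10% of
samples), because imputed dosages cannot be HWE-tested exactly. The
LD-effective number of tests uses the Li & Ji (2005) eigenvalue rule
m_eff = Σ [ I(λ_i ≥ 1) + (λ_i − ⌊λ_i⌋) ] on the SNP correlation matrix —
the same family of eigenvalue corrections as the dedicated error calculators,
and recorded as `method = "liji2005"` in the output. GWAS models are
ordinary least squares on complete cases, one SNP at a time, with
reference-coded categorical covariates (reference = lexicographically first
level, for determinism); conditional scans append the top SNP's dosage as a
covariate. Two-group heterogeneity uses the Wilcoxon rank-sum test (exact
enumeration below 50 per group on tie-free data), more groups use
Kruskal–Wallis with tie correction.

## Trans-eQTL and sub-cluster decomposition

Expression of each network gene is tested against each regional SNP's
hard-called genotype classes by Kruskal–Wallis; Bonferroni operates at two
levels (per SNP: α/m_eff; study-wide: α/(m_eff · n_genes)). Genes are then
clustered on their salience profiles with the asymmetric binary
dissimilarity — joint absences carry no information about co-salience, so
they are ignored; a pair of never-salient genes is assigned distance 0 with
a warning — and Ward linkage applied to the raw dissimilarities (the classic
`ward.D` variant). "Gradually lowering the height threshold" is implemented
as cutting the tree into k = 2, 3, … groups at successive merge heights:
the partitions are identical and the iteration is deterministic. At each k a
Kruskal–Wallis test of the gene-wise minimum eQTL p-values across emerging
sub-clusters is run; the decomposition stops at the first k with p < α and
the sub-cluster with the smallest median minimum-p becomes the target (ties:
smaller cluster, then lower label). Only genes with a non-missing minimum p
enter the tests. The procedure is monotone in α (a larger α stops at the
same or smaller k), which the suite asserts.

## What the synthetic generator emulates — and what it does not

The generator exists so that every pipeline stage is testable offline with
known ground truth.

* **Model**: reactions draw metabolites with a 90% chance of including one
  of a handful of planted hubs, plus mild preferential attachment among
  non-hubs — so currency removal has a well-defined correct answer (the
  planted hubs), verified over 100 seeds. Every metabolite is attached to at
  least one reaction so the triple-TSV serialization is lossless.
* **Genotypes**: independent Binomial(2, MAF) hard calls — exact HWE, no LD,
  MAFs in [0.1, 0.5] so default QC passes. One mid-panel SNP is causal.
* **Expression**: each sample receives a coherence propensity
  c_i = clamp(c₀ + β·dosage_i + ε) and a connected module grown by
  breadth-first expansion; each gene then receives *exactly* the
  quantile-implied number of salient samples, taking module samples with
  absolute probability `module_affinity · c_i` and filling the rest
  uniformly. Salient sets are planted first and continuous values
  synthesized afterwards (tails injected beyond a clamped standard-normal
  background), so `dichotomize()` is an exact round-trip oracle and
  salience-placement correctness is decoupled from quantile conventions.

A first implementation allocated module samples by *relative* selection
weights; that construction is competitive — raising every c_i equally only
redistributes salience — and mean MC consequently did not respond to the
planted effect. The absolute-probability allocation fixes this: mean MC now
rises monotonically with β (the "heritability dial"), while exact quotas and
the round trip are preserved.

Defaults are calibrated so that at n = 1000 and MAF 0.3 the causal dosage
explains ≈4% of MC variance (β = 0.15, c₀ = 0.25, noise sd 0.10,
affinity 0.6) — the regime the power properties are stated in.

What the generator does **not** emulate: RNA-seq count noise (negative
binomial, library size), LD structure, population stratification, admixture,
cell-type mixtures, or batch effects. A green planted-QTL test therefore
establishes that the estimator and scan recover a coherence signal of
realistic size under clean sampling — not that the pipeline is robust to
confounding; the PCA and covariate machinery exist precisely because real
data need them.

## Numerical choices and degenerate inputs

* Quantile ties at the salience threshold are inclusive (salient).
* Null sd uses the n−1 denominator (negligible at 2000 draws).
* The singleton gene set has connectivity 0; the empty intersection is an
  undefined value (NA), not 0.
* Monomorphic SNPs: skipped in GWAS with reason, whole column missing in the
  eQTL matrix, HWE p = 1 by convention.
* Rank-deficient designs (dosage collinear with covariates) are flagged, not
  silently dropped from the rank.
* Degenerate correlation entries in the m_eff computation impute to 0 with a
  warning; eigenvalues clipped at 0.
* Expression fixtures are snapped to their 6-decimal text representation so
  TSV round-trips are bit-identical.
* All randomness flows from one master seed through `derive_seed(master,
  tag)` (a fixed string-hash fan-out below 2³¹), so stages never share an
  RNG stream and every artefact is reproducible bit-for-bit.

## Known limitations

* The SBML reader handles a Level-3/FBC subset (species, speciesReferences,
  flattened gene-product references); boolean GPR logic is deliberately
  ignored because the projection uses association only.
* The greedy LD pruner is order-dependent (position-sorted left-to-right),
  like the standard tools it mirrors.
* `ward.D` merge *heights* are linkage-convention-specific; partitions, not
  heights, are the tested contract.
* The decomposition stopping rule inherits the usual caveat of sequential
  testing: the reported KW p at the stopping k is not corrected for the
  path taken to reach it. It is used as the selection device it is, not as
  a calibrated significance statement.
* No kinship/mixed models; samples are assumed unrelated after upstream QC.
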