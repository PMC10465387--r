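# rnamodsig

Clustering and prognostic scoring of RNA-modification regulator biology in
tumour expression cohorts.

## The problem

Writers, readers and erasers of the three major mRNA methylation marks —
N6-methyladenosine (m6A), 5-methylcytosine (m5C) and N1-methyladenosine
(m1A) — are recurrently dysregulated in colon cancer, and their combined
expression pattern carries prognostic information that no single regulator
captures. This package implements, as a tested and reusable R workflow, the
analysis chain that turns a gene × sample expression matrix plus a clinical
table into:

1. **Regulator consensus clusters** — resampled hierarchical clustering of
   samples on a 48-gene regulator panel (23 m6A, 15 m5C, 10 m1A), with the
   number of clusters *k* selected from the change in area under the
   consensus-matrix CDF across k = 2…9;
2. **Cluster-derived prognostic genes** — empirical-Bayes moderated t-tests
   between every pair of clusters, a Venn-overlap rule (adjusted p < 0.001
   in *all* pairwise contrasts), then a univariate Cox screen (p < 0.05) of
   the overlap genes against overall survival;
3. **A per-sample modification score** — PCA of the z-scored prognostic-gene
   matrix, score = PC1 + PC2 with each component sign-oriented so that its
   Cox coefficient on survival is non-negative (high score ⇒ higher
   hazard), then a median split into high/low groups;
4. **Score-stratified downstream analyses** — Kaplan–Meier / log-rank
   survival, tumour mutation burden and mutation summaries, TMB × score
   stratified survival, immunophenoscore / MSI / checkpoint comparisons
   (Wilcoxon, Kruskal–Wallis, chi-square), single-sample gene-set
   enrichment (ssGSEA) of immune signatures with Spearman score–immune
   correlations, hypergeometric over-representation, and the 2^−ΔΔCt
   fold-change rule.

Because real tumour cohorts of this kind live behind controlled-access or
per-platform downloads, the package
ships a **synthetic cohort generator** (`generate_cohort()`) that plants the
exact structure the analysis assumes — log-normal TPM expression, three
regulator-driven sample clusters, prognostic genes with ordered cluster
means, exponential survival with hazard `h0·exp(β·score)` under uniform
censoring, per-gene mutation frequencies, MSI and IPS columns — together
with the ground truth needed for recovery tests.

## Core statistics

- Consensus matrix: `M_ij` = fraction of co-sampled resampling iterations
  (80% of samples, 100 reps) in which samples i and j fell in the same
  hierarchical cluster (average linkage on 1 − Pearson). k is the largest
  value whose relative CDF-area gain `(A_k − A_{k−1})/A_{k−1}` ≥ 0.10.
- Moderated t: `t_g = Δmean_g / (s̃_g √(1/n_a + 1/n_b))` with
  `s̃²_g = (d₀s₀² + d s²_g)/(d₀ + d)`; `(d₀, s₀²)` fitted by method of
  moments on `log s²_g`.
- Modification score: `score_i = PC1_i + PC2_i` after risk orientation.
- Survival: product-limit estimator, Mantel–Haenszel log-rank, and Cox
  partial likelihood with Efron ties (via the `survival` package).

## Worked example

The numbered drivers under `analysis/` run the whole study on the default
synthetic cohort (300 samples, 578 genes) and narrate what they find:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_regulator_clusters.R
Rscript analysis/03_degs_survival.R
Rscript analysis/04_modification_score.R
Rscript analysis/05_downstream.R
```

Output from a run of steps 02–04:

```
chosen k = 3 (delta-areas: 0.471 0.41 0.008 0.003 0.007 0.007 0.007 0.008)
agreement with planted clusters: ARI = 1.000
cluster survival separation: log-rank chi2 = 146.1, p = 1.86e-32
overlap DEGs across 3 contrasts: 31 genes
prognostic after Cox screen (p < 0.05): 30 genes
planted prognostic genes recovered: 30 of 30
score: PC1+PC2 explain 85.7% variance; cut -0.151 (median)
score vs planted risk: Spearman rho = 0.950
high vs low survival: log-rank chi2 = 83.4, p = 6.63e-20
```

Read: the CDF-area elbow lands on the planted k = 3 and the labels match
the truth perfectly (adjusted Rand index 1.0); the overlap + Cox screen
returns the 30 planted prognostic genes; the PC1+PC2 score tracks the
latent risk (ρ = 0.95) and splits survival sharply. Step 05 adds the
mutation-burden contrast (98.7% vs 81.3% mutated samples in high vs low
score groups), the IPS/MSI comparisons and a held-out validation cohort
separated at log-rank p = 3.6e-09 through the frozen score model.

Programmatic use mirrors the drivers:

```r
library(rnamodsig)
cfg <- sim_config(seed = 1)
run <- run_pipeline(pipeline_config(sim = cfg, outdir = "out", seed = 1))
run$results$regulator_clusters$chosen_k  # 3
```

## Layout

- `R/` — the package: IO and unit conversion, regulator catalog, synthetic
  cohort generator, consensus clustering, ssGSEA, moderated DE, survival
  statistics, modification score, downstream analyses, pipeline driver.
- `analysis/` — numbered narrative drivers over the package.
- `tests/testthat/` — unit, property and end-to-end acceptance tests with
  independently coded oracles.
- `vignettes/modification-scoring.Rmd` — the methods vignette: models,
  assumptions, parameter choices, limitations.
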