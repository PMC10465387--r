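---
title: "Methods: regulator consensus clusters and the modification score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulator consensus clusters and the modification score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnamodsig)
```

This vignette is the package's own account of the statistical machinery it
implements: the models, their assumptions, the tunable parameters, and the
places where a design choice was genuinely open and had to be made.

## The analysis in one paragraph

Starting from a gene × sample abundance matrix (FPKM or TPM) and a clinical
table, the workflow (i) consensus-clusters samples on a 48-gene panel of
m6A/m5C/m1A regulators, (ii) extracts genes differentially expressed
between *every* pair of clusters, (iii) keeps those associated with overall
survival in univariate Cox models, (iv) summarises them into one number per
sample — the modification score, the sum of the first two principal
components of the z-scored prognostic-gene matrix, sign-oriented so high
score means high hazard — and (v) stratifies survival, mutation burden and
immunotherapy markers by that score.

## Units and transforms

All within-sample comparisons use TPM: `fpkm_to_tpm()` renormalises every
sample column to sum to 10^6, the defining property of the unit. Clustering,
differential expression and PCA operate on `log2(TPM + 1)`
(`log2_transform()`); the pseudocount of 1 is the ubiquitous default at TPM
scale, and since downstream results depend on the transform it is an
explicit, configurable step rather than something hidden in a reader. Gene
identifiers are matched case-sensitively as given; missing clinical values
propagate as `NA` and are never imputed.

## Consensus clustering

`build_consensus()` follows the resampling recipe: at each of `reps = 100`
iterations it draws `p_item = 0.8` of the samples without replacement,
clusters them hierarchically and records co-membership; the consensus
matrix entry for a pair is the fraction of co-sampled iterations in which
the pair co-clustered. The inner engine is average-linkage clustering on
1 − Pearson correlation between samples — the default of the classical
consensus-clustering framework, and deterministic given a resample. Genes
are z-scored across samples first so high-abundance regulators cannot
dominate the correlation. Pairs never co-sampled (vanishingly rare at these
settings) get consensus 0 with a warning rather than an undefined entry.

The number of clusters is chosen from the empirical CDF of the
upper-triangle consensus values. `cdf_and_area()` integrates the
right-continuous ECDF exactly over [0, 1]; a perfectly crisp matrix (all
entries 1) has area 0, an all-zero matrix area 1. `select_k()` computes the
relative area change `(A_k − A_{k−1})/A_{k−1}` (the area itself at the
smallest k) and picks the largest k whose change is at least `threshold =
0.10`. Analysts usually choose k visually from these curves; a fixed rule
makes the pipeline reproducible, and `force_k` preserves the analyst's
override. On the synthetic cohorts the delta-area sequence collapses by two
orders of magnitude after the planted k, so the 0.10 threshold is not
delicate.

## Moderated differential expression

`moderated_pairwise()` implements the two-group empirical-Bayes moderated
t: pooled per-gene variances `s²_g` on `d = n_a + n_b − 2` df are shrunk to
`s̃²_g = (d₀s₀² + d s²_g)/(d₀ + d)` with the prior `(d₀, s₀²)` estimated by
the classical method-of-moments fit to `log s²_g` (mean and variance of
`log s²` against their digamma/trigamma expectations, with a Newton solve
of the trigamma inverse). When the observed log-variances are no more
dispersed than chi-square sampling noise the prior df is infinite and the
prior scale reduces to the mean sample variance. The pipeline only ever
needs pairwise cluster contrasts, so the full design-matrix machinery of
the established packages is not reimplemented; a test cross-checks the
hyperparameters, t statistics and p-values against `limma` on
heteroscedastic data.

The "overlap DEG" rule is the intersection of the per-contrast DEG sets
(BH-adjusted p < 0.001) across *all* pairwise contrasts. A Venn overlap of
cluster comparisons is ambiguous between pairwise and one-vs-rest
contrasts; pairwise is the natural reading of a three-way Venn diagram and
is the implemented default. BH is used for "adjusted p" throughout, the de
facto default of this ecosystem.

## Survival statistics

Kaplan–Meier estimation, the log-rank test and univariate Cox regression
are delegated to the `survival` package behind thin, contract-checking
wrappers (`km_estimate()`, `logrank_test()`, `cox_univariate()`): constant
covariates short-circuit to β = 0, p = 1 with a flag; monotone-likelihood
warnings mark the fit as non-converged. Ties use Efron's method, the
less-biased standard (Breslow is available for oracle cross-checks, whose
grid-search maximiser assumes tie-free data). The prognostic screen keeps
genes at raw p < 0.05 — a screening convention rather than a derived
quantity, so the threshold is explicit, configurable and logged.

## The modification score

`compute_score()` z-scores the signature genes, runs PCA on the sample ×
gene matrix and sums the first two sample projections. Two choices here are
genuinely open and are resolved as follows:

- **Centering/scaling.** Signature-score constructions of this kind
  standardise gene expression before PCA, and unscaled PCA would be
  dominated by high-variance genes; genes are therefore z-scored.
- **Sign convention.** PCA components are sign-ambiguous across linear
  algebra backends, which would make "high score = poor prognosis"
  irreproducible. Each component is oriented so its univariate Cox
  coefficient on overall survival is ≥ 0; the final score then always has a
  non-negative Cox coefficient on the training cohort.
- **Dichotomisation.** High/low cuts are a convention, not a derived
  quantity. The default is the sample median (ties to the low group); an
  optimal
  log-rank cut over the central 40% of candidate cutpoints is available as
  `cut_method = "logrank_opt"` and is logged with its cutpoint.

`apply_score()` projects a *new* cohort through the frozen loadings and
signs with no refitting; genes are re-z-scored within the new cohort so
that platform-level location/scale differences are absorbed (projecting on
the training means and scales would conflate cohort shifts with risk).
Refitting the PCA within each validation cohort would also be defensible;
the frozen projection is the stricter test of transferability and is the
default.

## Single-sample enrichment

`ssgsea_scores()` ranks each sample's genes (descending, ties broken by
gene id for cross-platform determinism), weights positions by
`(n − rank + 1)^alpha` with the canonical `alpha = 0.25`, and accumulates
the difference between the weighted in-set CDF and the unweighted
out-of-set CDF down the full ranked list. One rank-based engine serves both
the immune-infiltration profiles and any pathway-activity summaries; the
Gaussian-kernel variation-analysis variant is deliberately not a second
engine — one well-tested statistic with a documented deviation was
preferred over two half-tested ones. Scores are min–max normalised per set
for cross-set comparability.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, not the biology of any real cohort:

- expression is log-normal: `exp(N(μ_g + δ_{g,z}, σ²))`, with baseline
  `μ_g ~ N(3, 1)` (natural-log scale) and TPM renormalisation afterwards;
- the regulator panel is split round-robin into `k_true` blocks; block j
  is shifted up by `cluster_shift` (default 1.5, natural-log units) in
  cluster j — each cluster has its own signature, so correlation distance
  sees all of them;
- prognostic genes share an *ordered* profile across clusters
  (`w_g · cluster_shift · a_z` with `a` equispaced on [−1, 1] and
  `w_g ~ U(0.75, 1.25)`), which makes every planted gene differential in
  every pairwise contrast and gives all of them one risk orientation;
- the latent risk `true_score` is the centred per-sample mean of the
  prognostic genes' log expression — a realisable analogue of the PCA
  score that gives end-to-end tests a monotone link without assuming PCA
  internals;
- survival is exponential with hazard `h₀·exp(β·true_score)` (defaults
  `h₀ = 0.001`/day, `β = 0.8`) under independent uniform censoring on
  `[0, c]`, with `c` solved numerically so the expected censored fraction
  hits `censor_rate_target = 0.3` — standard, and it keeps proportional
  hazards intact;
- mutations are per-(sample, gene) Bernoulli draws at literature-scale
  frequencies (APC 0.7, TP53 0.5, TTN 0.4, …), optionally multiplied by
  `exp(mutation_score_coef · true_score)`; the multiplier defaults to 0 so
  the generator's marginal frequencies are exactly the configured ones,
  and analyses that need the burden–risk link enable it explicitly
  (`mutation_score_coef = 0.5` in the drivers);
- MSI is a three-level categorical with score-dependent logits (MSS more
  likely at high score) and the four IPS columns are Gaussian with a
  negative score slope — only their group-comparison behaviour needs
  emulating.

Everything is a deterministic function of the config's single seed, which
the pipeline derives per stage from its global seed so any stage is
reproducible in isolation.

What passing tests on this generator do **not** show: robustness to
platform/batch effects (not simulated), to heavy censoring or non-PH
hazards, to symbol mismatches across cohorts, or to immune signatures that
overlap the prognostic programme. One coupling worth knowing about:
because ssGSEA is rank-based and TPM is compositional, even "null" gene
sets can correlate with the score when the planted programme shifts the
ranks of everything else — counts of significant score–immune correlations
on synthetic data are therefore not a null calibration.

## Problem sizes and numerical choices

The shipped drivers and tests use cohorts of 90–400 samples and a few
hundred genes, consensus runs of 25–100 repetitions over k = 2…9, 40-seed
recovery studies for the Cox coefficient and 20-seed null studies (2000
genes × 3 groups) for DEG calibration — sizes at which every planted
property is comfortably identifiable and the whole suite runs in about a
minute. Degenerate inputs have defined behaviour rather than silent
answers: zero-variance genes flag `p = 1` in DE, constant covariates flag
out of Cox, rank-deficient signature matrices set PC2 = 0 with a warning,
constant enrichment rows min–max-map to 0 with a warning, and resamples
with fewer than k distinct samples are redrawn with bounded retries.

## Known limitations

- The regulator catalog shipped in `inst/extdata/` is a synthetic stand-in
  panel (48 genes, 23/15/10 split) assembled from field-standard symbols;
  analyses of real cohorts should supply the curated panel of record.
- Consensus clustering reports no item-consensus, cluster-consensus or PAC
  statistics; the delta-area rule is the only k-selection criterion.
- Cox modelling is univariate by design — no multivariable adjustment,
  time-varying effects or proportionality diagnostics.
- TMB is a raw variant count by default (an optional per-megabase divisor
  exists); which variant classes count is explicit configuration, since
  conventions differ.
- Cross-platform batch correction is out of scope; `merge_cohorts()` joins
  cohorts on shared symbols but applies no correction, and says so.
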