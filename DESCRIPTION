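Package: rnamodsig
Title: RNA Modification Regulator Clustering and Prognostic Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis workflow for RNA modification (m6A/m5C/m1A) regulator
    biology in tumour expression cohorts. From a gene-by-sample expression
    matrix and a clinical table it derives regulator-based consensus clusters
    (resampled hierarchical clustering with CDF-area selection of the cluster
    number), single-sample gene-set enrichment scores for immune signatures,
    moderated differential expression between clusters with a Venn-overlap
    gene rule, univariate Cox screening of prognostic genes, a PCA-based
    per-sample modification score (PC1 + PC2, risk-oriented), and
    score-stratified survival, mutation-burden and immunotherapy-marker
    analyses. Includes a synthetic cohort generator with planted cluster,
    prognostic and survival structure for testing the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
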