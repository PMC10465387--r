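#!/usr/bin/env Rscript
# Score-stratified downstream analyses: immune ssGSEA and score-immune
# correlation, tumour mutation burden and mutation summaries, TMB x score
# stratified survival, IPS/MSI/vital-status group comparisons, generic
# over-representation of the DEGs, and frozen-model validation on a
# held-out synthetic cohort.

library(rnamodsig)

seed <- 20260924
dir.create("results/downstream", showWarnings = FALSE, recursive = TRUE)

expr <- read_expression("results/data/expression_tpm.tsv", "TPM")
cl <- read_clinical("results/data/clinical.tsv")
mutations <- read_mutations("results/data/mutations.tsv")
immune_sets <- read_gmt("results/data/immune_sets.gmt")
degs <- readLines("results/degs/overlap_degs.txt")
score_tab <- utils::read.delim("results/score/modscore.tsv")
ms <- readRDS("scratch/modscore_model.rds")
le <- log2_transform(expr)
grp <- stats::setNames(factor(score_tab$group, c("low", "high")),
                       score_tab$sample_id)

## immune enrichment and its correlation with the score
enr <- minmax_normalize(ssgsea_scores(le, immune_sets))
corr <- score_immune_correlation(ms$score, enr)
utils::write.table(corr, "results/downstream/immune_correlation.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

## mutation burden
tmb <- compute_tmb(mutations, cl$sample_id)
utils::write.table(tmb, "results/downstream/tmb.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
msum <- mutation_summary(mutations, grp)
utils::write.table(msum$genes, "results/downstream/mutation_genes.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
tmbg <- stats::setNames(tmb$tmb_group, tmb$sample_id)
skm <- stratified_km(cl, grp, tmbg)

## group comparisons (IPS, MSI, vital status, TMB)
comps <- list(compare_groups(tmb$tmb, grp[tmb$sample_id], name = "tmb"))
for (col in grep("^ips_", colnames(cl), value = TRUE))
  comps[[col]] <- compare_groups(cl[[col]], grp[cl$sample_id], name = col)
comps$score_by_msi <- compare_groups(
  stats::setNames(score_tab$score, score_tab$sample_id)[cl$sample_id],
  cl$msi, name = "score_by_msi")
comps$msi_by_group <- compare_groups(cl$msi, grp[cl$sample_id],
                                     name = "msi_by_group")
comps$score_by_vital <- compare_groups(
  stats::setNames(score_tab$score, score_tab$sample_id)[cl$sample_id],
  ifelse(cl$os_event == 1, "dead", "alive"), name = "score_by_vital")
comp_tab <- do.call(rbind, comps)
utils::write.table(comp_tab, "results/downstream/group_comparisons.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

## over-representation of the DEGs in the (synthetic) annotation sets
ora <- ora_hypergeometric(degs, immune_sets, rownames(le))
utils::write.table(ora, "results/downstream/ora.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

## held-out validation cohort through the frozen score model
vcoh <- generate_cohort(sim_config(n_samples = 150, seed = seed + 99))
val <- validate_external(ms, log2_transform(vcoh$expression),
                         vcoh$clinical)
utils::write.table(
  data.frame(sample_id = names(val$score), score = val$score,
             group = val$group),
  "results/downstream/validation_scores.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)

rates <- msum$rates
cat(sprintf("mutated samples: high %.1f%% vs low %.1f%%\n",
            100 * rates[["high"]], 100 * rates[["low"]]))
cat(sprintf("TMB higher in high-score group: wilcoxon p = %.3g\n",
            comps[[1]]$p))
cat(sprintf("TMB x score stratified survival: log-rank p = %.3g\n",
            skm$logrank$p))
cat(sprintf("immune sets correlated with score (BH < 0.05): %d of %d\n",
            sum(corr$p_adj < 0.05), nrow(corr)))
cat(sprintf("IPS comparisons with p < 0.05: %d of 4\n",
            sum(comp_tab$p[grep("^ips_", comp_tab$variable)] < 0.05)))
cat(sprintf("validation cohort separation: log-rank p = %.3g (%d genes)\n",
            val$logrank$p, length(val$genes_used)))
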