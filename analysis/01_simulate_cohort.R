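#!/usr/bin/env Rscript
# Build the synthetic study cohort: 300 tumour samples with three planted
# regulator-driven clusters, 30 prognostic genes, proportional-hazards
# survival, mutations enriched with risk, MSI and IPS columns.
# Writes the on-disk inputs every later step consumes.

library(rnamodsig)

seed <- 20260924
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(mutation_score_coef = 0.5, seed = seed)
cohort <- generate_cohort(cfg)
mutations <- generate_mutations(cfg, cohort$truth)
immune_sets <- generate_immune_sets(rownames(cohort$expression), seed = seed)

write_expression(cohort$expression, "results/data/expression_tpm.tsv")
write_clinical(cohort$clinical, "results/data/clinical.tsv")
write_mutations(mutations, "results/data/mutations.tsv")
write_gmt(immune_sets, "results/data/immune_sets.gmt")
utils::write.table(
  data.frame(sample_id = names(cohort$truth$cluster_labels),
             true_cluster = cohort$truth$cluster_labels,
             true_score = cohort$truth$true_score),
  "results/data/truth.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(cohort$truth$prognostic_gene_ids,
           "results/data/truth_prognostic_genes.txt")

cat(sprintf("cohort: %d samples, %d genes (%d regulators)\n",
            ncol(cohort$expression), nrow(cohort$expression),
            nrow(cohort$catalog)))
cat(sprintf("events: %d (%.0f%% censored); mutations: %d rows in %d samples\n",
            sum(cohort$clinical$os_event),
            100 * (1 - mean(cohort$clinical$os_event)),
            nrow(mutations), length(unique(mutations$sample_id))))
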