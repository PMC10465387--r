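#!/usr/bin/env Rscript
# Moderated differential expression between the regulator clusters, the
# Venn-overlap DEG rule (adjusted p < 0.001 in every pairwise contrast),
# then a univariate Cox screen of the overlap genes for prognosis.

library(rnamodsig)

dir.create("results/degs", showWarnings = FALSE, recursive = TRUE)

expr <- read_expression("results/data/expression_tpm.tsv", "TPM")
cl <- read_clinical("results/data/clinical.tsv")
clusters <- utils::read.delim("results/clusters/regulator_clusters.tsv")
le <- log2_transform(expr)
labels <- clusters$cluster[match(colnames(le), clusters$sample_id)]

de <- pairwise_contrasts(le, labels, alpha = 0.001)
for (nm in names(de))
  utils::write.table(de[[nm]], sprintf("results/degs/de_%s.tsv", nm),
                     sep = "\t", quote = FALSE, row.names = FALSE)
degs <- overlap_degs(de, alpha = 0.001)
writeLines(degs, "results/degs/overlap_degs.txt")

prog <- prognostic_filter(le, cl, degs, p_threshold = 0.05)
utils::write.table(prog$table, "results/degs/prognostic_cox.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(prog$genes, "results/degs/prognostic_genes.txt")

planted <- readLines("results/data/truth_prognostic_genes.txt")
cat(sprintf("overlap DEGs across %d contrasts: %d genes\n",
            length(de), length(degs)))
cat(sprintf("prognostic after Cox screen (p < 0.05): %d genes\n",
            length(prog$genes)))
cat(sprintf("planted prognostic genes recovered: %d of %d\n",
            length(intersect(prog$genes, planted)), length(planted)))
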