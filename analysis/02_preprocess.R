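#!/usr/bin/env Rscript
# Stage 2: preprocessing.
#
# For each cohort: drop probes missing in more than 30% of samples,
# impute the rest by 5-nearest-probe means, replace expression zeros by
# the dataset minimum positive value, log2-transform and quantile
# normalize, and collapse probes to gene-level promoter methylation
# (TSS200, else first exon, else TSS1500; body probes never used).
#
# Run from the repository root after 01_simulate.R.

library(sigdomnet)

root <- "results/synthetic"
types <- c("SYNTH1", "SYNTH2", "SYNTH3")

for (ty in types) {
  dir <- file.path(root, ty)
  cohort <- load_cohort(dir)
  beta <- clean_beta(cohort$beta)
  expr <- normalize_expression(cohort$expr_raw)
  gm <- gene_level_methylation(beta, cohort$probes)
  write_matrix_tsv(gm, file.path(dir, "gene_methylation.tsv"),
                   id_col = "gene")
  write_matrix_tsv(expr, file.path(dir, "expression_norm.tsv"),
                   id_col = "gene")
  cat(sprintf(
    "%s: %d/%d probes kept, %d genes with promoter methylation\n",
    ty, nrow(beta), nrow(cohort$beta), nrow(gm)))
}
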