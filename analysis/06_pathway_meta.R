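#!/usr/bin/env Rscript
# Stage 6: pan-cancer pathway meta-analysis.
#
# For every pathway in the GMT collection and every cohort, tests
# whether methylation-driven alterations concentrate in the
# extracellular domain relative to copy-number-driven ones, then
# combines the per-cohort p-values with Fisher's combined test.
# Also writes the cumulative (summed over cohorts) alteration-by-
# domain table for the top pathway.
#
# Run from the repository root after 05_domain_enrichment.R.

library(sigdomnet)

root <- "results/synthetic"
types <- c("SYNTH1", "SYNTH2", "SYNTH3")

pathways <- read_gmt(file.path(root, "pathways.gmt"))
edges <- read_sif(file.path(root, "SYNTH1", "edges.sif.tsv"))
loc <- read_localization(file.path(root, "SYNTH1", "localization.tsv"))
pin <- build_pruned_pin(edges, coarse_domains(loc))
coarse <- stats::setNames(igraph::V(pin)$coarse, igraph::V(pin)$name)

dnam_by_type <- list()
scna_by_type <- list()
for (ty in types) {
  dir <- file.path(root, ty)
  rd <- read_df_tsv(file.path(dir, "ranked_dnam.tsv"))
  dnam_by_type[[ty]] <- unique(rd$gene)
  scna_by_type[[ty]] <- unique(c(
    read_df_tsv(file.path(dir, "ranked_amplification.tsv"))$gene,
    read_df_tsv(file.path(dir, "ranked_deletion.tsv"))$gene))
}

meta <- pathway_meta_analysis(pathways, dnam_by_type, scna_by_type, coarse)
write_df_tsv(meta, file.path(root, "pathway_meta.tsv"))
cum <- pathway_cumulative_table(pathways, dnam_by_type, scna_by_type,
                                coarse, pathway_names = meta$pathway[1:3])
write_df_tsv(cum, file.path(root, "pathway_cumulative.tsv"))

cat("top pathways by combined meta p:\n")
print(utils::head(meta[, c("pathway", "meta_p", "meta_p_bh")], 5),
      row.names = FALSE)
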