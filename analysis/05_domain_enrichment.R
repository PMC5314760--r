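#!/usr/bin/env Rscript
# Stage 5: signaling-domain enrichment of the alteration classes.
#
# For each cohort, tests whether each alteration class is enriched
# (methylation classes, mutations) or depleted (copy-number classes)
# in the combined extracellular + membrane-receptor domain relative to
# the annotated network background, in both the all-significant and
# the equalized (common top-k) modes.
#
# Run from the repository root after 04_network_topology.R.

library(sigdomnet)

root <- "results/synthetic"
types <- c("SYNTH1", "SYNTH2", "SYNTH3")

edges <- read_sif(file.path(root, "SYNTH1", "edges.sif.tsv"))
loc <- read_localization(file.path(root, "SYNTH1", "localization.tsv"))
pin <- build_pruned_pin(edges, coarse_domains(loc))
coarse <- stats::setNames(igraph::V(pin)$coarse, igraph::V(pin)$name)

read_lists <- function(dir) {
  rd <- read_df_tsv(file.path(dir, "ranked_dnam.tsv"))
  list(HyperM = rd$gene[rd$class == "HyperM"],
       HypoM = rd$gene[rd$class == "HypoM"],
       Amplification = read_df_tsv(
         file.path(dir, "ranked_amplification.tsv"))$gene,
       Deletion = read_df_tsv(file.path(dir, "ranked_deletion.tsv"))$gene,
       Mutation = utils::head(
         read_df_tsv(file.path(dir, "ranked_mutation.tsv"))$gene, 100))
}

for (ty in types) {
  dir <- file.path(root, ty)
  lists <- read_lists(dir)
  enr <- domain_enrichment(lists, coarse, "all")
  enr_eq <- domain_enrichment(lists, coarse, "equalized")
  write_df_tsv(enr, file.path(dir, "domain_enrichment_all.tsv"))
  write_df_tsv(enr_eq, file.path(dir, "domain_enrichment_equalized.tsv"))
  cat(sprintf("%s  EC+MR odds ratios:\n", ty))
  print(enr[, c("class", "n", "observed_ecmr", "expected_ecmr",
                "odds_ratio", "p", "direction")], row.names = FALSE)
}
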