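#!/usr/bin/env Rscript
# Stage 4: interactome topology of the alteration classes.
#
# Builds the pruned signaling-hierarchy network from the edge list and
# localization table (only EC-EC, EC-MR, MR-IC, IC-IC edges survive),
# maps the top-100 genes of each alteration class onto it, and
# compares connectivity (degree) and within-class shortest-path
# distributions with one-tailed rank-sum tests.
#
# Run from the repository root after 03_driver_calls.R.

library(sigdomnet)

root <- "results/synthetic"
types <- c("SYNTH1", "SYNTH2", "SYNTH3")

edges <- read_sif(file.path(root, "SYNTH1", "edges.sif.tsv"))
loc <- read_localization(file.path(root, "SYNTH1", "localization.tsv"))
coarse <- coarse_domains(loc)
pin <- build_pruned_pin(edges, coarse)
cat(sprintf("pruned network: %d nodes, %d edges, sparsity %.4f\n",
            pin$n_nodes, pin$n_edges, pin$sparsity))
jsonlite::write_json(list(n_nodes = pin$n_nodes, n_edges = pin$n_edges,
                          sparsity = pin$sparsity),
                     file.path(root, "network_stats.json"),
                     auto_unbox = TRUE, digits = NA)

read_lists <- function(dir) {
  rd <- read_df_tsv(file.path(dir, "ranked_dnam.tsv"))
  list(HyperM = rd$gene[rd$class == "HyperM"][order(
         rd$rank[rd$class == "HyperM"])],
       HypoM = rd$gene[rd$class == "HypoM"][order(
         rd$rank[rd$class == "HypoM"])],
       Amplification = read_df_tsv(
         file.path(dir, "ranked_amplification.tsv"))$gene,
       Deletion = read_df_tsv(file.path(dir, "ranked_deletion.tsv"))$gene,
       Mutation = read_df_tsv(file.path(dir, "ranked_mutation.tsv"))$gene)
}

for (ty in types) {
  dir <- file.path(root, ty)
  lists <- read_lists(dir)
  deg <- suppressWarnings(degree_comparison(lists, pin))
  sp <- suppressWarnings(shortest_path_comparison(lists, pin))
  write_matrix_tsv(deg$p_matrix, file.path(dir, "degree_comparison_p.tsv"),
                   id_col = "class")
  write_df_tsv(sp$comparisons, file.path(dir, "path_comparison.tsv"))
  cat(sprintf("%s: pooled DNAm-vs-CNV degree p = %.3g\n",
              ty, deg$pooled_dnam_vs_cnv_p))
}
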