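#!/usr/bin/env Rscript
# Stage 1: simulate the study inputs.
#
# Builds one signaling-domain-annotated interactome shared by three
# synthetic "cancer types", plants domain-biased alteration classes in
# each cohort (methylation classes biased toward extracellular /
# membrane-receptor genes, copy-number classes toward intracellular
# genes), and writes every input the downstream stages consume:
# beta matrix, probe annotation, raw expression, SEG, MAF, sample
# sheet, gene coordinates, SIF edge list, localization table, pathway
# GMT and ground-truth JSON.
#
# Run from the repository root: Rscript analysis/01_simulate.R

library(sigdomnet)

out_root <- "results/synthetic"
dir.create(out_root, showWarnings = FALSE, recursive = TRUE)

base_seed <- 11L
types <- c("SYNTH1", "SYNTH2", "SYNTH3")

net_cfg <- synth_config(n_genes = 600, n_normal = 40, n_tumor = 40,
                        seed = base_seed,
                        planted = list(n_hyperm = 40, n_hypom = 40,
                                       n_amp = 40, n_del = 40, n_mut = 40,
                                       degree_bias = 1.5))
net <- generate_interactome(net_cfg)
cat(sprintf("interactome: %d nodes, %d edges\n",
            igraph::vcount(net), igraph::ecount(net)))
print(table(igraph::V(net)$coarse))

for (i in seq_along(types)) {
  cfg <- synth_config(n_genes = 600, n_normal = 40, n_tumor = 40,
                      seed = base_seed + i, cancer_type = types[i],
                      planted = list(n_hyperm = 40, n_hypom = 40,
                                     n_amp = 40, n_del = 40, n_mut = 40,
                                     degree_bias = 1.5))
  cohort <- generate_cohort(cfg, net)
  dir <- file.path(out_root, types[i])
  write_cohort(cohort, net, dir)
  cat(sprintf("%s: %d probes, %d planted HyperM genes -> %s\n",
              types[i], nrow(cohort$beta), length(cohort$truth$hyperm), dir))
}

pathways <- generate_pathways(net, n_pathways = 15, min_size = 60,
                              max_size = 120, seed = base_seed)
write_gmt(pathways, file.path(out_root, "pathways.gmt"))
cat(sprintf("pathways: %d gene sets -> %s\n", length(pathways),
            file.path(out_root, "pathways.gmt")))
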