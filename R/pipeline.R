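#' Default analysis thresholds
#'
#' All values are the standard settings of the workflow: FDR 0.05,
#' promoter beta difference 0.1, |log2FC| 1 (tissue variants 0.3 / 2),
#' 30% probe NA filter with k = 5 imputation, 2/4 sigma copy-number
#' calling, 5% expression tails, top-100 lists, p < 0.05 multivariate
#' gate.
#'
#' @return named list of thresholds.
#' @export
default_thresholds <- function() {
  list(fdr_max = 0.05, min_delta_beta = 0.1, min_abs_log2fc = 1,
       tissue_delta_beta = 0.3, tissue_log2fc = 2,
       max_na_fraction = 0.3, knn_k = 5, tail = 0.05, top_k = 100,
       p_multivar = 0.05)
}

#' Load a cohort directory written by [write_cohort()]
#'
#' Missing files abort with the name of the pipeline stage that needs
#' them.
#'
#' @param dir cohort directory.
#' @return cohort list usable by [run_cancer_type()].
#' @export
load_cohort <- function(dir) {
  need <- function(f, stage) {
    path <- file.path(dir, f)
    if (!file.exists(path))
      stop(stage, " stage input missing: ", f, call. = FALSE)
    path
  }
  cfg <- yaml::read_yaml(need("config.yaml", "config"))
  cfg$domain_fractions <- unlist(cfg$domain_fractions)
  config <- synth_config(n_genes = cfg$n_genes, n_normal = cfg$n_normal,
                         n_tumor = cfg$n_tumor,
                         cancer_type = cfg$cancer_type,
                         domain_fractions = cfg$domain_fractions,
                         planted = cfg$planted, noise = cfg$noise,
                         degree_model = cfg$degree_model, seed = cfg$seed)
  list(beta = read_matrix_tsv(need("beta.tsv", "preprocess")),
       probes = read_probe_annotation(need("probes.tsv", "preprocess")),
       expr_raw = read_matrix_tsv(need("expression.tsv", "preprocess")),
       segments = read_seg(need("segments.seg.tsv", "scna")),
       mutations = read_maf(need("mutations.maf.tsv", "mutation")),
       samples = read_sample_sheet(need("samples.tsv", "preprocess")),
       gene_coords = read_gene_coords(need("gene_coords.tsv", "scna")),
       truth = jsonlite::read_json(need("ground_truth.json", "truth"),
                                   simplifyVector = TRUE),
       config = config)
}

#' Run the full per-cancer-type analysis
#'
#' Sequences the stages end to end: beta cleaning and imputation,
#' expression normalization, gene-level methylation, moderated-t driver
#' calling with the multivariate filter, copy-number call matrix and
#' joint SCNA rankings, mutation frequency ranking, interactome pruning
#' and topology comparisons, and signaling-domain enrichment. With a
#' [synth_config()] the inputs are generated; alternatively a
#' pre-generated cohort/network pair can be passed (e.g. loaded from
#' files).
#'
#' @param config [synth_config()] object.
#' @param net,cohort optional pre-generated interactome and cohort.
#' @param thresholds from [default_thresholds()].
#' @return bundle list: matrices, statistics, ranked lists, pruned
#'   network, topology and enrichment results, and a filter log.
#' @export
run_cancer_type <- function(config, net = NULL, cohort = NULL,
                            thresholds = default_thresholds()) {
  if (is.null(net)) net <- generate_interactome(config)
  if (is.null(cohort)) cohort <- generate_cohort(config, net)
  thr <- thresholds
  group <- cohort$samples$group
  log <- list()
  note <- function(stage, before, after) {
    log[[stage]] <<- c(before = before, after = after)
  }

  beta_clean <- clean_beta(cohort$beta, thr$max_na_fraction, thr$knn_k)
  note("probe_na_filter", nrow(cohort$beta), nrow(beta_clean))
  expr <- normalize_expression(cohort$expr_raw)
  gm <- gene_level_methylation(beta_clean, cohort$probes)
  note("gene_level_meth", length(unique(cohort$probes$gene)), nrow(gm))

  st <- diff_stats(gm, expr, group)
  sig <- call_dnam_de(st, thr$fdr_max, thr$min_delta_beta, thr$min_abs_log2fc)
  ranked <- classify_and_rank(sig)
  note("dnam_de_calls", nrow(st), nrow(ranked))

  tum_ids <- cohort$samples$sample_id[group == "tumor"]
  cn_thr <- cn_thresholds(cohort$segments)
  calls <- build_call_matrix(cohort$segments, cn_thr, cohort$gene_coords)
  cn_state <- matrix(0, nrow(cohort$expr_raw), length(group),
                     dimnames = list(rownames(cohort$expr_raw),
                                     cohort$samples$sample_id))
  shared <- intersect(rownames(calls), colnames(cn_state))
  cn_state[colnames(calls), shared] <- t(calls[shared, , drop = FALSE])

  mv <- multivariate_filter(expr, gm, cn_state, ranked$gene,
                            class = "dnam", p_max = thr$p_multivar)
  ranked <- ranked[ranked$gene %in% mv$gene[mv$kept], , drop = FALSE]
  if (nrow(ranked)) {
    ranked <- do.call(rbind, lapply(split(ranked, ranked$class), function(d) {
      d$rank <- seq_len(nrow(d))
      d
    }))
    rownames(ranked) <- NULL
  }
  note("dnam_multivar_filter", nrow(mv), nrow(ranked))

  tails <- expression_tail_calls(expr[, tum_ids, drop = FALSE], thr$tail)
  scna <- rank_scna_genes(calls, tails, expr = expr, meth = gm,
                          cn_state = cn_state, p_max = thr$p_multivar)
  muts <- rank_mutated_genes(cohort$mutations)

  coarse <- stats::setNames(igraph::V(net)$coarse, igraph::V(net)$name)
  el <- igraph::as_edgelist(net)
  pin <- build_pruned_pin(data.frame(geneA = el[, 1], geneB = el[, 2]),
                          coarse)
  lists <- list(
    HyperM = ranked$gene[ranked$class == "HyperM"][order(
      ranked$rank[ranked$class == "HyperM"])],
    HypoM = ranked$gene[ranked$class == "HypoM"][order(
      ranked$rank[ranked$class == "HypoM"])],
    Amplification = scna$amplification$gene,
    Deletion = scna$deletion$gene,
    Mutation = muts$gene)
  topo_degree <- degree_comparison(lists, pin, thr$top_k)
  topo_paths <- shortest_path_comparison(lists, pin, thr$top_k)
  pin_coarse <- stats::setNames(igraph::V(pin)$coarse, igraph::V(pin)$name)
  enrich_all <- domain_enrichment(lists, pin_coarse, "all")
  enrich_eq <- domain_enrichment(lists, pin_coarse, "equalized")

  list(cancer_type = cohort$samples$cancer_type[1], config = cohort$config,
       thresholds = thr, stats = st, ranked_dnam = ranked,
       scna_lists = scna, mutation_list = muts, call_matrix = calls,
       cn_thresholds = cn_thr, expression_tails = tails,
       gene_meth = gm, expr = expr, lists = lists, pin = pin,
       topo_degree = topo_degree, topo_paths = topo_paths,
       enrich_all = enrich_all, enrich_eq = enrich_eq,
       truth = cohort$truth, log = log)
}

#' Pan-cancer meta-analysis over per-type bundles
#'
#' Combines per-cancer-type bundles: pathway-level differential-domain
#' meta-analysis (Fisher's combined test), cumulative alteration
#' tables, deregulation-category matrix and its consistency test, and
#' optional enzyme co-expression analysis.
#'
#' @param bundles named list of [run_cancer_type()] bundles (>= 2).
#' @param pathways named list of pathway gene vectors.
#' @param enzyme_targets optional target gene vector for
#'   [enzyme_correlation()].
#' @param enzymes enzyme genes (default DNMT1, EZH2).
#' @param n_perm permutations for the consistency test.
#' @param seed RNG seed for the permutation test.
#' @return list: `pathway_meta`, `cumulative`, `categories`,
#'   `consistency`, and `enzyme` (or NULL).
#' @export
run_pan_cancer <- function(bundles, pathways, enzyme_targets = NULL,
                           enzymes = c("DNMT1", "EZH2"), n_perm = 200,
                           seed = 1) {
  if (length(bundles) < 2) stop("need >= 2 per-cancer bundles")
  universes <- lapply(bundles, function(b) sort(igraph::V(b$pin)$name))
  if (!all(vapply(universes, identical, TRUE, universes[[1]]))) {
    bad <- names(bundles)[!vapply(universes, identical, TRUE, universes[[1]])]
    stop("bundles with incompatible gene universes: ",
         paste(bad, collapse = ", "))
  }
  coarse <- stats::setNames(igraph::V(bundles[[1]]$pin)$coarse,
                            igraph::V(bundles[[1]]$pin)$name)
  dnam_by_type <- lapply(bundles, function(b)
    unique(b$ranked_dnam$gene))
  scna_by_type <- lapply(bundles, function(b)
    unique(c(b$scna_lists$amplification$gene, b$scna_lists$deletion$gene)))
  meta <- pathway_meta_analysis(pathways, dnam_by_type, scna_by_type, coarse)
  cumulative <- pathway_cumulative_table(pathways, dnam_by_type,
                                         scna_by_type, coarse)
  categories <- categorize_deregulation(lapply(bundles, `[[`, "stats"))
  consistency <- consistency_empirical_p(categories, n_perm = n_perm,
                                         seed = seed)
  enzyme <- NULL
  if (!is.null(enzyme_targets)) {
    expr_by_type <- lapply(bundles, function(b) {
      tum <- grepl("^T", colnames(b$expr))
      b$expr[, tum, drop = FALSE]
    })
    enzyme <- enzyme_correlation(expr_by_type, enzyme_targets, enzymes)
  }
  list(pathway_meta = meta, cumulative = cumulative,
       categories = categories, consistency = consistency, enzyme = enzyme)
}

#' Write a per-cancer bundle to plain-text files
#'
#' Every table carries a provenance header (package version, seed,
#' thresholds); output bytes are a deterministic function of the
#' bundle.
#'
#' @param bundle from [run_cancer_type()].
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prov <- c(paste("sigdomnet", as.character(utils::packageVersion("sigdomnet"))),
            paste("seed", bundle$config$seed),
            paste("thresholds",
                  paste(names(bundle$thresholds), unlist(bundle$thresholds),
                        sep = "=", collapse = " ")))
  p <- function(f) file.path(dir, f)
  write_df_tsv(bundle$ranked_dnam, p("ranked_dnam.tsv"), prov)
  write_df_tsv(bundle$scna_lists$amplification, p("ranked_amplification.tsv"),
               prov)
  write_df_tsv(bundle$scna_lists$deletion, p("ranked_deletion.tsv"), prov)
  write_df_tsv(bundle$mutation_list, p("ranked_mutation.tsv"), prov)
  write_matrix_tsv(bundle$call_matrix, p("cn_call_matrix.tsv"),
                   id_col = "sample", provenance = prov)
  write_matrix_tsv(bundle$topo_degree$p_matrix, p("degree_comparison_p.tsv"),
                   id_col = "class", provenance = prov)
  write_df_tsv(bundle$topo_paths$comparisons, p("path_comparison.tsv"), prov)
  write_df_tsv(bundle$enrich_all, p("domain_enrichment_all.tsv"), prov)
  write_df_tsv(bundle$enrich_eq, p("domain_enrichment_equalized.tsv"), prov)
  jsonlite::write_json(
    list(n_nodes = bundle$pin$n_nodes, n_edges = bundle$pin$n_edges,
         sparsity = bundle$pin$sparsity,
         pooled_dnam_vs_cnv_degree_p = bundle$topo_degree$pooled_dnam_vs_cnv_p,
         filter_log = bundle$log),
    p("network_stats.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
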