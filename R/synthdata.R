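#' Configuration for the synthetic interactome and cohort generator
#'
#' Defaults define the standard study conditions: 1000 genes on a
#' connected scale-free-like interactome, 50 normal + 50 tumor samples,
#' 60 planted genes per alteration class with a promoter beta shift of
#' 0.3, a 2-fold-change expression effect, copy-number events of
#' log2-ratio 1 in 40% of tumors, and a 15% per-sample mutation rate.
#' Methylation/copy-number classes are planted with 3:1 odds toward
#' their characteristic domains (HyperM/HypoM toward EC/MR,
#' Amplification/Deletion toward IC).
#'
#' @param n_genes number of genes (>= 10).
#' @param n_normal,n_tumor sample counts.
#' @param cancer_type cohort label.
#' @param domain_fractions proportions over GM, SF, MR, ICRS, ICNRS
#'   (sum 1).
#' @param planted list: n_hyperm, n_hypom, n_amp, n_del, n_mut class
#'   sizes; delta_beta in `[0, 1]`; log2fc; cn_shift (log2-ratio units);
#'   mutation_rate in `[0, 1]`; cn_event_frac tumor fraction carrying a
#'   planted CNV segment; domain_bias_odds; degree_bias (0 = none;
#'   positive plants methylation classes on low-degree and copy-number
#'   classes on high-degree nodes).
#' @param noise list: beta_logit_sd (logit-scale beta dispersion),
#'   expr_sd (log2 expression s.d.), seg_sd (background segment
#'   log2-ratio s.d.), na_frac (methylation missingness rate),
#'   high_na_frac_probes (fraction of probes made mostly-missing to
#'   exercise the NA filter).
#' @param degree_model list: power (preferential-attachment exponent)
#'   and m (edges per new node).
#' @param seed integer RNG seed; fixed seed gives byte-identical output.
#' @return validated config list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 1000, n_normal = 50, n_tumor = 50,
                         cancer_type = "SYNTH1",
                         domain_fractions = c(GM = 0.1, SF = 0.1, MR = 0.2,
                                              ICRS = 0.3, ICNRS = 0.3),
                         planted = list(), noise = list(),
                         degree_model = list(), seed = 1) {
  planted_def <- list(n_hyperm = 60, n_hypom = 60, n_amp = 60, n_del = 60,
                      n_mut = 60, delta_beta = 0.3, log2fc = 2, cn_shift = 1,
                      mutation_rate = 0.15, cn_event_frac = 0.4,
                      domain_bias_odds = 3, degree_bias = 0)
  noise_def <- list(beta_logit_sd = 0.5, expr_sd = 1, seg_sd = 0.1,
                    na_frac = 0.005, high_na_frac_probes = 0.01)
  degree_def <- list(power = 1, m = 3)
  planted <- utils::modifyList(planted_def, planted)
  noise <- utils::modifyList(noise_def, noise)
  degree_model <- utils::modifyList(degree_def, degree_model)

  stopifnot(n_genes >= 10, n_normal >= 0, n_tumor >= 0)
  stopifnot(setequal(names(domain_fractions),
                     c("GM", "SF", "MR", "ICRS", "ICNRS")))
  if (abs(sum(domain_fractions) - 1) > 1e-9)
    stop("domain_fractions must sum to 1")
  counts <- unlist(planted[c("n_hyperm", "n_hypom", "n_amp", "n_del",
                             "n_mut")])
  stopifnot(all(counts >= 0), sum(counts) <= n_genes)
  stopifnot(planted$delta_beta >= 0, planted$delta_beta <= 1)
  stopifnot(planted$mutation_rate >= 0, planted$mutation_rate <= 1)
  structure(list(n_genes = n_genes, n_normal = n_normal, n_tumor = n_tumor,
                 cancer_type = cancer_type,
                 domain_fractions = domain_fractions, planted = planted,
                 noise = noise, degree_model = degree_model,
                 seed = as.integer(seed)),
            class = "synth_config")
}

fine_to_coarse <- c(GM = "EC", SF = "EC", MR = "MR", ICRS = "IC",
                    ICNRS = "IC")

#' Generate a connected, domain-annotated synthetic interactome
#'
#' Label-aware preferential attachment: nodes receive fine signaling-
#' domain labels drawn from `domain_fractions`; each new node attaches
#' to `m` existing nodes chosen with probability proportional to
#' `(degree + 1)^power` among nodes whose coarse domain forms a
#' hierarchy-consistent pair (EC-EC, EC-MR, MR-IC, IC-IC) with the new
#' node; when no compatible node exists (degenerate label mixes) the
#' attachment falls back to all nodes, so the resulting edges violate
#' the hierarchy and exercise downstream pruning. The graph is
#' connected by construction, and each node carries a localization term
#' consistent with its label.
#'
#' @param config [synth_config()] object.
#' @return annotated igraph object (vertex attributes `fine`, `coarse`,
#'   `term`).
#' @export
generate_interactome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_genes
  fine <- sample(names(config$domain_fractions), n, replace = TRUE,
                 prob = config$domain_fractions)
  coarse <- fine_to_coarse[fine]
  m <- config$degree_model$m
  power <- config$degree_model$power
  deg <- integer(n)
  from <- integer(0)
  to <- integer(0)
  for (i in 2:n) {
    prev <- seq_len(i - 1)
    compat <- prev[edge_pair_allowed(coarse[i], coarse[prev])]
    cand <- if (length(compat)) compat else prev
    k <- min(m, length(cand))
    w <- (deg[cand] + 1)^power
    tgt <- if (length(cand) == 1) cand
    else sample(cand, k, prob = w)
    from <- c(from, rep.int(i, k))
    to <- c(to, tgt)
    deg[i] <- deg[i] + k
    deg[tgt] <- deg[tgt] + 1L
  }
  genes <- sprintf("G%04d", seq_len(n))
  g <- igraph::graph_from_data_frame(
    data.frame(from = genes[from], to = genes[to]),
    directed = FALSE, vertices = data.frame(name = genes))
  g <- igraph::simplify(g)
  g <- largest_component(g)
  if (igraph::vcount(g) == 0)
    stop("empty interactome; check n_genes/degree_model in the config")
  keep <- match(igraph::V(g)$name, genes)
  igraph::V(g)$fine <- fine[keep]
  igraph::V(g)$coarse <- unname(coarse[keep])
  terms <- c(GM = "Extracellular", SF = "Extracellular",
             MR = "Plasma membrane", ICRS = "Cytoplasm", ICNRS = "Nucleus")
  igraph::V(g)$term <- unname(terms[fine[keep]])
  g
}

weighted_sample <- function(x, size, w) {
  if (size == 0) return(x[0])
  sample(x, size, prob = w)
}

#' Generate a matched multi-omic synthetic cohort with planted effects
#'
#' Emits a probe-level beta matrix with TSS200/first-exon/TSS1500/body
#' probe structure, raw-scale expression, SEG-like copy-number
#' segments on a single linear pseudo-chromosome (genes tiled every
#' 10 kb), MAF-like mutation records, a sample sheet and the planted
#' ground truth. Planted HyperM genes gain `delta_beta` promoter
#' methylation and lose `log2fc` log2 expression in tumors (HypoM
#' mirrored); planted Amplification genes carry tumor segments at
#' `+cn_shift` with matching overexpression in the same samples
#' (Deletion mirrored); planted Mutation genes are mutated in a tumor
#' fraction `mutation_rate`. Body probes carry independent signal and
#' must be ignored downstream. All five planted classes are disjoint.
#'
#' @param config [synth_config()] object.
#' @param net interactome from [generate_interactome()]; its node set
#'   is the gene universe.
#' @return list: beta, probes, expr_raw, segments, mutations, samples,
#'   gene_coords, truth, config.
#' @export
generate_cohort <- function(config, net) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  genes <- igraph::V(net)$name
  n_g <- length(genes)
  coarse <- igraph::V(net)$coarse
  deg <- igraph::degree(net)
  pl <- config$planted
  stopifnot(pl$n_hyperm + pl$n_hypom + pl$n_amp + pl$n_del + pl$n_mut <= n_g)

  # planted class selection: domain bias (HyperM/HypoM toward EC+MR,
  # Amplification/Deletion toward IC) and optional degree bias
  w_dnam <- ifelse(coarse %in% c("EC", "MR"), pl$domain_bias_odds, 1)
  w_scna <- ifelse(coarse == "IC", pl$domain_bias_odds, 1)
  if (pl$degree_bias > 0) {
    w_dnam <- w_dnam * (1 / deg)^pl$degree_bias
    w_scna <- w_scna * deg^pl$degree_bias
  }
  avail <- rep(TRUE, n_g)
  draw <- function(nsize, w) {
    idx <- weighted_sample(which(avail), nsize, w[avail])
    avail[idx] <<- FALSE
    sort(genes[idx])
  }
  truth <- list(hyperm = draw(pl$n_hyperm, w_dnam),
                hypom = draw(pl$n_hypom, w_dnam),
                amplification = draw(pl$n_amp, w_scna),
                deletion = draw(pl$n_del, w_scna),
                mutation = draw(pl$n_mut, rep(1, n_g)))
  if (anyDuplicated(unlist(truth)))
    stop("overlapping planted sets")
  truth$domains <- data.frame(gene = genes, fine = igraph::V(net)$fine,
                              coarse = coarse, stringsAsFactors = FALSE)

  samples <- data.frame(
    sample_id = c(sprintf("N%03d", seq_len(config$n_normal)),
                  sprintf("T%03d", seq_len(config$n_tumor))),
    group = rep(c("normal", "tumor"), c(config$n_normal, config$n_tumor)),
    cancer_type = config$cancer_type, stringsAsFactors = FALSE)
  tumor <- samples$group == "tumor"
  n_s <- nrow(samples)

  # genome model: one linear pseudo-chromosome, genes tiled at 10 kb
  gene_coords <- data.frame(gene = genes, chrom = "chr1",
                            start = (seq_len(n_g) - 1L) * 10000L + 1L,
                            end = (seq_len(n_g) - 1L) * 10000L + 5000L,
                            stringsAsFactors = FALSE)

  # probe table: promoter regions with occasional fallback structure,
  # plus body probes that downstream gene-level averaging must ignore
  n200 <- sample(0:2, n_g, replace = TRUE, prob = c(0.2, 0.5, 0.3))
  nfe <- sample(0:1, n_g, replace = TRUE)
  n1500 <- sample(1:2, n_g, replace = TRUE)
  nbody <- sample(0:2, n_g, replace = TRUE, prob = c(0.3, 0.4, 0.3))
  reg <- rep(rep(c("TSS200", "FirstExon", "TSS1500", "Body"), n_g),
             times = as.vector(rbind(n200, nfe, n1500, nbody)))
  pgene <- rep(rep(genes, each = 4),
               times = as.vector(rbind(n200, nfe, n1500, nbody)))
  probes <- data.frame(
    probe_id = sprintf("cg%06d", seq_along(pgene)), gene = pgene,
    region = reg, chrom = "chr1",
    pos = gene_coords$start[match(pgene, genes)] +
      ifelse(reg == "Body", 2500L, sample(0:200, length(pgene),
                                          replace = TRUE)),
    stringsAsFactors = FALSE)

  # methylation: logit-normal noise around group means
  mu_prom <- stats::runif(n_g, 0.15, 0.6)
  mu_body <- stats::runif(n_g, 0.35, 0.65)
  shift <- numeric(n_g)
  names(mu_prom) <- names(mu_body) <- names(shift) <- genes
  # planted genes get baselines for which the shift stays inside [0, 1]
  if (length(truth$hyperm))
    mu_prom[truth$hyperm] <- stats::runif(length(truth$hyperm), 0.1,
                                          max(0.15, 0.9 - pl$delta_beta))
  if (length(truth$hypom))
    mu_prom[truth$hypom] <- stats::runif(length(truth$hypom),
                                         min(0.85, pl$delta_beta + 0.1), 0.9)
  shift[truth$hyperm] <- pl$delta_beta
  shift[truth$hypom] <- -pl$delta_beta
  body_drift <- numeric(n_g)
  drift_idx <- sample.int(n_g, max(1, round(0.1 * n_g)))
  body_drift[drift_idx] <- sample(c(-0.3, 0.3), length(drift_idx),
                                  replace = TRUE)
  names(body_drift) <- genes

  is_body <- probes$region == "Body"
  base_mean <- ifelse(is_body, mu_body[probes$gene], mu_prom[probes$gene])
  tum_shift <- ifelse(is_body, body_drift[probes$gene], shift[probes$gene])
  tum_mean <- base_mean + tum_shift
  if (any(tum_mean < 0 | tum_mean > 1)) {
    warning("planted beta means clipped to [0, 1]")
    tum_mean <- pmin(pmax(tum_mean, 0.001), 0.999)
  }
  mean_mat <- outer(base_mean, rep(1, n_s))
  mean_mat[, tumor] <- tum_mean
  beta <- stats::plogis(stats::qlogis(pmin(pmax(mean_mat, 0.001), 0.999)) +
                          matrix(stats::rnorm(length(mean_mat),
                                              sd = config$noise$beta_logit_sd),
                                 nrow(mean_mat)))
  dimnames(beta) <- list(probes$probe_id, samples$sample_id)
  # missingness: light scatter plus a few mostly-missing probes
  if (config$noise$na_frac > 0) {
    beta[matrix(stats::runif(length(beta)) < config$noise$na_frac,
                nrow(beta))] <- NA
  }
  n_high <- round(config$noise$high_na_frac_probes * nrow(beta))
  if (n_high > 0) {
    hi <- sample.int(nrow(beta), n_high)
    for (r in hi) beta[r, sample.int(n_s, ceiling(0.4 * n_s))] <- NA
  }

  # expression on log2 scale, emitted raw (2^x) for the normalizer
  base_expr <- stats::rnorm(n_g, 8, 2)
  names(base_expr) <- genes
  eshift <- numeric(n_g)
  names(eshift) <- genes
  eshift[truth$hyperm] <- -pl$log2fc
  eshift[truth$hypom] <- pl$log2fc
  log2e <- outer(base_expr, rep(1, n_s)) +
    matrix(stats::rnorm(n_g * n_s, sd = config$noise$expr_sd), n_g)
  log2e[, tumor] <- log2e[, tumor] + outer(eshift, rep(1, sum(tumor)))

  # copy number: background segmentation noise plus planted event
  # segments; matching expression shift in exactly the event samples
  tum_ids <- samples$sample_id[tumor]
  ev_amp <- matrix(stats::runif(length(truth$amplification) *
                                  length(tum_ids)) < pl$cn_event_frac,
                   nrow = length(truth$amplification),
                   ncol = length(tum_ids),
                   dimnames = list(truth$amplification, tum_ids))
  ev_del <- matrix(stats::runif(length(truth$deletion) *
                                  length(tum_ids)) < pl$cn_event_frac,
                   nrow = length(truth$deletion), ncol = length(tum_ids),
                   dimnames = list(truth$deletion, tum_ids))
  chrom_len <- n_g * 10000L
  seg_list <- list()
  for (s in tum_ids) {
    bp <- sort(sample.int(chrom_len - 1, 20))
    st <- c(1L, bp + 1L)
    en <- c(bp, chrom_len)
    seg_list[[s]] <- data.frame(
      sample = s, chrom = "chr1", start = st, end = en,
      num_probes = pmax(4L, as.integer(round((en - st + 1) / 5000))),
      seg_mean = stats::rnorm(length(st), 0, config$noise$seg_sd),
      stringsAsFactors = FALSE)
    add_events <- function(ev, sign) {
      gsel <- rownames(ev)[ev[, s]]
      if (!length(gsel)) return(NULL)
      i <- match(gsel, genes)
      data.frame(sample = s, chrom = "chr1", start = gene_coords$start[i],
                 end = gene_coords$end[i],
                 num_probes = 10L,
                 seg_mean = sign * (pl$cn_shift +
                                      stats::rnorm(length(i), 0, 0.05)),
                 stringsAsFactors = FALSE)
    }
    seg_list[[s]] <- rbind(seg_list[[s]], add_events(ev_amp, 1),
                           add_events(ev_del, -1))
  }
  segments <- do.call(rbind, seg_list)
  segments <- segments[order(segments$sample, segments$start, segments$end), ]
  rownames(segments) <- NULL
  for (g in truth$amplification) {
    log2e[g, match(colnames(ev_amp)[ev_amp[g, ]], samples$sample_id)] <-
      log2e[g, match(colnames(ev_amp)[ev_amp[g, ]], samples$sample_id)] +
      pl$log2fc
  }
  for (g in truth$deletion) {
    log2e[g, match(colnames(ev_del)[ev_del[g, ]], samples$sample_id)] <-
      log2e[g, match(colnames(ev_del)[ev_del[g, ]], samples$sample_id)] -
      pl$log2fc
  }
  expr_raw <- 2^log2e
  dimnames(expr_raw) <- list(genes, samples$sample_id)

  # mutations: background rate everywhere, planted rate on Mutation set
  bg_hits <- which(matrix(stats::runif(n_g * length(tum_ids)) < 0.01,
                          n_g), arr.ind = TRUE)
  classes <- sample(c("Missense_Mutation", "Nonsense_Mutation", "Silent"),
                    nrow(bg_hits), replace = TRUE, prob = c(0.6, 0.2, 0.2))
  mut <- data.frame(Hugo_Symbol = genes[bg_hits[, 1]],
                    Tumor_Sample_Barcode = tum_ids[bg_hits[, 2]],
                    Variant_Classification = classes,
                    stringsAsFactors = FALSE)
  pl_hits <- which(matrix(stats::runif(length(truth$mutation) *
                                         length(tum_ids)) <
                            pl$mutation_rate,
                          length(truth$mutation)), arr.ind = TRUE)
  if (nrow(pl_hits)) {
    mut <- rbind(mut, data.frame(
      Hugo_Symbol = truth$mutation[pl_hits[, 1]],
      Tumor_Sample_Barcode = tum_ids[pl_hits[, 2]],
      Variant_Classification = "Missense_Mutation",
      stringsAsFactors = FALSE))
  }
  mut <- mut[order(mut$Hugo_Symbol, mut$Tumor_Sample_Barcode,
                   mut$Variant_Classification), ]
  rownames(mut) <- NULL

  list(beta = beta, probes = probes, expr_raw = expr_raw,
       segments = segments, mutations = mut, samples = samples,
       gene_coords = gene_coords, truth = truth, config = config)
}

#' Generate a synthetic pathway collection over network genes
#'
#' @param net interactome.
#' @param n_pathways number of gene sets (default 20).
#' @param min_size,max_size pathway size range (defaults 80, 150).
#' @param seed RNG seed.
#' @return named list of gene identifier vectors.
#' @export
generate_pathways <- function(net, n_pathways = 20, min_size = 80,
                              max_size = 150, seed = 1) {
  set.seed(seed)
  genes <- igraph::V(net)$name
  sets <- lapply(seq_len(n_pathways), function(i) {
    sort(sample(genes, sample(min_size:max_size, 1)))
  })
  names(sets) <- sprintf("PATHWAY_%02d", seq_len(n_pathways))
  sets
}

#' Simulate altered gene sets with one EC-biased pathway planted
#'
#' For each synthetic cancer type, draws DNAm-altered and SCNA-altered
#' gene sets at a uniform background rate; within the designated
#' pathway, EC-labeled genes are DNAm-altered at an elevated rate,
#' planting the differential signaling-domain pattern the pathway
#' meta-analysis is designed to detect.
#'
#' @param pathways named list of pathway gene vectors.
#' @param coarse named coarse-domain vector (gene universe).
#' @param planted_pathway name of the pathway carrying the signal.
#' @param n_types number of synthetic cancer types (default 5).
#' @param base_rate background alteration probability (default 0.25).
#' @param planted_rate DNAm alteration probability for EC genes of the
#'   planted pathway (default 0.7).
#' @param seed RNG seed.
#' @return list per type of lists with `dnam` and `scna` gene vectors.
#' @export
simulate_pathway_alterations <- function(pathways, coarse, planted_pathway,
                                         n_types = 5, base_rate = 0.25,
                                         planted_rate = 0.7, seed = 1) {
  stopifnot(planted_pathway %in% names(pathways))
  set.seed(seed)
  genes <- names(coarse)
  ec_planted <- intersect(pathways[[planted_pathway]],
                          genes[coarse == "EC"])
  out <- lapply(seq_len(n_types), function(i) {
    p_dnam <- rep(base_rate, length(genes))
    names(p_dnam) <- genes
    p_dnam[ec_planted] <- planted_rate
    list(dnam = genes[stats::runif(length(genes)) < p_dnam],
         scna = genes[stats::runif(length(genes)) < base_rate])
  })
  names(out) <- sprintf("TYPE%02d", seq_len(n_types))
  out
}

#' Write a synthetic cohort and interactome to plain-text files
#'
#' Emits beta matrix, probe annotation, raw expression, SEG, MAF,
#' sample sheet, gene coordinates, SIF edge list, localization table
#' and ground-truth JSON (plus the config as YAML) into `dir`. Output
#' bytes are a deterministic function of the cohort object.
#'
#' @param cohort from [generate_cohort()].
#' @param net from [generate_interactome()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_matrix_tsv(cohort$beta, p("beta.tsv"), id_col = "probe_id")
  write_df_tsv(cohort$probes, p("probes.tsv"))
  write_matrix_tsv(cohort$expr_raw, p("expression.tsv"), id_col = "gene")
  write_df_tsv(cohort$segments, p("segments.seg.tsv"))
  write_df_tsv(cohort$mutations, p("mutations.maf.tsv"))
  write_df_tsv(cohort$samples, p("samples.tsv"))
  write_df_tsv(cohort$gene_coords, p("gene_coords.tsv"))
  el <- igraph::as_edgelist(net)
  write_df_tsv(data.frame(geneA = el[, 1], geneB = el[, 2]), p("edges.sif.tsv"))
  write_df_tsv(data.frame(gene = igraph::V(net)$name,
                          term = igraph::V(net)$term), p("localization.tsv"))
  truth <- cohort$truth
  truth$domains <- NULL
  jsonlite::write_json(truth, p("ground_truth.json"), pretty = TRUE)
  cfg <- unclass(cohort$config)
  cfg$domain_fractions <- as.list(cfg$domain_fractions)
  yaml::write_yaml(cfg, p("config.yaml"))
  invisible(dir)
}
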