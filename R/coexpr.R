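#' Per-gene deregulation categories across cancer types
#'
#' Classifies each gene, in each cancer type, as HyperM_F (significant
#' promoter hypermethylation with significant underexpression),
#' HyperM_NF (hypermethylation without the expression change), HypoM_F,
#' HypoM_NF, or NC (no significant methylation change). Significance
#' uses the driver-calling thresholds.
#'
#' @param stats_by_type named list (per cancer type) of [diff_stats()]
#'   data frames.
#' @param fdr_max,min_delta_beta,min_abs_log2fc thresholds (defaults
#'   0.05, 0.1, 1).
#' @return genes x cancer-types character matrix (NA where a gene is
#'   unmeasured in a type).
#' @export
categorize_deregulation <- function(stats_by_type, fdr_max = 0.05,
                                    min_delta_beta = 0.1,
                                    min_abs_log2fc = 1) {
  genes <- sort(unique(unlist(lapply(stats_by_type, `[[`, "gene"))))
  out <- matrix(NA_character_, length(genes), length(stats_by_type),
                dimnames = list(genes, names(stats_by_type)))
  for (ty in names(stats_by_type)) {
    st <- stats_by_type[[ty]]
    hyper <- st$fdr_meth < fdr_max & st$delta_beta > min_delta_beta
    hypo <- st$fdr_meth < fdr_max & st$delta_beta < -min_delta_beta
    under <- st$fdr_expr < fdr_max & st$log2fc < -min_abs_log2fc
    over <- st$fdr_expr < fdr_max & st$log2fc > min_abs_log2fc
    cat <- ifelse(hyper & under, "HyperM_F",
                  ifelse(hyper, "HyperM_NF",
                         ifelse(hypo & over, "HypoM_F",
                                ifelse(hypo, "HypoM_NF", "NC"))))
    out[st$gene, ty] <- cat
  }
  out
}

#' Permutation test for cross-cancer consistency of deregulation
#' categories
#'
#' The observed statistic is the mean, over cancer-type pairs, of the
#' fraction of genes with identical category (over genes measured in
#' both types). The null permutes gene labels independently within each
#' cancer type, preserving per-type category frequencies;
#' p = (1 + #\{perm >= observed\}) / (n_perm + 1).
#'
#' @param categories matrix from [categorize_deregulation()].
#' @param n_perm number of permutations (default 1000).
#' @param seed optional RNG seed.
#' @return list: `observed`, `p`, `n_perm`, `at_floor` (TRUE when no
#'   permutation reached the observed value, so p is the attainable
#'   floor and should be read as "<=").
#' @export
consistency_empirical_p <- function(categories, n_perm = 1000, seed = NULL) {
  stopifnot(ncol(categories) >= 2, nrow(categories) >= 2)
  # canonical column order so the result is invariant to how the
  # cancer types were supplied
  categories <- categories[, order(colnames(categories)), drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  agree_stat <- function(m) {
    k <- ncol(m)
    tot <- 0
    np <- 0
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      ok <- !is.na(m[, i]) & !is.na(m[, j])
      if (!any(ok)) next
      tot <- tot + mean(m[ok, i] == m[ok, j])
      np <- np + 1
    }
    if (np == 0) NA_real_ else tot / np
  }
  obs <- agree_stat(categories)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- apply(categories, 2, sample)
    if (agree_stat(perm) >= obs) exceed <- exceed + 1L
  }
  p <- (1 + exceed) / (n_perm + 1)
  list(observed = obs, p = p, n_perm = n_perm, at_floor = exceed == 0L)
}

#' Tumor-only correlation of target genes with epigenetic-enzyme genes
#'
#' Pearson correlation (and two-sided p) of each target gene's tumor
#' expression with each enzyme gene, per cancer type. A target is
#' labeled `positive` for an enzyme when r > 0 with p < `p_max` in at
#' least half of the cancer types with data and no type shows a
#' significant negative correlation; `negative` is mirrored; otherwise
#' `none`. Zero-variance vectors give NA cells excluded from the rule.
#'
#' @param expr_by_type named list (per cancer type) of genes x tumor-
#'   samples log2 expression matrices (>= 10 tumor samples each).
#' @param targets target gene identifiers.
#' @param enzymes enzyme gene identifiers (default DNMT1, EZH2).
#' @param p_max per-type significance threshold (default 0.05).
#' @return list: `correlations` long data frame (target, enzyme,
#'   cancer_type, r, p) and `labels` data frame (target, enzyme, label).
#' @export
enzyme_correlation <- function(expr_by_type, targets,
                               enzymes = c("DNMT1", "EZH2"), p_max = 0.05) {
  stopifnot(all(vapply(expr_by_type, ncol, 0L) >= 10))
  rows <- list()
  for (ty in names(expr_by_type)) {
    ex <- expr_by_type[[ty]]
    for (en in enzymes) {
      if (!(en %in% rownames(ex))) next
      ev <- ex[en, ]
      for (tg in targets) {
        r <- p <- NA_real_
        if (tg %in% rownames(ex)) {
          tv <- ex[tg, ]
          if (stats::sd(tv) > 0 && stats::sd(ev) > 0) {
            ct <- stats::cor.test(tv, ev, method = "pearson")
            r <- unname(ct$estimate)
            p <- ct$p.value
          }
        }
        rows[[length(rows) + 1]] <- data.frame(
          target = tg, enzyme = en, cancer_type = ty, r = r, p = p,
          stringsAsFactors = FALSE)
      }
    }
  }
  cor_df <- do.call(rbind, rows)
  labels <- do.call(rbind, lapply(unique(cor_df$target), function(tg) {
    do.call(rbind, lapply(enzymes, function(en) {
      d <- cor_df[cor_df$target == tg & cor_df$enzyme == en & !is.na(cor_df$r), ]
      n <- nrow(d)
      pos <- sum(d$r > 0 & d$p < p_max)
      neg <- sum(d$r < 0 & d$p < p_max)
      lab <- if (n == 0) "none"
      else if (pos >= ceiling(n / 2) && neg == 0) "positive"
      else if (neg >= ceiling(n / 2) && pos == 0) "negative"
      else "none"
      data.frame(target = tg, enzyme = en, label = lab,
                 stringsAsFactors = FALSE)
    }))
  }))
  list(correlations = cor_df, labels = labels)
}
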