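#' Moderated two-sample t-statistics with an empirical Bayes variance
#'
#' Per-gene two-sample t-statistics in which the residual variance is
#' shrunk toward a common prior: the posterior variance is
#' \eqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)}, where the
#' prior degrees of freedom \eqn{d_0} and prior variance \eqn{s_0^2} are
#' method-of-moments fits of a scaled inverse-chi-square distribution to
#' the observed per-gene pooled variances (marginally,
#' \eqn{s_g^2 \sim s_0^2 F_{d_g, d_0}}). P-values come from a t
#' distribution on \eqn{d_g + d_0} degrees of freedom. Positive t means
#' tumor above normal.
#'
#' @param x genes x samples numeric matrix.
#' @param group character/factor per column, values `"normal"`/`"tumor"`.
#' @param d0,s0sq optional prior overrides; `d0 = 0` recovers the
#'   ordinary two-sample t.
#' @return data frame with gene, t, p, df, and the prior (d0, s0sq) used.
#' @export
moderated_t <- function(x, group, d0 = NULL, s0sq = NULL) {
  stopifnot(is.matrix(x), ncol(x) == length(group))
  group <- as.character(group)
  stopifnot(all(group %in% c("normal", "tumor")))
  n1 <- sum(group == "tumor")
  n2 <- sum(group == "normal")
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per group")
  if (nrow(x) < 2) stop("need >= 2 genes for variance pooling")

  xt <- x[, group == "tumor", drop = FALSE]
  xn <- x[, group == "normal", drop = FALSE]
  m1 <- rowMeans(xt)
  m2 <- rowMeans(xn)
  ssq <- (rowSums((xt - m1)^2) + rowSums((xn - m2)^2))
  dg <- n1 + n2 - 2
  s2 <- ssq / dg

  if (all(s2 == 0)) {
    warning("zero residual variance in all genes; falling back to ordinary t")
    d0 <- 0
  }
  if (is.null(d0)) {
    m <- mean(s2)
    v <- stats::var(s2)
    r <- v / m^2                       # squared coefficient of variation
    if (!is.finite(r) || r * dg <= 2 + 1e-12) {
      d0 <- 1e6                        # no excess dispersion: full pooling
    } else {
      d0 <- (4 * r * dg + 2 * dg - 4) / (r * dg - 2)
    }
    if (is.null(s0sq)) s0sq <- if (d0 > 2) m * (d0 - 2) / d0 else m
  } else if (is.null(s0sq)) {
    s0sq <- if (d0 > 0) mean(s2) else 0
  }

  s2_post <- if (d0 == 0) s2 else (d0 * s0sq + dg * s2) / (d0 + dg)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  t[se == 0 & m1 == m2] <- 0
  df <- dg + d0
  p <- 2 * stats::pt(-abs(t), df = df)
  data.frame(gene = rownames(x), t = t, p = p, df = df,
             d0 = d0, s0sq = s0sq, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Differential methylation and expression statistics per gene
#'
#' Runs [moderated_t()] on the gene-level methylation and log2
#' expression matrices over the genes shared by both, and attaches the
#' tumor-minus-normal mean differences and Benjamini-Hochberg FDRs
#' (computed within each data type).
#'
#' @param meth genes x samples gene-level beta matrix.
#' @param expr genes x samples log2 expression matrix (same samples).
#' @param group per-column group labels (`"normal"`/`"tumor"`).
#' @return data frame: gene, t_meth, t_expr, p_meth, p_expr, fdr_meth,
#'   fdr_expr, delta_beta, log2fc.
#' @export
diff_stats <- function(meth, expr, group) {
  stopifnot(ncol(meth) == ncol(expr), ncol(meth) == length(group))
  genes <- sort(intersect(rownames(meth), rownames(expr)))
  if (!length(genes)) stop("no genes shared between methylation and expression")
  meth <- meth[genes, , drop = FALSE]
  expr <- expr[genes, , drop = FALSE]
  tm <- moderated_t(meth, group)
  te <- moderated_t(expr, group)
  tum <- group == "tumor"
  data.frame(
    gene = genes,
    t_meth = tm$t, t_expr = te$t,
    p_meth = tm$p, p_expr = te$p,
    fdr_meth = stats::p.adjust(tm$p, "BH"),
    fdr_expr = stats::p.adjust(te$p, "BH"),
    delta_beta = rowMeans(meth[, tum, drop = FALSE]) -
      rowMeans(meth[, !tum, drop = FALSE]),
    log2fc = rowMeans(expr[, tum, drop = FALSE]) -
      rowMeans(expr[, !tum, drop = FALSE]),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Select genes differential in both methylation and expression
#'
#' Keeps genes with methylation FDR below `fdr_max` and absolute mean
#' beta difference above `min_delta_beta`, and expression FDR below
#' `fdr_max` with absolute log2 fold change above `min_abs_log2fc`.
#'
#' @param stats data frame from [diff_stats()].
#' @param fdr_max FDR threshold (default 0.05).
#' @param min_delta_beta minimum |tumor - normal| mean beta (default 0.1).
#' @param min_abs_log2fc minimum |log2 fold change| (default 1).
#' @return subset of `stats`.
#' @export
call_dnam_de <- function(stats, fdr_max = 0.05, min_delta_beta = 0.1,
                         min_abs_log2fc = 1) {
  keep <- stats$fdr_meth < fdr_max & abs(stats$delta_beta) > min_delta_beta &
    stats$fdr_expr < fdr_max & abs(stats$log2fc) > min_abs_log2fc
  stats[keep, , drop = FALSE]
}

#' Classify anti-correlated genes as HyperM/HypoM and rank them
#'
#' Genes with positive methylation t and negative expression t are
#' hypermethylated/underexpressed (HyperM); the mirror image is HypoM;
#' genes whose two t-statistics share a sign are discarded. Within each
#' class, genes are ranked by the integrative score
#' \eqn{S = (|t_{meth}| + |t_{expr}|)/2}, non-increasing; ties are
#' broken by larger |t_expr|, then lexicographic gene identifier.
#'
#' @param stats data frame of [call_dnam_de()] survivors.
#' @return data frame: gene, class, score, rank, t_meth, t_expr,
#'   delta_beta, log2fc.
#' @export
classify_and_rank <- function(stats) {
  empty <- data.frame(gene = character(0), class = character(0),
                      score = numeric(0), rank = integer(0),
                      t_meth = numeric(0), t_expr = numeric(0),
                      delta_beta = numeric(0), log2fc = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nrow(stats)) return(empty)
  cls <- ifelse(stats$t_meth > 0 & stats$t_expr < 0, "HyperM",
                ifelse(stats$t_meth < 0 & stats$t_expr > 0, "HypoM", NA))
  stats <- stats[!is.na(cls), , drop = FALSE]
  cls <- cls[!is.na(cls)]
  if (!nrow(stats)) return(empty)
  score <- (abs(stats$t_meth) + abs(stats$t_expr)) / 2
  out <- data.frame(gene = stats$gene, class = cls, score = score,
                    t_meth = stats$t_meth, t_expr = stats$t_expr,
                    delta_beta = stats$delta_beta, log2fc = stats$log2fc,
                    stringsAsFactors = FALSE)
  pieces <- lapply(split(out, out$class), function(d) {
    d <- d[order(-d$score, -abs(d$t_expr), d$gene), , drop = FALSE]
    d$rank <- seq_len(nrow(d))
    d
  })
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  res[, c("gene", "class", "score", "rank", "t_meth", "t_expr",
          "delta_beta", "log2fc")]
}

#' Multivariate regression filter of expression on methylation and CNV
#'
#' Per gene, ordinary least squares of log2 expression on gene-level
#' methylation and numeric copy-number state over all (normal and tumor)
#' samples. For methylation-driven lists, genes are kept when the
#' methylation coefficient is negative and significant; for copy-number
#' lists, when the CNV coefficient is positive and significant. A
#' constant covariate of interest makes the coefficient undefined and
#' drops the gene with a warning; a constant nuisance covariate is
#' simply omitted from the model.
#'
#' @param expr genes x samples log2 expression matrix.
#' @param meth genes x samples gene-level beta matrix (may lack genes).
#' @param cn_state genes x samples numeric copy-number states in
#'   -2..2 (normal samples 0); may be NULL for purely DNAm designs.
#' @param genes genes to test.
#' @param class `"dnam"` (keep coef_dnam < 0, p < p_max) or `"cnv"`
#'   (keep coef_cnv > 0, p < p_max).
#' @param p_max significance threshold (default 0.05).
#' @return data frame: gene, coef_dnam, coef_cnv, p_dnam, p_cnv, kept.
#' @export
multivariate_filter <- function(expr, meth, cn_state, genes,
                                class = c("dnam", "cnv"), p_max = 0.05) {
  class <- match.arg(class)
  res <- lapply(genes, function(g) {
    if (!(g %in% rownames(expr))) return(NULL)
    y <- expr[g, ]
    mv <- if (!is.null(meth) && g %in% rownames(meth)) meth[g, ] else NULL
    cv <- if (!is.null(cn_state) && g %in% rownames(cn_state))
      cn_state[g, ] else NULL
    if (!is.null(mv) && stats::sd(mv) == 0) mv <- NULL
    if (!is.null(cv) && stats::sd(cv) == 0) cv <- NULL
    covs <- list(dnam = mv, cnv = cv)
    covs <- covs[!vapply(covs, is.null, TRUE)]
    out <- c(coef_dnam = NA_real_, coef_cnv = NA_real_,
             p_dnam = NA_real_, p_cnv = NA_real_)
    if (length(covs)) {
      df <- data.frame(y = y, covs)
      cf <- summary(stats::lm(y ~ ., data = df))$coefficients
      for (term in names(covs)) {
        if (term %in% rownames(cf)) {
          out[paste0("coef_", term)] <- cf[term, 1]
          out[paste0("p_", term)] <- cf[term, 4]
        }
      }
    }
    data.frame(gene = g, t(out), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res) || !nrow(res)) {
    return(data.frame(gene = character(0), coef_dnam = numeric(0),
                      coef_cnv = numeric(0), p_dnam = numeric(0),
                      p_cnv = numeric(0), kept = logical(0)))
  }
  if (class == "dnam") {
    undef <- is.na(res$coef_dnam)
    res$kept <- !undef & res$coef_dnam < 0 & res$p_dnam < p_max
  } else {
    undef <- is.na(res$coef_cnv)
    res$kept <- !undef & res$coef_cnv > 0 & res$p_cnv < p_max
  }
  if (any(undef))
    warning(sum(undef), " gene(s) dropped: constant ", class, " covariate")
  rownames(res) <- NULL
  res
}

#' Epigenetically regulated tissue-specific gene lists
#'
#' Same machinery as the tumor/normal comparison, but contrasting the
#' normals of one tissue against pooled normals of the other tissues,
#' with stricter effect-size thresholds: |mean beta difference| > 0.3
#' and |log2 fold change| > 2 (both at FDR < `fdr_max`); the
#' opposite-sign (anti-correlation) constraint applies.
#'
#' @param meth,expr gene-level matrices over normal samples only.
#' @param tissue logical/character: which columns belong to the focal
#'   tissue (treated as the "tumor" side of the contrast so that
#'   positive t means focal tissue above the rest).
#' @param fdr_max FDR threshold (default 0.05).
#' @param min_delta_beta effect threshold on beta (default 0.3).
#' @param min_abs_log2fc effect threshold on log2 expression (default 2).
#' @return ranked data frame as [classify_and_rank()]; classes label
#'   tissue-specific hyper-/hypomethylation.
#' @export
tissue_specific_genes <- function(meth, expr, tissue, fdr_max = 0.05,
                                  min_delta_beta = 0.3, min_abs_log2fc = 2) {
  if (!is.logical(tissue)) tissue <- seq_len(ncol(meth)) %in% tissue
  if (sum(tissue) < 2 || sum(!tissue) < 2)
    stop("need >= 2 samples on each side of the tissue contrast")
  group <- ifelse(tissue, "tumor", "normal")
  st <- diff_stats(meth, expr, group)
  sig <- call_dnam_de(st, fdr_max = fdr_max, min_delta_beta = min_delta_beta,
                      min_abs_log2fc = min_abs_log2fc)
  classify_and_rank(sig)
}
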