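#' Per-sample copy-number calling thresholds
#'
#' For each sample, the center `m` is the (probe-weighted) median of the
#' segment log2 ratios, and the noise scale `sigma` is the standard
#' deviation of the 50% of segment values nearest `m` (weights from
#' `num_probes` when present). Gains/losses are called beyond
#' `m +/- 2 sigma`, amplifications/deletions beyond `m +/- 4 sigma`.
#'
#' @param segments SEG-like data frame (sample, chrom, start, end,
#'   seg_mean, optional num_probes).
#' @return data frame: sample, m, sigma, gain, loss, amp, del.
#' @export
cn_thresholds <- function(segments) {
  stopifnot(all(c("sample", "seg_mean") %in% names(segments)))
  w_all <- if ("num_probes" %in% names(segments))
    segments$num_probes else rep(1, nrow(segments))
  out <- lapply(split(seq_len(nrow(segments)), segments$sample), function(idx) {
    v <- segments$seg_mean[idx]
    w <- w_all[idx]
    if (length(v) < 4) stop("need >= 4 segment values per sample")
    m <- weighted_median(v, w)
    # noise half: the 50% of weight closest to the center
    ord <- order(abs(v - m))
    cum <- cumsum(w[ord])
    take <- ord[cum <= sum(w) / 2]
    if (length(take) < 2) take <- ord[1:2]
    sigma <- sqrt(weighted_ss(v[take], w[take]))
    if (sigma == 0)
      warning("zero noise scale; all calls will be Neutral for sample ",
              segments$sample[idx[1]])
    data.frame(sample = segments$sample[idx[1]], m = m, sigma = sigma,
               gain = m + 2 * sigma, loss = m - 2 * sigma,
               amp = m + 4 * sigma, del = m - 4 * sigma,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

weighted_median <- function(v, w) {
  ord <- order(v)
  v <- v[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  i <- which(cw >= 0.5)[1]
  if (abs(cw[i] - 0.5) < 1e-12 && i < length(v)) (v[i] + v[i + 1]) / 2 else v[i]
}

weighted_ss <- function(v, w) {
  mu <- sum(w * v) / sum(w)
  if (sum(w) <= 1) return(0)
  sum(w * (v - mu)^2) / (sum(w) - 1)
}

#' Copy-number state of one segment value against sample thresholds
#' @keywords internal
segment_state <- function(v, thr) {
  ifelse(v > thr$amp, 2L,
         ifelse(v > thr$gain, 1L,
                ifelse(v < thr$del, -2L,
                       ifelse(v < thr$loss, -1L, 0L))))
}

#' Build the patient-by-gene copy-number call matrix
#'
#' For each (sample, gene), all segments overlapping the gene (1-based
#' inclusive intervals, any >= 1 bp intersection) are collected and the
#' state of maximal severity (Neutral < Gain/Loss < Amplification/
#' Deletion) is assigned; severity ties between loss-type and gain-type
#' states are broken by the larger absolute segmented mean. Genes with
#' no overlapping segment are Neutral.
#'
#' @param segments SEG-like data frame.
#' @param thresholds from [cn_thresholds()].
#' @param gene_coords data frame (gene, chrom, start, end).
#' @return samples x genes integer matrix with values in -2..2.
#' @export
build_call_matrix <- function(segments, thresholds, gene_coords) {
  samples <- thresholds$sample
  genes <- gene_coords$gene
  calls <- matrix(0L, length(samples), length(genes),
                  dimnames = list(samples, genes))
  thr_idx <- match(segments$sample, thresholds$sample)
  states <- integer(nrow(segments))
  for (i in seq_len(nrow(thresholds))) {
    sel <- which(thr_idx == i)
    states[sel] <- segment_state(segments$seg_mean[sel], thresholds[i, ])
  }
  hit <- segments$sample %in% samples & states != 0L
  seg <- segments[hit, , drop = FALSE]
  seg$state <- states[hit]
  if (!nrow(seg)) return(calls)

  for (ch in unique(seg$chrom)) {
    gsel <- gene_coords$chrom == ch
    ssel <- seg$chrom == ch
    if (!any(gsel) || !any(ssel)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(gene_coords$start[gsel], gene_coords$end[gsel]),
      IRanges::IRanges(seg$start[ssel], seg$end[ssel]))
    if (!length(ov)) next
    gi <- which(gsel)[S4Vectors::queryHits(ov)]
    si <- which(ssel)[S4Vectors::subjectHits(ov)]
    df <- data.frame(row = match(seg$sample[si], samples), col = gi,
                     state = seg$state[si], mean = seg$seg_mean[si])
    # maximal severity first; within severity, larger |seg_mean| decides
    df <- df[order(df$row, df$col, -abs(df$state), -abs(df$mean)), ]
    first <- !duplicated(df[, c("row", "col")])
    calls[cbind(df$row[first], df$col[first])] <- df$state[first]
  }
  calls
}

#' Flag expression outliers from a per-gene Gaussian fit
#'
#' Per gene, a normal distribution is fitted by maximum likelihood over
#' all samples; samples below the 5% left tail
#' (value < mean - 1.6449 sd) are flagged underexpressed (-1), above the
#' 5% right tail overexpressed (+1), else 0. Genes with zero variance
#' get no calls.
#'
#' @param expr genes x samples log2 expression matrix.
#' @param tail upper-tail probability defining the flags (default 0.05).
#' @return genes x samples integer matrix in \{-1, 0, 1\}.
#' @export
expression_tail_calls <- function(expr, tail = 0.05) {
  stopifnot(is.matrix(expr), ncol(expr) >= 3)
  z <- stats::qnorm(1 - tail)
  mu <- rowMeans(expr)
  sd_mle <- sqrt(rowMeans((expr - mu)^2))
  lo <- mu - z * sd_mle
  hi <- mu + z * sd_mle
  flags <- matrix(0L, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  ok <- sd_mle > 0                       # row masks recycle down columns
  flags[ok & expr < lo] <- -1L
  flags[ok & expr > hi] <- 1L
  flags
}

#' Rank genes by joint copy-number and expression events
#'
#' Builds the Amplification/Overexpression and Deletion/Underexpression
#' binary matrices (state Amplification AND over-flag, resp. Deletion
#' AND under-flag), keeps genes with at least one joint event, and ranks
#' by event count descending (ties lexicographic). When expression and
#' methylation matrices are supplied, lists are additionally gated by
#' the multivariate regression filter (positive, significant CNV
#' coefficient).
#'
#' @param calls samples x genes call matrix from [build_call_matrix()].
#' @param tails genes x samples flags from [expression_tail_calls()]
#'   (tumor samples; columns matching `rownames(calls)`).
#' @param expr,meth,cn_state optional matrices over all samples for the
#'   multivariate filter (see [multivariate_filter()]).
#' @param p_max filter significance threshold.
#' @return list with `amplification` and `deletion` ranked data frames
#'   (gene, count, rank).
#' @export
rank_scna_genes <- function(calls, tails, expr = NULL, meth = NULL,
                            cn_state = NULL, p_max = 0.05) {
  genes <- intersect(colnames(calls), rownames(tails))
  samples <- intersect(rownames(calls), colnames(tails))
  cm <- calls[samples, genes, drop = FALSE]
  tf <- t(tails[genes, samples, drop = FALSE])
  one_list <- function(joint, cls) {
    cnt <- colSums(joint)
    cnt <- cnt[cnt >= 1]
    g <- names(cnt)[order(-cnt, names(cnt))]
    cnt <- cnt[g]
    if (length(g) && !is.null(expr)) {
      mv <- multivariate_filter(expr, meth, cn_state, g, class = "cnv",
                                p_max = p_max)
      keep <- mv$gene[mv$kept]
      cnt <- cnt[names(cnt) %in% keep]
    }
    data.frame(gene = names(cnt), count = as.integer(cnt),
               rank = seq_along(cnt), row.names = NULL,
               stringsAsFactors = FALSE)
  }
  list(amplification = one_list(cm == 2L & tf == 1L, "Amplification"),
       deletion = one_list(cm == -2L & tf == -1L, "Deletion"))
}

#' Rank genes by mutation frequency
#'
#' Counts, per gene, the distinct samples carrying at least one
#' non-silent mutation record and ranks by count descending (ties
#' lexicographic). Genes with only silent records are excluded.
#'
#' @param muts MAF-like data frame (Hugo_Symbol, Tumor_Sample_Barcode,
#'   Variant_Classification).
#' @param silent_classes variant classes ignored (default `"Silent"`).
#' @return data frame: gene, count, rank.
#' @export
rank_mutated_genes <- function(muts, silent_classes = "Silent") {
  keep <- !(muts$Variant_Classification %in% silent_classes)
  muts <- muts[keep, , drop = FALSE]
  if (!nrow(muts)) {
    return(data.frame(gene = character(0), count = integer(0),
                      rank = integer(0)))
  }
  pairs <- unique(muts[, c("Hugo_Symbol", "Tumor_Sample_Barcode")])
  cnt <- table(pairs$Hugo_Symbol)
  g <- names(cnt)[order(-as.integer(cnt), names(cnt))]
  data.frame(gene = g, count = as.integer(cnt[g]), rank = seq_along(g),
             row.names = NULL, stringsAsFactors = FALSE)
}
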