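#' Filter and impute a probe-level methylation beta matrix
#'
#' Probes missing in more than `max_na_fraction` of samples are removed.
#' Remaining missing entries are replaced by the mean beta of the `k`
#' nearest probes (Euclidean distance over pairwise-complete samples)
#' among probes observed at that sample. Imputation is probe-wise: probes
#' are the points, samples the coordinates.
#'
#' @param beta probes x samples matrix of beta values in `[0, 1]`, NAs
#'   allowed.
#' @param max_na_fraction drop probes with NA fraction strictly above
#'   this (default 0.3).
#' @param k number of neighbor probes (default 5).
#' @return beta matrix without missing values.
#' @export
clean_beta <- function(beta, max_na_fraction = 0.3, k = 5) {
  stopifnot(is.matrix(beta), max_na_fraction >= 0, max_na_fraction < 1, k >= 1)
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("beta values must lie in [0, 1]")
  na_frac <- rowMeans(is.na(beta))
  beta <- beta[na_frac <= max_na_fraction, , drop = FALSE]
  if (!anyNA(beta)) return(beta)

  # pairwise-complete squared Euclidean distances via mask algebra:
  # d2[i,j] = sum over shared samples of (x_i - x_j)^2, scaled to a
  # mean so probes with different overlap sizes are comparable
  M <- !is.na(beta)
  X0 <- beta
  X0[!M] <- 0
  Xsq <- X0 * X0
  shared <- tcrossprod(M * 1)
  d2 <- tcrossprod(Xsq, M) + tcrossprod(M, Xsq) - 2 * tcrossprod(X0)
  d2 <- d2 / pmax(shared, 1)
  d2[shared == 0] <- Inf
  diag(d2) <- Inf

  need <- which(!M, arr.ind = TRUE)
  warned <- FALSE
  for (r in unique(need[, 1])) {
    ord <- order(d2[r, ])
    for (s in need[need[, 1] == r, 2]) {
      cand <- ord[M[ord, s]]
      if (length(cand) < k && !warned) {
        warning("fewer than k complete neighbor probes available; using all")
        warned <- TRUE
      }
      use <- cand[seq_len(min(k, length(cand)))]
      beta[r, s] <- mean(beta[use, s])
    }
  }
  beta
}

#' Normalize a raw expression matrix
#'
#' Zeros are replaced by the minimum positive value of the whole
#' dataset, values are log2-transformed, and columns are quantile
#' normalized to a common distribution (tied values receive the mean of
#' the quantile targets they span).
#'
#' @param raw genes x samples matrix of non-negative expression values.
#' @return genes x samples matrix of normalized log2 expression.
#' @export
normalize_expression <- function(raw) {
  stopifnot(is.matrix(raw))
  if (any(raw < 0, na.rm = TRUE)) stop("expression values must be >= 0")
  pos <- raw[raw > 0]
  if (!length(pos)) stop("all-zero expression matrix")
  raw[raw == 0] <- min(pos)
  limma::normalizeQuantiles(log2(raw), ties = TRUE)
}

#' Collapse probe-level methylation to gene level by promoter region
#'
#' Per gene and sample: the mean of TSS200 probes if any exist; else the
#' mean of first-exon probes; else the mean of TSS1500 probes; genes with
#' only gene-body probes are absent from the output. Body probes never
#' contribute.
#'
#' @param beta clean (NA-free) probes x samples beta matrix.
#' @param annot probe annotation data frame (probe_id, gene, region).
#' @return genes x samples matrix of gene-level beta values.
#' @export
gene_level_methylation <- function(beta, annot) {
  stopifnot(!anyNA(beta))
  annot <- annot[annot$probe_id %in% rownames(beta) &
                   annot$region != "Body", , drop = FALSE]
  if (!nrow(annot)) {
    return(matrix(numeric(0), 0, ncol(beta),
                  dimnames = list(NULL, colnames(beta))))
  }
  out <- list()
  assigned <- character(0)
  for (reg in c("TSS200", "FirstExon", "TSS1500")) {
    sub <- annot[annot$region == reg & !(annot$gene %in% assigned), ,
                 drop = FALSE]
    if (!nrow(sub)) next
    vals <- beta[sub$probe_id, , drop = FALSE]
    sums <- rowsum(vals, group = sub$gene)
    n <- as.vector(table(sub$gene)[rownames(sums)])
    out[[reg]] <- sums / n
    assigned <- c(assigned, rownames(sums))
  }
  res <- do.call(rbind, out)
  res[order(rownames(res)), , drop = FALSE]
}
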