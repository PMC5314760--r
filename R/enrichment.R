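#' One-tailed Fisher's exact test on a 2x2 table
#'
#' Returns the conditional hypergeometric tail probability in the
#' requested direction together with the sample odds ratio
#' `(a d) / (b c)` (reported as NA when 0/0).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param direction `"greater"` (odds ratio above 1) or `"less"`.
#' @return list with `odds_ratio` and `p`.
#' @export
fisher_one_tailed <- function(tab, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0),
            all(tab == round(tab)))
  num <- tab[1, 1] * tab[2, 2]
  den <- tab[1, 2] * tab[2, 1]
  or <- if (num == 0 && den == 0) NA_real_ else num / den
  p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1
  else stats::fisher.test(tab, alternative = direction)$p.value
  list(odds_ratio = or, p = p)
}

#' Two-domain (EC vs IC) label used for pathway-level analyses
#'
#' Collapses coarse domains onto the two-domain scheme: EC stays EC,
#' IC stays IC; genes whose only annotation is the membrane-receptor
#' class carry no two-domain label and are excluded (NA).
#'
#' @param coarse named coarse-domain vector.
#' @return named vector with values `"EC"`, `"IC"` or NA.
#' @export
two_domain <- function(coarse) {
  out <- ifelse(coarse == "EC", "EC", ifelse(coarse == "IC", "IC",
                                             NA_character_))
  names(out) <- names(coarse)
  out
}

#' Signaling-domain enrichment of alteration gene lists
#'
#' For each ranked list, builds the 2x2 table of (in list vs rest of the
#' annotated network) x (EC+MR vs IC) and computes a one-tailed Fisher
#' test; the expected count is the list size times the background EC+MR
#' fraction. Default directions follow the biology under test: the
#' methylation classes and Mutation are tested for EC+MR
#' over-representation (`"greater"`), the copy-number classes for EC+MR
#' depletion (`"less"`). In `"equalized"` mode all lists are first
#' truncated to the length of the shortest.
#'
#' @param lists named list of ranked gene identifier vectors.
#' @param coarse named coarse-domain vector (background = all its genes).
#' @param mode `"all"` or `"equalized"`.
#' @param directions named vector of test directions per class;
#'   defaults as described.
#' @return data frame: class, n, observed_ecmr, expected_ecmr,
#'   odds_ratio, p, direction.
#' @export
domain_enrichment <- function(lists, coarse, mode = c("all", "equalized"),
                              directions = NULL) {
  mode <- match.arg(mode)
  if (is.null(directions)) {
    directions <- c(HyperM = "greater", HypoM = "greater",
                    Amplification = "less", Deletion = "less",
                    Mutation = "greater")
  }
  lists <- lapply(lists, function(g) g[g %in% names(coarse)])
  if (mode == "equalized") {
    k <- min(lengths(lists))
    lists <- lapply(lists, utils::head, k)
  }
  bg <- names(coarse)
  is_ecmr <- coarse %in% c("EC", "MR")
  n_ecmr_bg <- sum(is_ecmr)
  rows <- lapply(names(lists), function(cl) {
    g <- lists[[cl]]
    if (!length(g)) {
      return(data.frame(class = cl, n = 0L, observed_ecmr = NA_integer_,
                        expected_ecmr = NA_real_, odds_ratio = NA_real_,
                        p = NA_real_, direction = NA_character_,
                        stringsAsFactors = FALSE))
    }
    dir <- if (cl %in% names(directions)) directions[[cl]] else "greater"
    a <- sum(is_ecmr[match(g, bg)])
    b <- length(g) - a
    tab <- matrix(c(a, b, n_ecmr_bg - a, sum(!is_ecmr) - b), 2, 2,
                  byrow = TRUE)
    ft <- fisher_one_tailed(tab, dir)
    data.frame(class = cl, n = length(g), observed_ecmr = a,
               expected_ecmr = length(g) * n_ecmr_bg / length(bg),
               odds_ratio = ft$odds_ratio, p = ft$p, direction = dir,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Differential domain distribution of DNAm versus SCNA alterations in
#' a pathway
#'
#' Restricts to pathway members carrying an EC or IC two-domain label,
#' counts DNAm-altered (HyperM or HypoM) and SCNA-altered
#' (Amplification or Deletion) genes per domain, and tests the one-
#' tailed alternative that DNAm alterations are enriched in the EC
#' domain relative to SCNA alterations. Pathways with no altered genes
#' give p = 1 (flagged).
#'
#' @param pathway_genes gene identifiers of the pathway.
#' @param dnam_genes,scna_genes altered gene identifier vectors.
#' @param coarse named coarse-domain vector.
#' @return list: `table` (2x2: rows DNAm/SCNA, columns EC/IC),
#'   `odds_ratio`, `p`, `degenerate`.
#' @export
pathway_domain_differential <- function(pathway_genes, dnam_genes,
                                        scna_genes, coarse) {
  td <- two_domain(coarse)
  pg <- pathway_genes[pathway_genes %in% names(td)]
  pg <- pg[!is.na(td[pg])]
  dn <- intersect(pg, dnam_genes)
  sc <- intersect(pg, scna_genes)
  tab <- matrix(c(sum(td[dn] == "EC"), sum(td[dn] == "IC"),
                  sum(td[sc] == "EC"), sum(td[sc] == "IC")),
                2, 2, byrow = TRUE,
                dimnames = list(c("DNAm", "SCNA"), c("EC", "IC")))
  degenerate <- sum(tab) == 0 || length(dn) + length(sc) == 0
  ft <- fisher_one_tailed(tab, "greater")
  list(table = tab, odds_ratio = ft$odds_ratio,
       p = if (degenerate) 1 else ft$p, degenerate = degenerate)
}

#' EC enrichment of DNAm-altered genes within a pathway
#'
#' Compares DNAm-altered versus not-altered pathway members across the
#' EC/IC two-domain split, one-tailed for EC excess among altered genes.
#'
#' @inheritParams pathway_domain_differential
#' @return list: `table`, `odds_ratio`, `p`, `degenerate`.
#' @export
pathway_dnam_ec_enrichment <- function(pathway_genes, dnam_genes, coarse) {
  td <- two_domain(coarse)
  pg <- pathway_genes[pathway_genes %in% names(td)]
  pg <- pg[!is.na(td[pg])]
  alt <- intersect(pg, dnam_genes)
  rest <- setdiff(pg, dnam_genes)
  tab <- matrix(c(sum(td[alt] == "EC"), sum(td[alt] == "IC"),
                  sum(td[rest] == "EC"), sum(td[rest] == "IC")),
                2, 2, byrow = TRUE,
                dimnames = list(c("altered", "not_altered"), c("EC", "IC")))
  degenerate <- length(alt) == 0 || all(colSums(tab) == 0) ||
    any(colSums(tab) == sum(tab))
  ft <- fisher_one_tailed(tab, "greater")
  list(table = tab, odds_ratio = ft$odds_ratio,
       p = if (degenerate) 1 else ft$p, degenerate = degenerate)
}

#' Fisher's combined probability test
#'
#' Combines independent one-tailed p-values via
#' \eqn{X = -2 \sum \ln p_i}, referred to a chi-square distribution
#' with 2k degrees of freedom. NA entries are skipped (k reduced);
#' zeros are clamped to the smallest positive double with a warning.
#'
#' @param p vector of p-values in (0, 1].
#' @return combined meta p-value.
#' @export
fisher_combined <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) return(NA_real_)
  stopifnot(all(p >= 0), all(p <= 1))
  if (any(p == 0)) {
    warning("p = 0 input clamped to the smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  x <- -2 * sum(log(p))
  stats::pchisq(x, df = 2 * length(p), lower.tail = FALSE)
}

#' Over-representation (overlap) test between two gene lists
#'
#' Hypergeometric upper-tail probability of observing at least the
#' realized intersection size given the list sizes and universe.
#'
#' @param list_a,list_b gene identifier vectors (subsets of `universe`).
#' @param universe gene universe.
#' @return one-tailed p-value.
#' @export
overlap_test <- function(list_a, list_b, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  a <- unique(list_a[list_a %in% universe])
  b <- unique(list_b[list_b %in% universe])
  k <- length(intersect(a, b))
  stats::phyper(k - 1, length(a), length(universe) - length(a), length(b),
                lower.tail = FALSE)
}

#' Pathway-level meta-analysis table across cancer types
#'
#' Runs [pathway_domain_differential()] per pathway and cancer type and
#' combines the per-type p-values with [fisher_combined()]. A BH-
#' adjusted meta p-value column is reported alongside the raw values as
#' an extension.
#'
#' @param pathways named list of pathway gene vectors (GMT semantics:
#'   genes in several pathways count in each).
#' @param dnam_by_type,scna_by_type named lists (per cancer type) of
#'   altered gene vectors.
#' @param coarse named coarse-domain vector.
#' @return data frame: pathway, one p column per cancer type, meta_p,
#'   meta_p_bh; ordered by meta_p.
#' @export
pathway_meta_analysis <- function(pathways, dnam_by_type, scna_by_type,
                                  coarse) {
  types <- names(dnam_by_type)
  stopifnot(identical(types, names(scna_by_type)))
  pmat <- sapply(types, function(ty) {
    vapply(pathways, function(pg) {
      pathway_domain_differential(pg, dnam_by_type[[ty]],
                                  scna_by_type[[ty]], coarse)$p
    }, 0)
  })
  pmat <- matrix(pmat, nrow = length(pathways),
                 dimnames = list(names(pathways), types))
  meta <- apply(pmat, 1, fisher_combined)
  out <- data.frame(pathway = names(pathways), pmat, meta_p = meta,
                    meta_p_bh = stats::p.adjust(meta, "BH"),
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out[order(out$meta_p), , drop = FALSE]
}

#' Cumulative alteration-by-domain table for selected pathways
#'
#' Sums the per-cancer-type 2x2 tables of
#' [pathway_domain_differential()] before testing, mirroring a
#' cumulative barplot over cancer types.
#'
#' @inheritParams pathway_meta_analysis
#' @param pathway_names pathways to aggregate (default all).
#' @return data frame: pathway, dnam_ec, dnam_ic, scna_ec, scna_ic, p.
#' @export
pathway_cumulative_table <- function(pathways, dnam_by_type, scna_by_type,
                                     coarse, pathway_names = names(pathways)) {
  rows <- lapply(pathway_names, function(pn) {
    tab <- matrix(0, 2, 2)
    for (ty in names(dnam_by_type)) {
      tab <- tab + pathway_domain_differential(
        pathways[[pn]], dnam_by_type[[ty]], scna_by_type[[ty]], coarse)$table
    }
    ft <- fisher_one_tailed(tab, "greater")
    data.frame(pathway = pn, dnam_ec = tab[1, 1], dnam_ic = tab[1, 2],
               scna_ec = tab[2, 1], scna_ic = tab[2, 2],
               odds_ratio = ft$odds_ratio, p = ft$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
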