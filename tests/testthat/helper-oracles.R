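# Independent oracles used across tests. These deliberately re-derive
# results from first principles (enumeration, brute force) and share no
# code with the implementation paths they check.

# full hypergeometric enumeration of the one-tailed Fisher p for a 2x2
# table with fixed margins
enum_fisher_p <- function(tab, direction) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  pmf <- choose(r1, support) * choose(r2, c1 - support) / choose(n, c1)
  a <- tab[1, 1]
  if (direction == "greater") sum(pmf[support >= a]) else sum(pmf[support <= a])
}

# Floyd-Warshall all-pairs shortest paths on an adjacency matrix
fw_dist <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  D[adj > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

# brute-force copy-number call for one (sample, gene): enumerate all
# overlapping segments, classify each against the thresholds, take the
# maximal severity with |seg_mean| tie-break
brute_call_one <- function(gene_row, segs, thr) {
  states <- integer(0); means <- numeric(0)
  for (i in seq_len(nrow(segs))) {
    if (segs$chrom[i] != gene_row$chrom) next
    if (segs$end[i] < gene_row$start || segs$start[i] > gene_row$end) next
    v <- segs$seg_mean[i]
    st <- if (v > thr$amp) 2L else if (v > thr$gain) 1L
    else if (v < thr$del) -2L else if (v < thr$loss) -1L else 0L
    states <- c(states, st); means <- c(means, v)
  }
  if (!length(states) || all(states == 0L)) return(0L)
  sev <- abs(states)
  best <- which(sev == max(sev))
  states[best][which.max(abs(means[best]))]
}

# small connected graph with random coarse labels
random_annotated_graph <- function(n, p = 0.15) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- sprintf("g%02d", seq_len(n))
  lab <- sample(c("EC", "MR", "IC"), n, replace = TRUE)
  list(graph = g, coarse = stats::setNames(lab, igraph::V(g)$name))
}

# DiffStat-shaped data frame from explicit fields
mk_stats <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  defaults <- list(t_meth = 3, t_expr = -3, p_meth = 1e-4, p_expr = 1e-4,
                   fdr_meth = 1e-3, fdr_expr = 1e-3, delta_beta = 0.2,
                   log2fc = -1.5)
  for (nm in names(defaults)) if (!nm %in% names(df)) df[[nm]] <- defaults[[nm]]
  if (!"gene" %in% names(df)) df$gene <- sprintf("g%03d", seq_len(nrow(df)))
  df
}
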