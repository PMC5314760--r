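#' Default cellular-localization keyword lists for the three coarse
#' signaling domains
#'
#' Keyword lists used to map localization terms onto the intracellular
#' (IC), membrane-receptor (MR) and extracellular (EC) coarse domains.
#' Matching is by case-insensitive substring containment.
#'
#' @return named list with elements `IC`, `MR`, `EC`.
#' @export
default_domain_keywords <- function() {
  list(
    IC = c("Nucleus", "Cytoplasm", "Ribosome", "Nucleolus", "Mitochondri",
           "Endoplasmic reticulum", "Golgi", "Lysosome", "Cytosol",
           "Cytoskeleton", "Nuclear", "Kinetochore", "Chromosome",
           "Endosome", "Intracellular", "Nucleoplasm", "Perinuclear",
           "Centrosome", "Peroxisome", "Microtubule", "Microsome",
           "endosome", "Centriole", "Sarcoplasm", "Secretory granule",
           "Endocytic vesicle", "cytoskeleton", "Peroxisomal membrane",
           "Acrosome", "Zymogen granule"),
    MR = c("Plasma membrane", "Integral to membrane", "Cell surface",
           "Integral to plasma membrane", "Cell projection",
           "Basolateral membrane", "Axoneme", "Apical membrane"),
    EC = c("Extracellular", "Cell junction", "Synapse", "Dendrite",
           "Secreted", "Synaptic vesicle"))
}

#' Assign coarse signaling domains from localization terms
#'
#' Each gene is matched against the three keyword lists; multi-domain
#' memberships are resolved by the signaling hierarchy: a gene matching
#' EC terms is EC (including EC+MR and EC+IC combinations); otherwise a
#' gene matching both MR and IC is IC; otherwise the single matched
#' domain stands. Genes matching no keyword are excluded.
#'
#' @param loc named list: gene -> character vector of localization
#'   terms (as from [read_localization()]).
#' @param keywords keyword configuration (default
#'   [default_domain_keywords()]).
#' @return named character vector: gene -> `"EC"`, `"MR"` or `"IC"`.
#' @export
coarse_domains <- function(loc, keywords = default_domain_keywords()) {
  stopifnot(all(c("EC", "MR", "IC") %in% names(keywords)))
  kw <- lapply(keywords, tolower)
  res <- vapply(loc, function(terms) {
    lt <- tolower(terms)
    hits <- vapply(kw, function(k) {
      any(vapply(k, function(p) any(grepl(p, lt, fixed = TRUE)), TRUE))
    }, TRUE)
    if (hits[["EC"]]) "EC"
    else if (hits[["MR"]] && hits[["IC"]]) "IC"
    else if (hits[["MR"]]) "MR"
    else if (hits[["IC"]]) "IC"
    else NA_character_
  }, "")
  res[!is.na(res)]
}

#' Refine coarse domains into the five fine signaling classes
#'
#' IC genes with at least one membrane-receptor neighbor in the network
#' are intracellular receptor substrates (ICRS), otherwise non-receptor
#' substrates (ICNRS); EC genes with an MR neighbor are secreted factors
#' (SF), otherwise growth modulators (GM); MR genes stay MR.
#'
#' @param coarse named vector from [coarse_domains()] covering the
#'   graph's vertices.
#' @param graph igraph object whose vertex names are gene identifiers.
#' @return named character vector: gene -> GM/SF/MR/ICRS/ICNRS.
#' @export
fine_domains <- function(coarse, graph) {
  vn <- igraph::V(graph)$name
  stopifnot(all(vn %in% names(coarse)))
  cg <- coarse[vn]
  mr_nodes <- vn[cg == "MR"]
  has_mr <- rep(FALSE, length(vn))
  names(has_mr) <- vn
  if (length(mr_nodes)) {
    adj <- igraph::adjacent_vertices(graph, v = vn)
    has_mr <- vapply(adj, function(a) any(a$name %in% mr_nodes), TRUE)
  }
  out <- ifelse(cg == "MR", "MR",
                ifelse(cg == "EC", ifelse(has_mr, "SF", "GM"),
                       ifelse(has_mr, "ICRS", "ICNRS")))
  names(out) <- vn
  out
}

edge_pair_allowed <- function(c1, c2) {
  key <- ifelse(c1 <= c2, paste(c1, c2, sep = "|"), paste(c2, c1, sep = "|"))
  # canonical unordered keys for the allowed set
  key %in% c("EC|EC", "EC|MR", "IC|MR", "IC|IC")
}

#' Build the pruned, domain-annotated protein interaction network
#'
#' Self-loops and duplicate edges are dropped and the largest connected
#' component taken; edges whose endpoint coarse domains are not among
#' the hierarchy-consistent combinations EC-EC, EC-MR, MR-IC, IC-IC are
#' removed (in particular MR-MR and EC-IC); the largest connected
#' component is extracted again. Vertices carry `coarse` and `fine`
#' domain attributes (fine classes computed on the pruned graph), and
#' the graph carries `n_nodes`, `n_edges` and `sparsity` attributes.
#'
#' @param edges data frame of undirected edges (geneA, geneB).
#' @param coarse named vector from [coarse_domains()]; genes without a
#'   coarse label are excluded from the network.
#' @return annotated igraph object.
#' @export
build_pruned_pin <- function(edges, coarse) {
  genes <- union(edges[[1]], edges[[2]])
  genes <- genes[genes %in% names(coarse)]
  edges <- edges[edges[[1]] %in% genes & edges[[2]] %in% genes, , drop = FALSE]
  if (!nrow(edges)) stop("empty network after domain annotation")
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = genes))
  g <- igraph::simplify(g)
  g <- largest_component(g)
  el <- igraph::as_edgelist(g)
  ok <- edge_pair_allowed(coarse[el[, 1]], coarse[el[, 2]])
  g <- igraph::delete_edges(g, which(!ok))
  g <- largest_component(g)
  if (igraph::vcount(g) == 0 || igraph::ecount(g) == 0)
    stop("empty network after domain-hierarchy pruning")
  igraph::V(g)$coarse <- unname(coarse[igraph::V(g)$name])
  fine <- fine_domains(coarse, g)
  igraph::V(g)$fine <- unname(fine[igraph::V(g)$name])
  g$n_nodes <- igraph::vcount(g)
  g$n_edges <- igraph::ecount(g)
  g$sparsity <- pin_sparsity(g$n_nodes, g$n_edges)
  g
}

largest_component <- function(g) {
  comp <- igraph::components(g)
  igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
}

#' Edge density of an undirected simple graph
#' @param n_nodes,n_edges node and edge counts.
#' @return `2E / (N (N - 1))`.
#' @export
pin_sparsity <- function(n_nodes, n_edges) {
  2 * n_edges / (n_nodes * (n_nodes - 1))
}

map_list_to_net <- function(genes, net, top_k) {
  genes <- utils::head(genes, top_k)
  list(mapped = genes[genes %in% igraph::V(net)$name],
       n_dropped = sum(!(genes %in% igraph::V(net)$name)))
}

#' Compare interactome connectivity between alteration classes
#'
#' Maps the top-`top_k` genes of each ranked alteration list onto the
#' network (genes absent from the network are dropped and counted) and
#' compares degree distributions with one-tailed Mann-Whitney rank-sum
#' tests: `p_matrix[row, col]` tests whether the column class has
#' smaller degrees than the row class. Also reports the pooled
#' DNAm (HyperM+HypoM) versus CNV (Amplification+Deletion) comparison
#' when those classes are present.
#'
#' @param lists named list of ranked gene identifier vectors (e.g.
#'   HyperM, HypoM, Amplification, Deletion, Mutation).
#' @param net annotated igraph network.
#' @param top_k list truncation (default 100).
#' @param min_genes smallest mapped class size still tested; below it
#'   the p-value is reported missing with a warning (default 5).
#' @return list: `degrees` (per class), `p_matrix`,
#'   `pooled_dnam_vs_cnv_p`, `n_dropped`.
#' @export
degree_comparison <- function(lists, net, top_k = 100, min_genes = 5) {
  deg_all <- igraph::degree(net)
  mapped <- lapply(lists, map_list_to_net, net = net, top_k = top_k)
  degrees <- lapply(mapped, function(m) unname(deg_all[m$mapped]))
  n_dropped <- vapply(mapped, `[[`, 0L, "n_dropped")
  cls <- names(lists)
  p <- matrix(NA_real_, length(cls), length(cls), dimnames = list(cls, cls))
  for (a in cls) for (b in cls) {
    if (a == b) next
    if (length(degrees[[a]]) < min_genes || length(degrees[[b]]) < min_genes) {
      warning("fewer than ", min_genes, " mapped genes for ", a, " or ", b)
      next
    }
    # alternative: column class (b) smaller than row class (a); ties
    # among integer degrees are expected, so the tie warning is muted
    p[a, b] <- suppressWarnings(
      stats::wilcox.test(degrees[[b]], degrees[[a]],
                         alternative = "less")$p.value)
  }
  pooled <- NA_real_
  dn <- unlist(degrees[intersect(c("HyperM", "HypoM"), cls)])
  cn <- unlist(degrees[intersect(c("Amplification", "Deletion"), cls)])
  if (length(dn) >= min_genes && length(cn) >= min_genes) {
    pooled <- suppressWarnings(
      stats::wilcox.test(dn, cn, alternative = "less")$p.value)
  }
  list(degrees = degrees, p_matrix = p, pooled_dnam_vs_cnv_p = pooled,
       n_dropped = n_dropped)
}

#' Compare within-class shortest-path distances between alteration
#' classes
#'
#' Per class, all pairwise unweighted shortest-path lengths among the
#' mapped top-`top_k` genes are computed; class pairs are compared by a
#' one-tailed Mann-Whitney test oriented along the hierarchy HyperM >
#' HypoM > Mutation > Amplification > Deletion (the earlier class is
#' tested for longer paths than the later one). Classes not in the
#' hierarchy are compared in list order.
#'
#' @inheritParams degree_comparison
#' @return list: `distances` (vector per class), `comparisons` data
#'   frame (class_a, class_b, mean_a, mean_b, p), `n_dropped`.
#' @export
shortest_path_comparison <- function(lists, net, top_k = 100) {
  mapped <- lapply(lists, map_list_to_net, net = net, top_k = top_k)
  dists <- lapply(mapped, function(m) {
    g <- m$mapped
    if (length(g) < 2) return(numeric(0))
    D <- igraph::distances(net, v = g, to = g)
    D[upper.tri(D)]
  })
  n_dropped <- vapply(mapped, `[[`, 0L, "n_dropped")
  hierarchy <- c("HyperM", "HypoM", "Mutation", "Amplification", "Deletion")
  cls <- names(lists)
  cls <- c(intersect(hierarchy, cls), setdiff(cls, hierarchy))
  rows <- list()
  for (i in seq_along(cls)) for (j in seq_along(cls)) {
    if (j <= i) next
    a <- cls[i]; b <- cls[j]
    p <- if (length(dists[[a]]) && length(dists[[b]])) {
      suppressWarnings(stats::wilcox.test(dists[[a]], dists[[b]],
                                          alternative = "greater")$p.value)
    } else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      class_a = a, class_b = b,
      mean_a = mean(dists[[a]]), mean_b = mean(dists[[b]]), p = p,
      stringsAsFactors = FALSE)
  }
  list(distances = dists, comparisons = do.call(rbind, rows),
       n_dropped = n_dropped)
}
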