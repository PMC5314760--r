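test_that("localization keywords map to coarse domains with EC-dominant resolution", {
  loc <- list(a = "Nucleus",
              b = c("Extracellular", "Plasma membrane"),
              c = "Unknown organelle",
              d = c("Plasma membrane", "Cytoplasm"),
              e = "Integral to plasma membrane",
              f = c("Extracellular", "Nucleolus"))
  cd <- coarse_domains(loc)
  expect_equal(unname(cd["a"]), "IC")
  expect_equal(unname(cd["b"]), "EC")    # EC wins over MR
  expect_false("c" %in% names(cd))       # unannotated genes excluded
  expect_equal(unname(cd["d"]), "IC")    # MR + IC resolves to IC
  expect_equal(unname(cd["e"]), "MR")
  expect_equal(unname(cd["f"]), "EC")    # EC + IC resolves to EC
})

test_that("fine domains depend on membrane-receptor adjacency", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("ec1", "mr1", "ic2", "ec2"),
               to = c("mr1", "ic1", "ic1", "ec1")),
    directed = FALSE)
  coarse <- c(ec1 = "EC", ec2 = "EC", mr1 = "MR", ic1 = "IC", ic2 = "IC")
  fine <- fine_domains(coarse, g)
  expect_equal(unname(fine["ec1"]), "SF")    # EC touching an MR
  expect_equal(unname(fine["ec2"]), "GM")    # EC without MR contact
  expect_equal(unname(fine["ic1"]), "ICRS")
  expect_equal(unname(fine["ic2"]), "ICNRS")
  expect_equal(unname(fine["mr1"]), "MR")
})

test_that("pruning removes hierarchy-violating edges and duplicates", {
  edges <- data.frame(
    geneA = c("ec", "mr", "ec", "ec", "mr2"),
    geneB = c("mr", "ic", "ic", "mr", "mr"),   # EC-IC violates; EC-MR dup
    stringsAsFactors = FALSE)
  coarse <- c(ec = "EC", mr = "MR", ic = "IC", mr2 = "MR")
  pin <- build_pruned_pin(edges, coarse)
  el <- igraph::as_edgelist(pin)
  pairs <- apply(el, 1, function(e) paste(sort(e), collapse = "-"))
  expect_true(setequal(pairs, c("ec-mr", "ic-mr")))  # EC-IC, MR-MR dropped
  expect_equal(pin$n_edges, 2)
  expect_equal(pin$sparsity, pin_sparsity(3, 2))
})

test_that("pruned edge set matches a brute-force filter plus largest component", {
  set.seed(30)
  for (rep in 1:30) {
    rg <- random_annotated_graph(15, p = 0.2)
    el <- igraph::as_edgelist(rg$graph)
    pin <- tryCatch(
      build_pruned_pin(data.frame(geneA = el[, 1], geneB = el[, 2]),
                       rg$coarse),
      error = function(e) NULL)
    # brute force: keep allowed pairs, then take the largest component
    lab <- rg$coarse
    ok <- apply(el, 1, function(e) {
      pr <- paste(sort(lab[e]), collapse = "-")
      pr %in% c("EC-EC", "EC-MR", "IC-MR", "IC-IC")
    })
    gb <- igraph::graph_from_data_frame(as.data.frame(el[ok, , drop = FALSE]),
                                        directed = FALSE)
    if (igraph::ecount(gb) == 0) {
      expect_null(pin)
      next
    }
    comp <- igraph::components(gb)
    keep <- igraph::V(gb)$name[comp$membership == which.max(comp$csize)]
    gb <- igraph::induced_subgraph(gb, keep)
    expect_false(is.null(pin))
    a <- apply(igraph::as_edgelist(pin), 1,
               function(e) paste(sort(e), collapse = "|"))
    b <- apply(igraph::as_edgelist(gb), 1,
               function(e) paste(sort(e), collapse = "|"))
    expect_true(setequal(a, b))
    # node degree equals its count of retained incident edges
    deg <- igraph::degree(pin)
    for (v in names(deg)[1:3]) {
      expect_equal(unname(deg[v]), sum(grepl(paste0("^", v, "\\|"), a) |
                                         grepl(paste0("\\|", v, "$"), a)))
    }
  }
})

test_that("degree comparison reproduces the exact rank-sum tail for separated sets", {
  # degrees {1,2,3} vs {5,6,7}: all 3 small ranks below all 3 large
  # ranks, one-tailed p = 1 / C(6,3) = 0.05
  edges <- data.frame(
    from = c("z", "z", "z", "z", "z", "z", "z", "y", "y", "y", "y", "y",
             "x", "x", "x", "c", "b", "b", "a"),
    to   = c("f1", "f2", "f3", "f4", "x", "y", "c", "f1", "f2", "f3", "x",
             "c", "f1", "f2", "f3", "f5", "f5", "f6", "f7"))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  expect_equal(unname(igraph::degree(g)[c("a", "b", "c", "x", "y", "z")]),
               c(1, 2, 3, 5, 6, 7))
  res <- degree_comparison(list(low = c("a", "b", "c"),
                                high = c("x", "y", "z")), g, min_genes = 3)
  expect_equal(unname(res$p_matrix["high", "low"]), 0.05)
  # below the minimum mapped size the p is missing, with a warning
  expect_warning(
    res_na <- degree_comparison(list(low = c("a", "b", "c"),
                                     high = c("x", "y", "z")), g),
    "fewer than 5")
  expect_true(is.na(res_na$p_matrix["high", "low"]))
  # a class against itself is symmetric
  res2 <- degree_comparison(list(A = c("a", "b", "c", "x", "y", "z"),
                                 B = c("a", "b", "c", "x", "y", "z")), g)
  expect_gt(res2$p_matrix["A", "B"], 0.4)
  expect_lt(res2$p_matrix["A", "B"], 0.65)
})

test_that("star leaves have stochastically smaller degrees than star centers", {
  # a chain of 100 stars: hubs have degree >= 5, leaves degree 1
  hubs <- sprintf("h%03d", 1:100)
  star <- data.frame(from = rep(hubs, each = 5),
                     to = sprintf("l%03d_%d", rep(1:100, each = 5), 1:5))
  chain <- data.frame(from = hubs[-100], to = hubs[-1])
  g <- igraph::graph_from_data_frame(rbind(star, chain), directed = FALSE)
  leaves <- sprintf("l%03d_1", 1:100)
  res <- degree_comparison(list(small = leaves, large = hubs), g,
                           top_k = 100)
  expect_lt(res$p_matrix["large", "small"], 0.05)
})

test_that("within-class path distances match hand enumeration and the FW oracle", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("A", "B", "C"), to = c("B", "C", "D")),
    directed = FALSE)
  res <- shortest_path_comparison(list(HyperM = c("A", "D"),
                                       Amplification = c("B", "C")), g,
                                  top_k = 10)
  expect_equal(unname(res$distances$HyperM), 3)
  expect_equal(unname(res$distances$Amplification), 1)
  expect_equal(res$comparisons$class_a, "HyperM")  # hierarchy orientation

  set.seed(32)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    rg <- random_annotated_graph(n, p = 0.15)
    D_ig <- igraph::distances(rg$graph)
    adj <- as.matrix(igraph::as_adjacency_matrix(rg$graph))
    D_fw <- fw_dist(adj)
    expect_equal(unname(D_ig), unname(D_fw))
  }
})
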