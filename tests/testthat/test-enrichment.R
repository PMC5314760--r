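test_that("one-tailed Fisher p matches hypergeometric enumeration", {
  res <- fisher_one_tailed(matrix(c(1, 0, 0, 1), 2, 2), "greater")
  expect_equal(res$p, 0.5)               # two outcomes at margins (1,1)
  # equal proportions give OR = 1
  expect_equal(fisher_one_tailed(matrix(c(5, 10, 5, 10), 2, 2),
                                 "greater")$odds_ratio, 1)
  # zero margin: p = 1, OR undefined
  z <- fisher_one_tailed(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE), "greater")
  expect_equal(z$p, 1)
  expect_true(is.na(z$odds_ratio))
  set.seed(40)
  for (i in 1:300) {
    tab <- matrix(sample(0:30, 4, TRUE), 2, 2)
    dir <- sample(c("greater", "less"), 1)
    expect_equal(fisher_one_tailed(tab, dir)$p, enum_fisher_p(tab, dir),
                 tolerance = 1e-12)
  }
})

test_that("domain enrichment builds the correct table and respects equalized mode", {
  genes <- sprintf("g%03d", 1:100)
  coarse <- setNames(rep(c("EC", "IC"), 50), genes)  # 50% EC+MR background
  all_ec <- genes[coarse == "EC"][1:10]
  res <- domain_enrichment(list(HyperM = all_ec), coarse)
  expect_equal(res$observed_ecmr, 10)
  expect_equal(res$expected_ecmr, 5)
  expect_gt(res$odds_ratio, 1)
  # oracle: hypergeometric tail for 10/10 EC at margins (10, 50 of 100)
  expect_equal(res$p,
               enum_fisher_p(matrix(c(10, 0, 40, 50), 2, 2, byrow = TRUE),
                             "greater"),
               tolerance = 1e-12)
  # equalized mode truncates every list to the shortest
  lists <- list(HyperM = genes[1:16], HypoM = genes[1:94],
                Amplification = genes[1:100], Deletion = genes[1:61],
                Mutation = genes[1:40])
  eq <- domain_enrichment(lists, coarse, mode = "equalized")
  expect_true(all(eq$n == 16))
})

test_that("uniform draws from the background give calibrated enrichment p-values", {
  set.seed(41)
  genes <- sprintf("g%04d", 1:1000)
  coarse <- setNames(sample(c("EC", "MR", "IC"), 1000, TRUE,
                            prob = c(0.2, 0.2, 0.6)), genes)
  hits <- replicate(400, {
    lst <- list(HyperM = sample(genes, 50))
    domain_enrichment(lst, coarse)$p < 0.05
  })
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.08)
})

test_that("pathway differential-domain test detects EC-skewed DNAm alterations", {
  genes <- sprintf("g%02d", 1:40)
  coarse <- setNames(rep(c("EC", "IC"), each = 20), genes)
  pw <- genes
  dnam <- c(genes[1:8], genes[21:22])    # 8 EC, 2 IC
  scna <- c(genes[9:10], genes[23:30])   # 2 EC, 8 IC
  res <- pathway_domain_differential(pw, dnam, scna, coarse)
  expect_equal(unname(res$table[1, ]), c(8, 2))
  expect_equal(unname(res$table[2, ]), c(2, 8))
  expect_lt(res$p, 0.05)
  expect_equal(res$p, enum_fisher_p(res$table, "greater"), tolerance = 1e-12)
  # identical splits carry no signal
  same <- pathway_domain_differential(pw, dnam, dnam, coarse)
  expect_gte(same$p, 0.5)
  # no altered genes: p = 1 by convention, flagged
  none <- pathway_domain_differential(pw, character(0), character(0), coarse)
  expect_equal(none$p, 1)
  expect_true(none$degenerate)
})

test_that("within-pathway EC enrichment of DNAm alterations is tested against the rest", {
  genes <- sprintf("g%02d", 1:20)
  coarse <- setNames(rep(c("EC", "IC"), each = 10), genes)
  # all altered genes EC, all unaltered IC: minimal attainable p
  res <- pathway_dnam_ec_enrichment(genes, genes[1:10], coarse)
  expect_equal(res$p, enum_fisher_p(res$table, "greater"), tolerance = 1e-12)
  expect_equal(res$p, 1 / choose(20, 10), tolerance = 1e-12)
  expect_equal(pathway_dnam_ec_enrichment(genes, character(0), coarse)$p, 1)
  # degenerate single-domain pathway
  ec_only <- setNames(rep("EC", 20), genes)
  expect_equal(pathway_dnam_ec_enrichment(genes, genes[1:5], ec_only)$p, 1)
})

test_that("Fisher's combined test matches its closed form and is monotone", {
  expect_equal(fisher_combined(0.037), 0.037)
  expect_equal(fisher_combined(c(1, 1, 1)), 1)
  x <- -2 * sum(log(c(0.1, 0.1)))
  expect_equal(x, 9.2103, tolerance = 1e-4)
  expect_equal(fisher_combined(c(0.1, 0.1)), exp(-x / 2) * (1 + x / 2),
               tolerance = 1e-12)
  # monotone: decreasing any input p never increases the meta p
  set.seed(42)
  for (i in 1:50) {
    p <- runif(4)
    q <- p
    j <- sample(4, 1)
    q[j] <- q[j] * runif(1)
    expect_lte(fisher_combined(q), fisher_combined(p))
  }
  expect_warning(res <- fisher_combined(c(0, 0.5)), "clamped")
  expect_lt(res, 1e-100)
})

test_that("overlap test gives the hypergeometric over-representation tail", {
  universe <- sprintf("u%04d", 1:1000)
  a <- universe[1:10]
  expect_equal(overlap_test(a, a, universe), 1 / choose(1000, 10),
               tolerance = 1e-12)
  # disjoint lists covering the universe
  half <- universe[1:500]
  expect_equal(overlap_test(half, setdiff(universe, half), universe), 1)
  expect_error(overlap_test(a, a, character(0)), "empty universe")
})

test_that("the pathway meta-analysis ranks a planted EC-biased pathway first", {
  set.seed(43)
  genes <- sprintf("g%04d", 1:800)
  coarse <- setNames(sample(c("EC", "MR", "IC"), 800, TRUE,
                            prob = c(0.25, 0.2, 0.55)), genes)
  net <- igraph::make_ring(800)
  igraph::V(net)$name <- genes
  pws <- generate_pathways(net, n_pathways = 10, min_size = 100,
                           max_size = 150, seed = 5)
  alt <- simulate_pathway_alterations(pws, coarse, "PATHWAY_03",
                                      n_types = 5, seed = 6)
  meta <- pathway_meta_analysis(pws, lapply(alt, `[[`, "dnam"),
                                lapply(alt, `[[`, "scna"), coarse)
  expect_equal(meta$pathway[1], "PATHWAY_03")
  expect_lt(meta$meta_p[1], 0.01)
  expect_true(all(meta$meta_p_bh >= meta$meta_p))
})
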