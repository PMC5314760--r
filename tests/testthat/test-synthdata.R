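test_that("config invariants are enforced", {
  expect_error(synth_config(domain_fractions = c(GM = 0.5, SF = 0.4,
                                                 MR = 0.2, ICRS = 0,
                                                 ICNRS = 0)),
               "sum to 1")
  expect_error(synth_config(planted = list(delta_beta = 1.2)))
  expect_error(synth_config(n_genes = 5))
  expect_error(synth_config(n_genes = 100,
                            planted = list(n_hyperm = 50, n_hypom = 60)))
})

test_that("a fixed seed reproduces the interactome and cohort exactly", {
  cfg <- synth_config(n_genes = 120, n_normal = 8, n_tumor = 8, seed = 9,
                      planted = list(n_hyperm = 8, n_hypom = 8, n_amp = 8,
                                     n_del = 8, n_mut = 8))
  n1 <- generate_interactome(cfg)
  n2 <- generate_interactome(cfg)
  expect_identical(igraph::as_edgelist(n1), igraph::as_edgelist(n2))
  expect_identical(igraph::V(n1)$fine, igraph::V(n2)$fine)
  c1 <- generate_cohort(cfg, n1)
  c2 <- generate_cohort(cfg, n2)
  expect_identical(c1$beta, c2$beta)
  expect_identical(c1$segments, c2$segments)
  expect_identical(c1$mutations, c2$mutations)
  expect_identical(c1$truth, c2$truth)
})

test_that("an all-MR network has only hierarchy-violating edges", {
  cfg <- synth_config(n_genes = 50, n_normal = 4, n_tumor = 4,
                      domain_fractions = c(GM = 0, SF = 0, MR = 1,
                                           ICRS = 0, ICNRS = 0),
                      planted = list(n_hyperm = 0, n_hypom = 0, n_amp = 0,
                                     n_del = 0, n_mut = 0),
                      seed = 3)
  net <- generate_interactome(cfg)
  expect_true(all(igraph::V(net)$coarse == "MR"))
  el <- igraph::as_edgelist(net)
  expect_true(igraph::ecount(net) > 0)
  # every MR-MR edge violates the allowed set, so pruning empties the graph
  coarse <- setNames(igraph::V(net)$coarse, igraph::V(net)$name)
  expect_error(build_pruned_pin(data.frame(geneA = el[, 1], geneB = el[, 2]),
                                coarse),
               "empty network")
})

test_that("a higher preferential-attachment exponent increases degree variance", {
  pl0 <- list(n_hyperm = 0, n_hypom = 0, n_amp = 0, n_del = 0, n_mut = 0)
  vars <- sapply(1:20, function(s) {
    lo <- generate_interactome(synth_config(n_genes = 150, seed = s,
                                            planted = pl0,
                                            degree_model = list(power = 0.2)))
    hi <- generate_interactome(synth_config(n_genes = 150, seed = s,
                                            planted = pl0,
                                            degree_model = list(power = 1.5)))
    c(lo = var(igraph::degree(lo)), hi = var(igraph::degree(hi)))
  })
  expect_gt(mean(vars["hi", ]), mean(vars["lo", ]))
})

test_that("ground truth classes are disjoint, on-network, and domain-biased", {
  cfg <- synth_config(n_genes = 600, n_normal = 10, n_tumor = 10, seed = 4)
  net <- generate_interactome(cfg)
  co <- generate_cohort(cfg, net)
  planted <- co$truth[c("hyperm", "hypom", "amplification", "deletion",
                        "mutation")]
  expect_equal(anyDuplicated(unlist(planted)), 0L)
  expect_true(all(unlist(planted) %in% igraph::V(net)$name))
  coarse <- setNames(igraph::V(net)$coarse, igraph::V(net)$name)
  # 3:1 odds toward EC/MR for methylation classes, IC for copy number
  frac_ecmr <- mean(coarse %in% c("EC", "MR"))
  expect_gt(mean(coarse[co$truth$hyperm] %in% c("EC", "MR")), frac_ecmr)
  expect_gt(mean(coarse[co$truth$amplification] == "IC"), mean(coarse == "IC"))
})

test_that("emitted beta values, segments and probe table are well-formed", {
  cfg <- synth_config(n_genes = 200, n_normal = 10, n_tumor = 10, seed = 5,
                      planted = list(n_hyperm = 15, n_hypom = 15, n_amp = 15,
                                     n_del = 15, n_mut = 15))
  net <- generate_interactome(cfg)
  co <- generate_cohort(cfg, net)
  expect_true(all(co$beta >= 0 & co$beta <= 1, na.rm = TRUE))
  expect_true(all(co$segments$end >= co$segments$start))
  by_sample <- split(co$segments$start, co$segments$sample)
  expect_true(all(vapply(by_sample, function(s) !is.unsorted(s), TRUE)))
  expect_true(all(co$probes$region %in% c("TSS200", "FirstExon", "TSS1500",
                                          "Body")))
  expect_true(any(co$probes$region == "Body"))
  expect_true(all(co$probes$pos >= 1))
})

test_that("cohort files round-trip and are byte-stable", {
  cfg <- synth_config(n_genes = 80, n_normal = 6, n_tumor = 6, seed = 6,
                      planted = list(n_hyperm = 5, n_hypom = 5, n_amp = 5,
                                     n_del = 5, n_mut = 5))
  net <- generate_interactome(cfg)
  co <- generate_cohort(cfg, net)
  d1 <- file.path(tempdir(), "coh1")
  d2 <- file.path(tempdir(), "coh2")
  write_cohort(co, net, d1)
  write_cohort(co, net, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  back <- load_cohort(d1)
  expect_equal(back$beta, co$beta)
  expect_equal(back$segments$seg_mean, co$segments$seg_mean)
  expect_identical(sort(back$truth$hyperm), co$truth$hyperm)
  # missing input aborts with the stage name
  file.remove(file.path(d1, "expression.tsv"))
  expect_error(load_cohort(d1), "preprocess stage input missing")
})
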