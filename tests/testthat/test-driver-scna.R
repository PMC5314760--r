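test_that("thresholds are median +/- 2 and 4 times the central-half spread", {
  c_half <- 0.25 / sqrt(2)               # two central values at +/- this
  v <- c(-1, -c_half, c_half, 1)         # sd of the central half = 0.25
  seg <- data.frame(sample = "s1", chrom = "chr1", start = 1:4 * 10,
                    end = 1:4 * 10 + 5, seg_mean = v)
  thr <- cn_thresholds(seg)
  expect_equal(thr$m, 0)
  expect_equal(thr$sigma, 0.25)
  expect_equal(thr$gain, 0.5)
  expect_equal(thr$amp, 1.0)
  expect_equal(thr$loss, -0.5)
  expect_equal(thr$del, -1.0)
  # location equivariance
  seg2 <- seg; seg2$seg_mean <- v + 0.3
  thr2 <- cn_thresholds(seg2)
  expect_equal(unlist(thr2[c("m", "gain", "loss", "amp", "del")]),
               unlist(thr[c("m", "gain", "loss", "amp", "del")]) + 0.3)
})

test_that("constant segment values give zero sigma and all-Neutral calls", {
  seg <- data.frame(sample = "s1", chrom = "chr1",
                    start = c(1, 100, 200, 300), end = c(99, 199, 299, 400),
                    seg_mean = 0.2)
  expect_warning(thr <- cn_thresholds(seg), "Neutral")
  coords <- data.frame(gene = "A", chrom = "chr1", start = 50, end = 150)
  calls <- suppressWarnings(build_call_matrix(seg, thr, coords))
  expect_true(all(calls == 0))
})

test_that("call matrix applies maximal severity with |seg_mean| tie-break", {
  thr <- data.frame(sample = "s1", m = 0, sigma = 0.3, gain = 0.6,
                    loss = -0.6, amp = 1.2, del = -1.2)
  coords <- data.frame(gene = c("amp1", "gain1", "tie1", "none1"),
                       chrom = "chr1",
                       start = c(100, 300, 500, 900),
                       end = c(199, 399, 599, 999))
  seg <- data.frame(
    sample = "s1", chrom = "chr1",
    start = c(100, 300, 350, 500, 520),
    end = c(199, 340, 399, 519, 599),
    seg_mean = c(1.5, 0.0, 0.8, 0.8, -1.1))
  calls <- build_call_matrix(seg, thr, coords)
  expect_equal(unname(calls["s1", "amp1"]), 2L)    # above amp threshold
  expect_equal(unname(calls["s1", "gain1"]), 1L)   # Neutral + Gain -> Gain
  expect_equal(unname(calls["s1", "tie1"]), -1L)   # Gain 0.8 vs Loss -1.1
  expect_equal(unname(calls["s1", "none1"]), 0L)   # no overlapping segment
})

test_that("call matrix agrees with brute-force overlap enumeration", {
  set.seed(20)
  for (rep in 1:200) {
    n_genes <- sample(3:8, 1)
    coords <- data.frame(gene = paste0("g", seq_len(n_genes)),
                         chrom = sample(c("chr1", "chr2"), n_genes, TRUE),
                         start = sample(1:500, n_genes))
    coords$end <- coords$start + sample(10:200, n_genes, TRUE)
    segs <- data.frame(sample = "s1",
                       chrom = sample(c("chr1", "chr2"), 6, TRUE),
                       start = sample(1:600, 6))
    segs$end <- segs$start + sample(10:300, 6, TRUE)
    segs$seg_mean <- rnorm(6, sd = 0.8)
    thr <- data.frame(sample = "s1", m = 0, sigma = 0.3, gain = 0.6,
                      loss = -0.6, amp = 1.2, del = -1.2)
    calls <- build_call_matrix(segs, thr, coords)
    for (i in seq_len(n_genes)) {
      expect_identical(unname(calls["s1", coords$gene[i]]),
                       brute_call_one(coords[i, ], segs, thr))
    }
  }
})

test_that("expression tails flag beyond 1.6449 MLE standard deviations", {
  set.seed(21)
  x <- matrix(rnorm(5 * 40), 5, 40,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:40)))
  x[1, 1] <- mean(x[1, -1])              # near-center value
  flags <- expression_tail_calls(x)
  mu <- rowMeans(x)
  sd_mle <- sqrt(rowMeans((x - mu)^2))
  manual <- matrix(0L, 5, 40)
  manual[x < mu - qnorm(0.95) * sd_mle] <- -1L
  manual[x > mu + qnorm(0.95) * sd_mle] <- 1L
  expect_equal(unname(flags), manual)
  # a value at the fitted mean is never flagged
  center <- which.min(abs(x[1, ] - mu[1]))
  expect_equal(unname(flags[1, center]), 0L)
  # zero-variance gene gets no calls
  x[2, ] <- 3
  expect_true(all(expression_tail_calls(x)[2, ] == 0L))
})

test_that("under-call fraction is close to the nominal 5% tail", {
  set.seed(22)
  x <- matrix(rnorm(10000), 1, 10000)
  rownames(x) <- "g"
  flags <- expression_tail_calls(x)
  expect_gt(mean(flags == -1L), 0.04)
  expect_lt(mean(flags == -1L), 0.06)
})

test_that("joint SCNA ranking counts amplification-and-overexpression events", {
  samples <- paste0("s", 1:20)
  genes <- c("a", "b", "c")
  calls <- matrix(0L, 20, 3, dimnames = list(samples, genes))
  tails <- matrix(0L, 3, 20, dimnames = list(genes, samples))
  calls[1:10, "a"] <- 2L; tails["a", 1:10] <- 1L   # 10 joint events
  calls[1:5, "b"] <- 2L;  tails["b", 1:5] <- 1L    # 5 joint events
  calls[1:8, "c"] <- 2L                            # amplified, never over
  rk <- rank_scna_genes(calls, tails)
  expect_equal(rk$amplification$gene, c("a", "b"))
  expect_equal(rk$amplification$count, c(10L, 5L))
  expect_false("c" %in% rk$amplification$gene)
  # empty cohort
  empty <- rank_scna_genes(calls * 0L, tails * 0L)
  expect_equal(nrow(empty$amplification), 0)
  expect_equal(nrow(empty$deletion), 0)
})

test_that("mutation ranking counts distinct samples with non-silent records", {
  maf <- data.frame(
    Hugo_Symbol = c(rep("a", 30), rep("b", 10), "c", "c", "d", "d"),
    Tumor_Sample_Barcode = c(paste0("s", 1:30), paste0("s", 1:10),
                             "s1", "s2", "s1", "s1"),
    Variant_Classification = c(rep("Missense_Mutation", 40),
                               "Silent", "Silent",
                               "Missense_Mutation", "Nonsense_Mutation"),
    stringsAsFactors = FALSE)
  rk <- rank_mutated_genes(maf)
  expect_equal(rk$gene[1:2], c("a", "b"))
  expect_equal(rk$count[rk$gene == "a"], 30L)
  expect_false("c" %in% rk$gene)                   # silent-only excluded
  expect_equal(rk$count[rk$gene == "d"], 1L)       # same sample counted once
})
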