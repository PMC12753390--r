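test_that("one-sided Wilcoxon matches exhaustive sign enumeration (n <= 12)", {
  set.seed(17)
  for (i in seq_len(100)) {
    n <- sample(5:12, 1)
    d <- round(rnorm(n), 2)
    d[d == 0] <- 0.01
    res <- wilcoxonOneSided(d, rep(0, n), "greater")
    expect_equal(res$p, bruteForceSignedRankP(d), tolerance = 1e-12)
  }
})

test_that("Wilcoxon agrees with the reference implementation on distinct values", {
  set.seed(18)
  for (i in seq_len(20)) {
    n <- sample(6:20, 1)
    d <- rnorm(n)
    ours <- wilcoxonOneSided(d, rep(0, n), "greater")$p
    ref <- stats::wilcox.test(d, alternative = "greater", mu = 0,
                              exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("Wilcoxon handles direction, zeros, effect sizes and edge cases", {
  # n = 6 all-positive distinct differences: p = 1/64
  res <- wilcoxonOneSided(c(1, 2, 3, 4, 5, 6), rep(0, 6), "greater")
  expect_equal(res$p, 1 / 64)
  expect_equal(res$rbc, 1)
  expect_equal(res$cles, 1)

  # 'less' direction mirrors 'greater' on negated data
  d <- c(-1.2, -0.4, -3, -0.9, -2, 0.3)
  expect_equal(wilcoxonOneSided(d, rep(0, 6), "less")$p,
               wilcoxonOneSided(-d, rep(0, 6), "greater")$p)

  # zero differences are discarded; CLES counts them as half
  res2 <- wilcoxonOneSided(c(0, 0, 1, 2, 3, 4, 5), rep(0, 7), "greater")
  expect_equal(res2$nInformative, 5L)
  expect_equal(res2$cles, (5 + 2 * 0.5) / 7)

  expect_error(wilcoxonOneSided(rep(0, 8), rep(0, 8), "greater"),
               "all differences")
  expect_error(wilcoxonOneSided(c(0, 0, 0, 0, 1, 2), rep(0, 6), "greater"),
               "fewer than 5")

  # large-n normal branch stays close to the exact computation
  set.seed(19)
  d <- rnorm(40, 0.3)
  approx <- wilcoxonOneSided(d, rep(0, 40), "greater")$p
  exact <- wilcoxonOneSided(d, rep(0, 40), "greater", exactMax = 40L)$p
  expect_lt(abs(approx - exact), 0.005)
})

test_that("McNemar exact branch equals the doubled binomial tail for all b+c <= 25", {
  for (n in 1:25) for (b in 0:n) {
    cc <- n - b
    oracle <- min(1, 2 * sum(choose(n, 0:min(b, cc))) / 2^n)
    expect_equal(mcnemarP(b, cc), oracle, tolerance = 1e-12)
  }
  expect_equal(mcnemarP(8, 2), 0.109375)
  expect_equal(mcnemarP(0, 0), 1)
  # large-sample branch agrees with the reference continuity-corrected test
  tab <- matrix(c(50, 30, 14, 40), 2)
  expect_equal(mcnemarP(30, 14),
               stats::mcnemar.test(tab)$p.value, tolerance = 1e-12)
})

test_that("iterated McNemar flags an oracle and passes a null resample", {
  set.seed(20)
  truths <- sample(c("increase", "decrease"), 200, TRUE)
  cfg <- resampledBaselineConfig(seed = 7L)

  oracle <- mcnemarVsResampledBaseline(truths, truths, cfg)
  expect_lt(oracle$medianP, 0.05)
  expect_equal(length(oracle$p), 10000L)
  expect_equal(sum(oracle$histogram$count), 10000L)

  # a model that is itself a fresh resample of the null is not flagged
  nullModel <- sample(truths)
  null <- mcnemarVsResampledBaseline(nullModel, truths, cfg)
  expect_lte(null$propSignificant, 0.10)
  expect_error(mcnemarVsResampledBaseline(character(0), character(0)),
               "empty")
})

test_that("iterated Wilcoxon-vs-resampled-baseline runs per pair", {
  set.seed(21)
  truths <- sample(c("increase", "decrease"), 120, TRUE)
  pairIds <- rep(sprintf("pair%02d", 1:12), each = 10)
  res <- wilcoxonVsResampledBaseline(truths, truths, pairIds,
                                     resampledBaselineConfig(
                                       nIterationsWilcoxon = 200L, seed = 3L))
  expect_lt(res$medianP, 0.05)
})

test_that("p-value histogram uses 20 equal bins", {
  h <- pvalueHistogram(c(0.01, 0.02, 0.51, 0.99))
  expect_equal(nrow(h), 20L)
  expect_equal(sum(h$count), 4L)
  expect_equal(h$count[1], 2L)
})
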