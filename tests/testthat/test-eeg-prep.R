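test_that("scan segmentation covers half-open intervals and drops excess", {
  sig <- matrix(seq_len(2 * 80400), nrow = 2)   # 402 s at 200 Hz... 2ch
  sig <- sig[, seq_len(80200)]                  # 401 s
  segs <- segmentToScans(sig, sfreqHz = 200, trS = 2, nScans = 200)
  expect_length(segs, 200L)
  expect_true(all(vapply(segs, ncol, 0L) == 400L))
  # concatenation reconstructs the analyzed prefix exactly
  expect_equal(do.call(cbind, segs), sig[, seq_len(80000)])
  expect_error(segmentToScans(sig[, seq_len(79800)], 200, 2, 200),
               "shortfall")
})

test_that("Welch band powers recover analytic sinusoid and flat-noise values", {
  # 10 Hz sinusoid, amplitude 2 uV: alpha power = a^2/2 = 2 uV^2
  tau <- (0:399) / 200
  seg <- matrix(2 * sin(2 * pi * 10 * tau), nrow = 1)
  bp <- computeBandPowers(list(seg), sfreqHz = 200)
  expect_lt(abs(bp[1, 1, "alpha"] - 2) / 2, 0.10)
  expect_true(all(bp[1, 1, c("delta", "theta", "sigma", "beta", "gamma")] <
                    0.05 * bp[1, 1, "alpha"]))

  # all-zero segment: all powers zero
  expect_true(all(computeBandPowers(list(matrix(0, 1, 400)),
                                    sfreqHz = 200) == 0))

  # white noise with flat PSD level p: beta power ~ p * 14 Hz
  set.seed(5)
  sdNoise <- 1.5
  p <- 2 * sdNoise^2 / 200                  # one-sided level 2*sigma^2/fs
  segs <- lapply(seq_len(200), function(i) matrix(rnorm(400, sd = sdNoise), 1))
  bp <- computeBandPowers(segs, sfreqHz = 200)
  expect_lt(abs(mean(bp[, 1, "beta"]) - p * 14) / (p * 14), 0.05)

  expect_error(computeBandPowers(list(seg), bands = data.frame(
    name = "x", lowHz = 50, highHz = 150), sfreqHz = 200), "Nyquist")
})

test_that("band powers are non-negative and homogeneous of degree 2", {
  set.seed(6)
  seg <- matrix(rnorm(2 * 400), nrow = 2)
  bp1 <- computeBandPowers(list(seg), sfreqHz = 200)
  expect_true(all(bp1 >= 0))
  bp2 <- computeBandPowers(list(2 * seg), sfreqHz = 200)
  expect_equal(bp2, 4 * bp1, tolerance = 1e-6)
})

test_that("band-power normalization z-scores per channel-band and replaces |z|>4", {
  set.seed(8)
  tens <- array(rnorm(100 * 2 * 6), c(100, 2, 6),
                dimnames = list(NULL, c("ch1", "ch2"), defaultBands()$name))
  tens[, 1, 1] <- 7                           # constant series
  bpt <- normalizeBandPowers(tens)
  expect_true(all(bandPowerArray(bpt)[, 1, 1] == 0))

  # injected spike lands beyond z = 4 and is replaced by the previous scan
  tens2 <- array(rnorm(200 * 1 * 6), c(200, 1, 6),
                 dimnames = list(NULL, "ch1", defaultBands()$name))
  tens2[50, 1, 3] <- mean(tens2[, 1, 3]) + 8 * sd(tens2[, 1, 3])
  bpt2 <- normalizeBandPowers(tens2)
  v <- bandPowerArray(bpt2)
  expect_equal(v[50, 1, 3], v[49, 1, 3])
  expect_gt(sum(outlierProportions(bandPowerOutliers(bpt2))), 0)
})

test_that("study-level EEG outlier proportions stay below 0.1% per band", {
  st <- generateStudy(syntheticConfig(nSubjects = 3, nRegions = 4,
                                      nChannels = 16, nScans = 200,
                                      seed = 19))
  props <- sapply(studySessions(st), function(sess) {
    rep <- bandPowerOutliers(normalizeBandPowers(sess$bandPowers))
    # per band, pooled over channels
    colMeans(matrix(outlierProportions(rep), nrow = 16))
  })
  expect_lt(max(rowMeans(props)), 0.001)
})

test_that("band-power tensor round-trips to long TSV with sidecar", {
  tens <- array(rnorm(10 * 2 * 6), c(10, 2, 6),
                dimnames = list(NULL, c("ch1", "ch2"), defaultBands()$name))
  bpt <- normalizeBandPowers(tens)
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  writeBandPowerTensor(bpt, tsv, js)
  long <- utils::read.delim(tsv)
  expect_equal(nrow(long), 10L * 2L * 6L)
  side <- jsonlite::read_json(js)
  expect_equal(side$thresholdStd, 4)
})
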