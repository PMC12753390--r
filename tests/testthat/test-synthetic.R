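test_that("double-gamma HRF has unit peak, zero onset, peak near 5-6 s", {
  h <- makeHRF(hrfParams(), trS = 2)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  # dense-grid oracle for the peak location
  tDense <- seq(0, 32, by = 0.001)
  dense <- eegbold:::hrfDense(hrfParams(), tDense)
  peakS <- tDense[which.max(dense)]
  expect_gte(peakS, 4); expect_lte(peakS, 7)
  expect_error(hrfParams(peakDispS = -1), "positive")
})

test_that("band-power latents are seeded AR(1) with block modulation", {
  cfg <- tinyConfig()
  a <- simulateBandPowerLatents(cfg, streamSeed = 5L)
  b <- simulateBandPowerLatents(cfg, streamSeed = 5L)
  expect_identical(a, b)
  expect_false(identical(a, simulateBandPowerLatents(cfg, streamSeed = 6L)))
  expect_equal(dim(a), c(60L, 2L, 6L))

  # block amplitude 0: per-series mean within 4 SE of 0 under AR(1)
  cfg0 <- tinyConfig(blockAmp = 0)
  lat <- simulateBandPowerLatents(cfg0, streamSeed = 9L)
  rho <- 0.5; n <- dim(lat)[1]
  seMean <- sqrt((1 + rho) / (1 - rho) / n)   # long-run variance / n
  expect_lt(max(abs(apply(lat, c(2, 3), mean))), 4 * seMean)

  # large block amplitude raises task-block means in modulated series
  cfgBig <- tinyConfig(blockAmp = 5 * 1)
  latB <- simulateBandPowerLatents(cfgBig, streamSeed = 9L)
  design <- blockDesign(60L, 10L) == 1
  for (b in c("alpha", "beta"))
    expect_gt(mean(latB[design, 1, b]), mean(latB[!design, 1, b]))
})

test_that("BOLD simulation embodies causal HRF coupling, drift and noise", {
  cfg <- tinyConfig()
  h <- makeHRF(hrfParams(), cfg@trS)

  # noiseless single unit-weight pair: impulse maps to the shifted kernel
  cfgImp <- syntheticConfig(nSubjects = 1, nRegions = 1, nChannels = 1,
                            nScans = 40, blockLenScans = 10,
                            couplingGain = 1, noiseSd = 1e-12,
                            driftSlopeSd = 0, seed = 1)
  lat <- array(0, c(40, 1, 6))
  lat[5, 1, 1] <- 1
  W <- array(0, c(1, 1, 6)); W[1, 1, 1] <- 1
  bold <- simulateBold(lat, W, h, cfgImp, streamSeed = 2L)
  expected <- numeric(40)
  expected[5:min(40, 4 + length(h))] <- h[seq_len(min(36, length(h)))]
  expect_equal(as.numeric(bold), expected, tolerance = 1e-6)

  # zero coupling plus drift only: exactly linear in scan index
  cfgDrift <- syntheticConfig(nSubjects = 1, nRegions = 3, nChannels = 1,
                              nScans = 30, blockLenScans = 10,
                              couplingGain = 0, noiseSd = 1e-12,
                              driftSlopeSd = 0.5, seed = 3)
  boldD <- simulateBold(array(0, c(30, 1, 6)), array(0, c(3, 1, 6)), h,
                        cfgDrift, streamSeed = 4L)
  for (r in 1:3) {
    res <- resid(stats::lm(boldD[, r] ~ seq_len(30)))
    expect_lt(max(abs(res)), 1e-8)
  }

  # zero coupling: no lagged cross-correlation beyond the null bound
  cfg0 <- tinyConfig(couplingGain = 0)
  lat0 <- simulateBandPowerLatents(cfg0, streamSeed = 21L)
  bold0 <- simulateBold(lat0, simulateCoupling(cfg0, streamSeed = 22L), h,
                        cfg0, streamSeed = 23L)
  bound <- 4 / sqrt(cfg0@nScans)
  for (lag in 0:5) {
    n <- cfg0@nScans - lag
    cc <- abs(cor(lat0[seq_len(n), 1, 1], bold0[lag + seq_len(n), 1]))
    expect_lt(cc, bound)
  }
  expect_error(simulateBold(lat0, array(0, c(2, 9, 9)), h, cfg0),
               "inconsistent")
})

test_that("generateStudy fills all sessions deterministically with stable substreams", {
  cfg <- tinyConfig()
  st <- generateStudy(cfg)
  expect_s4_class(st, "SyntheticStudy")
  expect_length(studySessions(st), 6L)
  s1 <- studySessions(st)[[1]]
  expect_equal(dim(s1$bold), c(60L, 4L))
  expect_equal(dim(s1$bandPowers), c(60L, 2L, 6L))
  expect_identical(studySessions(generateStudy(cfg)), studySessions(st))

  # adding a subject never changes earlier subjects
  cfg3 <- tinyConfig(); cfg3@nSubjects <- 3L
  st3 <- generateStudy(cfg3)
  for (key in names(studySessions(st)))
    expect_identical(studySessions(st3)[[key]], studySessions(st)[[key]])
})

test_that("default study dimensions match the 9 x 3 x 49 design", {
  cfg <- syntheticConfig()
  expect_equal(cfg@nSubjects, 9L)
  expect_length(cfg@conditions, 3L)
  expect_equal(cfg@nRegions, 49L)
  expect_equal(cfg@nChannels, 64L)
  expect_equal(cfg@trS, 2)
  expect_equal(cfg@sfreqHz, 200)
  expect_error(syntheticConfig(nScans = 55L, blockLenScans = 20L),
               "divisible")
})

test_that("OLS on HRF-convolved latents recovers coupling signs", {
  cfg <- syntheticConfig(nSubjects = 1, nRegions = 6, nChannels = 2,
                         nScans = 400, blockLenScans = 20,
                         couplingGain = 5, noiseSd = 0.2,
                         driftSlopeSd = 0, outlierRate = 0, seed = 31)
  st <- generateStudy(cfg)
  sess <- studySessions(st)[[1]]
  W <- studyTruth(st)$coupling[["sub-01"]]
  h <- studyTruth(st)$hrfKernel
  lat <- sess$bandPowers
  conv <- apply(matrix(lat, cfg@nScans, 12), 2,
                function(x) eegbold:::causalConvolve(x, h))
  agree <- 0L; total <- 0L
  for (r in seq_len(cfg@nRegions)) {
    beta <- coef(stats::lm(sess$bold[, r] ~ conv))[-1]
    w <- as.vector(W[r, , ])
    nz <- which(w != 0)
    agree <- agree + sum(sign(beta[nz]) == sign(w[nz]) * sign(cfg@couplingGain))
    total <- total + length(nz)
  }
  expect_gte(agree / total, 0.95)
})

test_that("raw EEG realizes latent band powers recoverable by Welch analysis", {
  cfg <- syntheticConfig(nSubjects = 1, nRegions = 2, nChannels = 1,
                         nScans = 10, blockLenScans = 5, seed = 17,
                         outlierRate = 0)
  st <- generateStudy(cfg, rawEEG = TRUE, rawPowerOffset = 40,
                      rawNoiseSd = 0.05)
  sess <- studySessions(st)[[1]]
  expect_equal(ncol(sess$rawEEG), 10 * 2 * 200)
  segs <- segmentToScans(sess$rawEEG, cfg@sfreqHz, cfg@trS, cfg@nScans)
  bp <- computeBandPowers(segs, sfreqHz = cfg@sfreqHz)
  target <- pmax(sess$bandPowers[, 1, "alpha"] + 40, 0)
  expect_lt(max(abs(bp[, 1, "alpha"] - target) / target), 0.10)
})

test_that("study writer produces the BIDS-inspired TSV/JSON layout", {
  st <- generateStudy(tinyConfig())
  dir <- tempfile()
  writeStudy(st, dir)
  expect_true(file.exists(file.path(dir, "sub-01", "eegfmriNF", "bold.tsv")))
  expect_true(file.exists(file.path(dir, "sub-02", "fmriNF",
                                    "band_powers.tsv")))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$config$nSubjects, 2L)
  bold <- utils::read.delim(file.path(dir, "sub-01", "eegfmriNF", "bold.tsv"))
  expect_equal(dim(bold), c(60L, 4L))
})
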