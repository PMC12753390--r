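goldenSingleChannel <- paste0(
  "A human subject participated in a neuroscience experiment where EEG ",
  "data and fMRI data were recorded simultaneously. The EEG band powers ",
  "were measured every two seconds at electrode Fpz, with the following ",
  "results: {Delta (1–4 Hz): [0.12, -0.34], Theta (4–8 Hz): ",
  "[1.00, 0.50]}. The fMRI BOLD signal was measured in the Frontal Pole ",
  "during the last two seconds. Given the EEG data, is the fMRI signal in ",
  "this brain region likely increasing or decreasing during these last ",
  "two seconds? Base your answer on your general knowledge in ",
  "neuroscience, EEG research, and fMRI research. Since this is a time ",
  "series, you might need to take into account the hemodynamic response ",
  "function (HRF), and the fact that after an event, the fMRI response is ",
  "delayed compared to the EEG response. Please answer with only one ",
  "word: Increasing or Decreasing. Just give your best prediction, ",
  "without any explanation.")

twoBandValues <- function() {
  m <- rbind(c(0.123, -0.341), c(0.999, 0.5))
  rownames(m) <- c("delta", "theta")
  m
}

test_that("the single-channel prompt matches its golden text byte for byte", {
  map <- readRegionChannelMap()
  b <- buildPrompt("single_channel", map, twoBandValues(), "Frontal Pole")
  expect_identical(b$text, goldenSingleChannel)
  # byte-identical across calls
  expect_identical(buildPrompt("single_channel", map, twoBandValues(),
                               "Frontal Pole")$text, b$text)
  expect_error(buildPrompt("single_channel", map, twoBandValues(),
                           "Atlantis"), "not present")
})

test_that("every prompt mode renders its required slots", {
  map <- readRegionChannelMap()
  s1 <- buildPrompt("cot_step1", map, twoBandValues(), "Frontal Pole")
  expect_match(s1$text, "at electrode Fpz", fixed = TRUE)
  expect_match(s1$text, "which cognitive functions is the subject likely engaging in?",
               fixed = TRUE)
  expect_match(s1$text, "only a list of cognitive functions", fixed = TRUE)

  s2 <- buildPrompt("cot_step2", map, region = "Frontal Pole",
                    functions = c("Attention", "Working Memory"))
  expect_match(s2$text,
               "experienced the following cognitive functions: Attention, Working Memory",
               fixed = TRUE)
  expect_match(s2$text, "in the Frontal Pole", fixed = TRUE)
  expect_error(buildPrompt("cot_step2", map, region = "Frontal Pole"),
               "cognitive functions")

  mm <- buildPrompt("multimodal", map, region = "Cuneal Cortex",
                    band = "beta", attachment = "topomap-0042")
  expect_match(mm$text, "band power Beta (16–30 Hz)", fixed = TRUE)
  expect_match(mm$text, "four seconds after that", fixed = TRUE)
  expect_length(mm$attachments, 1L)
  expect_error(buildPrompt("multimodal", map, region = "Cuneal Cortex"),
               "attachment")

  arr <- array(rnorm(5 * 2 * 3), c(5, 2, 3),
               dimnames = list(NULL, c("alpha", "beta"), NULL))
  f5 <- buildPrompt("five_channel", map, arr, "Frontal Pole")
  expect_match(f5$text, "at electrodes Fpz, Fp1, Fp2, AFz, AF4", fixed = TRUE)
  # nested: electrode labels precede their own band dictionaries
  expect_match(f5$text, "Fpz: \\{Alpha \\(8–12 Hz\\)")
  expect_error(buildPrompt("five_channel", map, arr[1:3, , ], "Frontal Pole"),
               "5 x bands")
})

test_that("the parser is total and follows the keyword rule exactly", {
  fixtures <- list(
    list("Increasing.", "increase"),
    list("Decreasing.", "decrease"),
    list("The signal is likely increasing over this window.", "increase"),
    list("It DECREASED sharply.", "decrease"),
    list("increase decrease increase decrease", "invalid"),
    list("Both an increase and a decrease are possible.", "invalid"),
    list("I cannot determine this.", "invalid"),
    list("", "invalid"),
    list("The increases were notable.", "increase"),
    list("no change expected", "invalid"),
    list("Answer: Decreasing", "decrease"),
    list("INCREASING", "increase"))
  labels <- vapply(fixtures, function(f) parseResponse(f[[1]])$label, "")
  expect_identical(labels, vapply(fixtures, `[[`, "", 2L))
  # matched spans record the inflected evidence
  expect_equal(parseResponse("It increases and increased.")$matchedSpans,
               c("increases", "increased"))
})

test_that("foundation evaluation excludes invalids and keeps the books balanced", {
  set.seed(24)
  map <- readRegionChannelMap()
  truths <- sample(c("increase", "decrease"), 120, TRUE)
  bundles <- lapply(seq_along(truths), function(i)
    buildPrompt("single_channel", map, twoBandValues(), "Frontal Pole",
                provenance = list(scan = i)))
  cfg <- resampledBaselineConfig(nIterationsWilcoxon = 100L,
                                 nIterationsMcnemar = 500L, seed = 9L)

  oracle <- runFoundationEval(bundles, mockBackendOracle(truths), truths, cfg)
  expect_equal(oracle$accuracy, 1)
  expect_equal(oracle$invalidProportion, 0)
  expect_equal(oracle$nEvaluated + oracle$nInvalid, length(bundles))

  # constant answers on balanced truths: near-chance, null not rejected
  const <- runFoundationEval(bundles, mockBackendConstant("Increasing."),
                             truths, cfg)
  expect_lt(abs(const$accuracy - 0.5), 0.15)
  expect_gt(const$mcnemar$medianP, 0.2)

  # injected keyword-free responses are excluded at the injection rate
  noisy <- runFoundationEval(bundles,
                             mockBackendNoisy(mockBackendOracle(truths),
                                              invalidRate = 0.05, seed = 2L),
                             truths, cfg)
  expect_lt(abs(noisy$invalidProportion - 0.05), 0.06)
  expect_equal(noisy$accuracy, 1)        # valid responses stay aligned
  expect_equal(noisy$nEvaluated + noisy$nInvalid, length(bundles))
  expect_equal(nrow(noisy$log), length(bundles))

  # a crashing backend is an invalid prediction, not an error
  boom <- function(prompt) stop("backend offline")
  mixed <- runFoundationEval(bundles[1:10],
                             function(p) if (runif(1) < 0.5) boom(p)
                                         else "Increasing.",
                             truths[1:10], cfg)
  expect_equal(mixed$nEvaluated + mixed$nInvalid, 10L)
})

test_that("scan subsetting is seeded and bounded", {
  s1 <- selectScanSubset(200, 30, seed = 4L)
  expect_identical(s1, selectScanSubset(200, 30, seed = 4L))
  expect_length(s1, 30L)
  expect_true(all(s1 >= 0 & s1 <= 199))
  expect_error(selectScanSubset(10, 11), "exceeds")
})
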