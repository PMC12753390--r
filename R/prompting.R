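#' Region-to-channel mapping
#'
#' Associates each atlas region with EEG channels: the first channel is
#' the single-channel predictor, the full row of five supports the
#' extended hierarchical mode. The shipped default
#' (`system.file("extdata", "region_channel_map.tsv", package =
#' "eegbold")`) covers a proximity-based subset of cortical regions and is
#' meant to be replaced wholesale by the user's own table.
#'
#' @param path TSV with columns `region`, `channel1` .. `channel5`
#'   (default: the shipped table).
#' @return data.frame of class `RegionChannelMap`.
#' @export
readRegionChannelMap <- function(path = system.file("extdata",
                                   "region_channel_map.tsv",
                                   package = "eegbold")) {
  map <- utils::read.delim(path, check.names = FALSE)
  need <- c("region", paste0("channel", 1:5))
  if (!all(need %in% names(map)))
    stop("map must have columns region, channel1..channel5")
  if (anyDuplicated(map$region)) stop("regions must be unique")
  class(map) <- c("RegionChannelMap", "data.frame")
  map
}

mapChannels <- function(map, region, n) {
  row <- map[map$region == region, , drop = FALSE]
  if (nrow(row) == 0L) stop("region not present in the channel map: ", region)
  as.character(unlist(row[1, paste0("channel", seq_len(n))]))
}

bandLabel <- function(name, bands = defaultBands()) {
  b <- bands[bands$name == name, ]
  sprintf("%s (%g\u2013%g Hz)",
          paste0(toupper(substring(name, 1, 1)), substring(name, 2)),
          b$lowHz, b$highHz)
}

# dictionary-like serialization of one channel's band-power window
formatBandValues <- function(values, digits = 2) {
  # values: bands x timesteps matrix with band-name rownames
  entries <- vapply(rownames(values), function(b)
    sprintf("%s: [%s]", bandLabel(b),
            paste(sprintf(paste0("%.", digits, "f"), values[b, ]),
                  collapse = ", ")),
    "")
  paste0("{", paste(entries, collapse = ", "), "}")
}

promptTemplates <- function() {
  intro <- paste0("A human subject participated in a neuroscience experiment ",
                  "where EEG data and fMRI data were recorded simultaneously. ")
  ask <- paste0("Please answer with only one word: Increasing or Decreasing. ",
                "Just give your best prediction, without any explanation.")
  list(
    single_channel = paste0(intro,
      "The EEG band powers were measured every two seconds at electrode ",
      "%CHANNEL%, with the following results: %RESULTS%. The fMRI BOLD ",
      "signal was measured in the %REGION% during the last two seconds. ",
      "Given the EEG data, is the fMRI signal in this brain region likely ",
      "increasing or decreasing during these last two seconds? Base your ",
      "answer on your general knowledge in neuroscience, EEG research, and ",
      "fMRI research. Since this is a time series, you might need to take ",
      "into account the hemodynamic response function (HRF), and the fact ",
      "that after an event, the fMRI response is delayed compared to the ",
      "EEG response. ", ask),
    cot_step1 = paste0(intro,
      "The EEG band powers were measured every two seconds at electrode ",
      "%CHANNEL%, with the following results: %RESULTS%. Given the EEG ",
      "data, which cognitive functions is the subject likely engaging in? ",
      "Base your answer on your general knowledge in neuroscience and EEG ",
      "research. Please answer with only a list of cognitive functions. ",
      "Just give your best prediction, without any explanation."),
    cot_step2 = paste0(intro,
      "This subject experienced the following cognitive functions: ",
      "%FUNCTIONS%. The fMRI BOLD signal was measured in the %REGION%. ",
      "Given the cognitive functions, is the fMRI signal in this brain ",
      "region likely increasing or decreasing? Base your answer on your ",
      "general knowledge in neuroscience and fMRI research. ", ask),
    multimodal = paste0(intro,
      "This EEG topographic map shows the brain activity pattern observed ",
      "for the band power %BAND%. The fMRI BOLD signal was measured in the ",
      "%REGION% four seconds after that. Given the EEG data, is the fMRI ",
      "signal in this brain region likely increasing or decreasing? Base ",
      "your answer on your general knowledge in neuroscience, EEG ",
      "research, and fMRI research. ", ask),
    five_channel = paste0(intro,
      "The EEG band powers were measured every two seconds at electrodes ",
      "%CHANNELS%, with the following results: %RESULTS%. The fMRI BOLD ",
      "signal was measured in the %REGION% during the last two seconds. ",
      "Given the EEG data, is the fMRI signal in this brain region likely ",
      "increasing or decreasing during these last two seconds? Base your ",
      "answer on your general knowledge in neuroscience, EEG research, and ",
      "fMRI research. Since this is a time series, you might need to take ",
      "into account the hemodynamic response function (HRF), and the fact ",
      "that after an event, the fMRI response is delayed compared to the ",
      "EEG response. ", ask))
}

#' Build a prediction prompt
#'
#' Deterministically fills the mode's template: channel and region in
#' plain text, band powers as a dictionary-like structure mapping each
#' band label (e.g. `"Beta (16-30 Hz)"`) to the comma-separated windowed
#' values in square brackets, numeric values at a fixed decimal
#' precision. The five-channel mode nests the band dictionaries under
#' their electrode labels; the multimodal mode carries an attachment
#' reference instead of numeric results.
#'
#' @param mode one of `single_channel`, `cot_step1`, `cot_step2`,
#'   `multimodal`, `five_channel`.
#' @param map a `RegionChannelMap` ([readRegionChannelMap()]).
#' @param bandValues for single-channel/CoT modes a bands x timesteps
#'   matrix (band names as rownames); for five-channel mode a
#'   channels x bands x timesteps array.
#' @param region atlas region label.
#' @param functions character vector of predicted cognitive functions
#'   (cot_step2 only).
#' @param band band name for the multimodal mode (default `"beta"`).
#' @param attachment attachment reference for the multimodal mode.
#' @param digits decimal places for formatted values (default 2).
#' @param provenance optional list (subject, condition, scan) recorded in
#'   the bundle.
#' @return List of class `PromptBundle`: `mode`, `text`, `attachments`,
#'   `provenance`.
#' @export
buildPrompt <- function(mode = c("single_channel", "cot_step1", "cot_step2",
                                 "multimodal", "five_channel"),
                        map, bandValues = NULL, region,
                        functions = NULL, band = "beta",
                        attachment = NULL, digits = 2,
                        provenance = list()) {
  mode <- match.arg(mode)
  tpl <- promptTemplates()[[mode]]
  text <- tpl
  attachments <- character(0)
  if (mode %in% c("single_channel", "cot_step1")) {
    channel <- mapChannels(map, region, 1L)
    if (is.null(bandValues) || is.null(rownames(bandValues)))
      stop("bandValues must be a bands x timesteps matrix with band rownames")
    text <- gsub("%CHANNEL%", channel, text, fixed = TRUE)
    text <- gsub("%RESULTS%", formatBandValues(bandValues, digits), text,
                 fixed = TRUE)
  } else if (mode == "cot_step2") {
    if (is.null(functions) || length(functions) == 0L)
      stop("cot_step2 requires a list of cognitive functions")
    text <- gsub("%FUNCTIONS%", paste(functions, collapse = ", "), text,
                 fixed = TRUE)
  } else if (mode == "multimodal") {
    if (is.null(attachment) || length(attachment) != 1L)
      stop("multimodal mode requires exactly one attachment reference")
    text <- gsub("%BAND%", bandLabel(band), text, fixed = TRUE)
    attachments <- as.character(attachment)
  } else if (mode == "five_channel") {
    channels <- mapChannels(map, region, 5L)
    d <- dim(bandValues)
    if (is.null(d) || length(d) != 3L || d[1] != 5L)
      stop("five_channel mode needs a 5 x bands x timesteps array")
    nested <- vapply(seq_len(5L), function(i) {
      m <- bandValues[i, , , drop = TRUE]
      if (is.null(dim(m))) m <- matrix(m, nrow = dim(bandValues)[2])
      rownames(m) <- dimnames(bandValues)[[2]]
      sprintf("%s: %s", channels[i], formatBandValues(m, digits))
    }, "")
    text <- gsub("%CHANNELS%", paste(channels, collapse = ", "), text,
                 fixed = TRUE)
    text <- gsub("%RESULTS%", paste0("{", paste(nested, collapse = ", "), "}"),
                 text, fixed = TRUE)
  }
  if (mode != "cot_step1")
    text <- gsub("%REGION%", region, text, fixed = TRUE)
  structure(list(mode = mode, text = text, attachments = attachments,
                 provenance = provenance),
            class = "PromptBundle")
}

#' Parse a generated response into a direction label
#'
#' Case-insensitive match on the word stems `increas-` and `decreas-`
#' (covering all inflected forms: increases, increased, increasing, ...).
#' Exactly one stem family present yields that label; zero or both yield
#' `invalid`. Never throws: invalid is a value, not an error.
#'
#' @param raw response text.
#' @return List of class `ParsedPrediction`: `label` (`increase`,
#'   `decrease` or `invalid`), `matchedSpans`, `rawResponse`.
#' @examples
#' parseResponse("Increasing.")$label
#' parseResponse("increase decrease increase decrease")$label   # invalid
#' @export
parseResponse <- function(raw) {
  raw <- if (length(raw) == 1L && !is.na(raw)) as.character(raw) else ""
  inc <- regmatches(raw, gregexpr("(?i)increas\\w*", raw, perl = TRUE))[[1]]
  dec <- regmatches(raw, gregexpr("(?i)decreas\\w*", raw, perl = TRUE))[[1]]
  label <- if (length(inc) > 0L && length(dec) == 0L) "increase"
    else if (length(dec) > 0L && length(inc) == 0L) "decrease"
    else "invalid"
  structure(list(label = label, matchedSpans = c(inc, dec),
                 rawResponse = raw),
            class = "ParsedPrediction")
}

#' Deterministic mock text-generation backends
#'
#' Backends satisfy the generation contract: a function taking the prompt
#' text and returning a response string, with declared determinism.
#' `mockBackendOracle` answers from the supplied truth sequence in order;
#' `mockBackendConstant` always returns the same response;
#' `mockBackendNoisy` wraps another backend and replaces a fixed fraction
#' of responses with keyword-free text;
#' `mockBackendResample` answers randomly from the empirical truth
#' distribution (a realization of the null baseline).
#'
#' @param truths character vector of true labels (`increase`/`decrease`).
#' @return A backend function of one argument (the prompt text).
#' @export
mockBackendOracle <- function(truths) {
  i <- 0L
  words <- c(increase = "Increasing.", decrease = "Decreasing.")
  function(prompt) {
    i <<- i + 1L
    words[[as.character(truths[i])]]
  }
}

#' @rdname mockBackendOracle
#' @param response fixed response text.
#' @export
mockBackendConstant <- function(response = "Increasing.") {
  function(prompt) response
}

#' @rdname mockBackendOracle
#' @param backend backend to wrap.
#' @param invalidRate fraction of responses replaced by keyword-free text.
#' @param seed integer seed.
#' @export
mockBackendNoisy <- function(backend, invalidRate = 0.05, seed = 1L) {
  rng <- withSeed(seed, stats::runif(1e5))
  i <- 0L
  function(prompt) {
    i <<- i + 1L
    resp <- backend(prompt)   # always consume the wrapped backend
    if (rng[((i - 1L) %% length(rng)) + 1L] < invalidRate)
      "I cannot determine this from the data provided."
    else resp
  }
}

#' @rdname mockBackendOracle
#' @export
mockBackendResample <- function(truths, seed = 1L) {
  labs <- sort(unique(as.character(truths)))
  probs <- as.numeric(table(factor(truths, levels = labs))) / length(truths)
  draws <- withSeed(seed, sample(labs, length(truths) + 1000L,
                                 replace = TRUE, prob = probs))
  words <- c(increase = "Increasing.", decrease = "Decreasing.")
  i <- 0L
  function(prompt) {
    i <<- i + 1L
    words[[draws[i]]]
  }
}

#' Evaluate a text-generation backend on prompt bundles
#'
#' Queries the backend once per bundle, parses each response
#' ([parseResponse()]), excludes invalid predictions (reporting their
#' proportion), and runs the resampled-baseline statistics: the iterated
#' McNemar test ([mcnemarVsResampledBaseline()]) and, when `pairIds` is
#' given, the iterated Wilcoxon path
#' ([wilcoxonVsResampledBaseline()]). A backend error is recorded as an
#' invalid prediction, never a crash.
#'
#' @param bundles list of `PromptBundle`s (see [buildPrompt()]).
#' @param backend a backend function (see [mockBackendOracle()]).
#' @param truths aligned true labels.
#' @param cfg a [resampledBaselineConfig()].
#' @param pairIds optional grouping vector for the Wilcoxon path.
#' @return List: `accuracy` (on valid predictions), `invalidProportion`,
#'   `nEvaluated`, `nInvalid`, `predictions`, `labels`, `mcnemar`,
#'   `wilcoxon` (or NULL), `log` (data.frame of raw responses and parsed
#'   labels).
#' @export
runFoundationEval <- function(bundles, backend, truths,
                              cfg = resampledBaselineConfig(),
                              pairIds = NULL) {
  if (length(bundles) != length(truths)) stop("bundles/truths misaligned")
  parsed <- lapply(seq_along(bundles), function(i) {
    resp <- tryCatch(backend(bundles[[i]]$text),
                     error = function(e) "")
    parseResponse(resp)
  })
  labels <- vapply(parsed, `[[`, "", "label")
  valid <- labels != "invalid"
  nInvalid <- sum(!valid)
  if (!any(valid)) stop("empty prediction set after exclusions")
  truths <- as.character(truths)
  acc <- mean(labels[valid] == truths[valid])
  mcn <- mcnemarVsResampledBaseline(labels[valid], truths[valid], cfg)
  wil <- if (!is.null(pairIds))
    wilcoxonVsResampledBaseline(labels[valid], truths[valid],
                                pairIds[valid], cfg) else NULL
  list(accuracy = acc,
       invalidProportion = nInvalid / length(bundles),
       nEvaluated = sum(valid), nInvalid = nInvalid,
       predictions = labels[valid], labels = labels,
       mcnemar = mcn, wilcoxon = wil,
       log = data.frame(label = labels,
                        response = vapply(parsed, `[[`, "", "rawResponse")))
}

#' Select a scan subset for foundation-model evaluation
#'
#' The foundation branch is evaluated on a sampled subset of scans; the
#' selection rule is a uniform draw without replacement, controlled by a
#' count and a seed.
#'
#' @param nScans total available scans (0-based indices `0..nScans-1`).
#' @param count subset size.
#' @param seed integer seed.
#' @return Sorted integer vector of 0-based scan indices.
#' @export
selectScanSubset <- function(nScans, count, seed = 1L) {
  if (count > nScans) stop("count exceeds available scans")
  sort(withSeed(seed, sample.int(nScans, count)) - 1L)
}
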