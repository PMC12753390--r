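#' Condition-rotation cross-validation plan
#'
#' Cyclic threefold rotation over exactly three recording conditions:
#' iteration i trains on condition i and tests on condition i+1 (mod 3),
#' so every condition is used exactly once for training and once for
#' testing. The remaining condition is left out for classical models and
#' serves as the validation set for neural models.
#'
#' @param conditions ordered character vector of exactly 3 condition
#'   labels.
#' @param needsValidation logical: third condition is `validation`
#'   (neural) rather than `left_out` (classical).
#' @return data.frame with columns `iteration`, `train`, `test`, `third`,
#'   `thirdRole`.
#' @examples
#' makeCvPlan(c("eegfmriNF", "eegNF", "fmriNF"))
#' @export
makeCvPlan <- function(conditions, needsValidation = FALSE) {
  if (length(conditions) != 3L || anyDuplicated(conditions))
    stop("exactly 3 distinct conditions are required")
  i <- 1:3
  test <- i %% 3L + 1L
  third <- 6L - i - test
  data.frame(iteration = i, train = conditions[i], test = conditions[test],
             third = conditions[third],
             thirdRole = if (needsValidation) "validation" else "left_out")
}

#' Constant baseline predictors
#'
#' The classification baseline always predicts an increase (the majority
#' class on nearly balanced data); the regression baseline always
#' predicts 0, the mean of the z-normalized signal.
#'
#' @param task `"classification"` or `"regression"`.
#' @return A [ModelSpec-class] for the corresponding dummy family.
#' @export
constantBaselines <- function(task = c("classification", "regression")) {
  task <- match.arg(task)
  if (task == "classification") modelSpec("constant_increase", task)
  else modelSpec("constant_mean", task)
}

baselineMetric <- function(truth, task) {
  if (task == "classification") mean(truth == "increase")
  else mean(abs(truth))
}

#' Per-model statistical report
#'
#' @slot models data.frame: per model the mean metric, its standard error
#'   across pairs, one-sided Wilcoxon p against the constant baseline,
#'   RBC, CLES and (regression) the mean per-pair Pearson r.
#' @slot pairwise numeric matrix of one-sided Wilcoxon p-values; entry
#'   (i, j) tests whether model i beats model j.
#' @slot roi data.frame: per region and model the mean metric and a raw
#'   Wilcoxon p, plus a Benjamini-Hochberg adjusted column (`pBH`, an
#'   artifact extra).
#' @slot pairs the full per-pair result table.
#' @slot exclusions data.frame of (subject, region, iteration, model,
#'   reason) dropped from the design.
#' @export
setClass("StatReport",
  representation(models = "data.frame", pairwise = "matrix",
                 roi = "data.frame", pairs = "data.frame",
                 exclusions = "data.frame"))

setMethod("show", "StatReport", function(object) {
  cat(sprintf("StatReport: %d pairs, %d models, %d exclusions\n",
              nrow(object@pairs), nrow(object@models),
              nrow(object@exclusions)))
  print(object@models, digits = 3)
})

#' @describeIn StatReport per-model summary table
#' @param x a `StatReport`
#' @export
modelSummary <- function(x) x@models

#' @describeIn StatReport per-pair result table
#' @export
pairResults <- function(x) x@pairs

#' @describeIn StatReport per-region table
#' @export
roiTable <- function(x) x@roi

#' @describeIn StatReport pairwise model-vs-model p matrix
#' @export
pairwiseTests <- function(x) x@pairwise

#' Run the full prediction study on a synthetic (or preloaded) study
#'
#' Executes preprocessing (band-power normalization at |z| > 4; BOLD
#' detrend, normalize, |z| > 3 replacement), lagged feature construction,
#' the condition-rotation cross-validation, a fit/predict per
#' (subject, region, iteration, model), per-pair metrics against the
#' constant baseline, and the statistical layer. Deterministic given the
#' model seeds.
#'
#' @param study a [SyntheticStudy-class] (or a compatible list with
#'   `config` and `sessions`).
#' @param models list of [ModelSpec-class]s (all with the same task).
#' @param nLags lag depth for the features (default 5).
#' @param minTrainSamples pairs whose training set degenerates below this
#'   size are excluded and logged.
#' @return A [StatReport-class].
#' @export
runExperiment <- function(study, models, nLags = 5L, minTrainSamples = 10L) {
  cfg <- if (is(study, "SyntheticStudy")) study@config else study$config
  sessions <- if (is(study, "SyntheticStudy")) study@sessions else study$sessions
  task <- models[[1]]@task
  if (!all(vapply(models, function(m) m@task, "") == task))
    stop("all models must share one task")
  modelNames <- vapply(models, function(m) m@family, "")
  if (anyDuplicated(modelNames))
    modelNames <- make.unique(modelNames)
  anyNeural <- any(vapply(models, function(m) m@family %in% NEURAL_FAMILIES,
                          TRUE))
  plan <- makeCvPlan(cfg@conditions, needsValidation = anyNeural)
  subjects <- unique(vapply(strsplit(names(sessions), ".", fixed = TRUE),
                            `[`, "", 1L))
  # preprocess and featurize each session once
  prep <- lapply(sessions, function(sess) {
    bpt <- normalizeBandPowers(sess$bandPowers)
    rts <- preprocessBold(sess$bold, trS = cfg@trS)
    feat <- buildFeatures(bpt, nLags)
    list(bpt = bpt, rts = rts, feat = feat)
  })
  regions <- regionNames(prep[[1]]$rts)

  targetsFor <- function(p, region) {
    tgt <- buildTargets(p$rts, region)
    keep <- p$feat$scans
    list(yClass = tgt$yClass[match(keep, tgt$scans)],
         yReg = unname(tgt$yReg[keep + 1L]))
  }

  rows <- list()
  excl <- list()
  for (s in subjects) {
    for (it in seq_len(nrow(plan))) {
      pTr <- prep[[paste(s, plan$train[it], sep = ".")]]
      pTe <- prep[[paste(s, plan$test[it], sep = ".")]]
      pVa <- prep[[paste(s, plan$third[it], sep = ".")]]
      for (region in regions) {
        trT <- targetsFor(pTr, region)
        teT <- targetsFor(pTe, region)
        vaT <- targetsFor(pVa, region)
        yTr <- if (task == "classification") trT$yClass else trT$yReg
        yTe <- if (task == "classification") teT$yClass else teT$yReg
        train <- list(X = pTr$feat$X, yClass = trT$yClass, yReg = trT$yReg)
        val <- list(X = pVa$feat$X, yClass = vaT$yClass, yReg = vaT$yReg)
        base <- baselineMetric(yTe, task)
        for (m in seq_along(models)) {
          ok <- TRUE
          if (task == "classification" && length(unique(yTr)) < 2L)
            ok <- FALSE
          if (!ok || length(yTr) < minTrainSamples) {
            excl[[length(excl) + 1L]] <- data.frame(
              subject = s, region = region, iteration = it,
              model = modelNames[m],
              reason = if (!ok) "single-class training labels"
                       else "too few training samples")
            next
          }
          fitted <- fitModel(models[[m]], train,
                             val = if (models[[m]]@family %in% NEURAL_FAMILIES)
                               val else NULL)
          pred <- predict(fitted, pTe$feat$X)
          metric <- predictionMetric(pred, yTe, task)
          pearson <- if (task == "regression" && stats::sd(pred) > 0)
            stats::cor(pred, yTe) else NA_real_
          rows[[length(rows) + 1L]] <- data.frame(
            subject = s, region = region, model = modelNames[m],
            iteration = it, metric = metric, baselineMetric = base,
            pearson = pearson, nSamples = length(yTe))
        }
      }
    }
  }
  pairs <- do.call(rbind, rows)
  exclusions <- if (length(excl)) do.call(rbind, excl)
    else data.frame(subject = character(0), region = character(0),
                    iteration = integer(0), model = character(0),
                    reason = character(0))
  computeStatReport(pairs, task, exclusions = exclusions)
}

#' Statistical layer over a per-pair result table
#'
#' @param pairs data.frame with columns subject, region, model, iteration,
#'   metric, baselineMetric (and optionally pearson, nSamples).
#' @param task `"classification"` or `"regression"`.
#' @param exclusions optional exclusion log carried into the report.
#' @return A [StatReport-class].
#' @export
computeStatReport <- function(pairs, task,
                              exclusions = data.frame()) {
  direction <- if (task == "classification") "greater" else "less"
  modelNames <- unique(pairs$model)
  perModel <- lapply(modelNames, function(m) {
    sub <- pairs[pairs$model == m, ]
    w <- tryCatch(wilcoxonOneSided(sub$metric, sub$baselineMetric, direction),
                  error = function(e) list(p = NA_real_, rbc = NA_real_,
                                           cles = NA_real_))
    data.frame(model = m, nPairs = nrow(sub), meanMetric = mean(sub$metric),
               seMetric = stats::sd(sub$metric) / sqrt(nrow(sub)),
               meanBaseline = mean(sub$baselineMetric),
               p = w$p, rbc = w$rbc, cles = w$cles,
               meanPearson = if (task == "regression")
                 mean(sub$pearson, na.rm = TRUE) else NA_real_)
  })
  models <- do.call(rbind, perModel)

  pairwise <- matrix(NA_real_, length(modelNames), length(modelNames),
                     dimnames = list(modelNames, modelNames))
  key <- function(sub) paste(sub$subject, sub$region, sub$iteration)
  for (a in modelNames) for (b in modelNames) {
    if (a == b) next
    sa <- pairs[pairs$model == a, ]
    sb <- pairs[pairs$model == b, ]
    sb <- sb[match(key(sa), key(sb)), ]
    pairwise[a, b] <- tryCatch(
      wilcoxonOneSided(sa$metric, sb$metric, direction)$p,
      error = function(e) NA_real_)
  }

  roiRows <- list()
  for (m in modelNames) for (r in unique(pairs$region)) {
    sub <- pairs[pairs$model == m & pairs$region == r, ]
    p <- tryCatch(wilcoxonOneSided(sub$metric, sub$baselineMetric,
                                   direction)$p,
                  error = function(e) NA_real_)
    roiRows[[length(roiRows) + 1L]] <- data.frame(
      region = r, model = m, nPairs = nrow(sub),
      meanMetric = mean(sub$metric), p = p)
  }
  roi <- do.call(rbind, roiRows)
  roi$pBH <- stats::ave(roi$p, roi$model,
                        FUN = function(p) stats::p.adjust(p, "BH"))
  new("StatReport", models = models, pairwise = pairwise, roi = roi,
      pairs = pairs, exclusions = exclusions)
}

#' Write a StatReport to a directory
#'
#' Per-pair table, per-model summary, per-ROI table as TSV; the model
#' summary also as JSON.
#'
#' @param report a [StatReport-class].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeStatReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.table(df, file.path(dir, name),
    sep = "\t", row.names = FALSE, quote = FALSE)
  w(report@pairs, "pair_results.tsv")
  w(report@models, "model_summary.tsv")
  w(report@roi, "roi_table.tsv")
  w(as.data.frame(report@pairwise), "pairwise_p.tsv")
  if (nrow(report@exclusions)) w(report@exclusions, "exclusions.tsv")
  jsonlite::write_json(report@models, file.path(dir, "model_summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Pipeline calibration over replicate synthetic studies
#'
#' Runs the full pipeline (generation, preprocessing, features,
#' condition-rotation CV, model fit, one-sided Wilcoxon against the
#' constant baseline) on independent replicate studies at a given
#' coupling gain, and reports each replicate's p-value and pooled
#' accuracy. With `couplingGain = 0` this measures the false-rejection
#' rate of the statistical layer (nominally 5% at alpha = 0.05); with
#' increasing gains it traces the power curve. Replicates use scaled-down
#' studies (default 3 subjects, 8 regions, 2 channels, 120 scans) so that
#' hundreds of replicates stay cheap.
#'
#' @param nReplicates number of replicate studies.
#' @param couplingGain coupling gain for every replicate.
#' @param seed master seed; replicate r uses an independent substream.
#' @param model a [ModelSpec-class] (default 5-nearest-neighbour
#'   classification, a fast family with no training randomness).
#' @param nSubjects,nRegions,nChannels,nScans,blockLenScans scaled-down
#'   study dimensions.
#' @return data.frame with one row per replicate: `p`, `meanMetric`,
#'   `meanBaseline`.
#' @export
calibratePipeline <- function(nReplicates = 200L, couplingGain = 0,
                              seed = 1L,
                              model = modelSpec("knn", "classification",
                                                list(k = 5L)),
                              nSubjects = 3L, nRegions = 8L,
                              nChannels = 2L, nScans = 120L,
                              blockLenScans = 20L) {
  rows <- lapply(seq_len(nReplicates), function(r) {
    cfg <- syntheticConfig(nSubjects = nSubjects, nRegions = nRegions,
                           nChannels = nChannels, nScans = nScans,
                           blockLenScans = blockLenScans,
                           couplingGain = couplingGain,
                           seed = substreamSeed(seed, "replicate", r,
                                                couplingGain))
    report <- runExperiment(generateStudy(cfg), list(model))
    s <- modelSummary(report)
    data.frame(replicate = r, p = s$p[1], meanMetric = s$meanMetric[1],
               meanBaseline = s$meanBaseline[1])
  })
  do.call(rbind, rows)
}
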