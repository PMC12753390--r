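NEURAL_FAMILIES <- c("mlp", "cnn1d", "gru", "transformer")
CLASSICAL_FAMILIES <- c("logistic", "linear", "knn", "dtree", "rforest",
                        "svm", "gboost")
DUMMY_FAMILIES <- c("constant_increase", "constant_mean")

#' Model specification
#'
#' A uniform description of one model family, task and hyperparameter set.
#' Families: `logistic` (classification only), `linear` (regression only),
#' `knn`, `dtree`, `rforest`, `svm`, `gboost`, the neural families `mlp`,
#' `cnn1d`, `gru`, `transformer`, and the constant baselines
#' `constant_increase` / `constant_mean`.
#'
#' @slot family character family name.
#' @slot task `"classification"` or `"regression"`.
#' @slot hyper named list of hyperparameters.
#' @slot seed integer seed used by every stochastic fit.
#' @export
setClass("ModelSpec",
  representation(family = "character", task = "character", hyper = "list",
                 seed = "integer"))

setValidity("ModelSpec", function(object) {
  fams <- c(CLASSICAL_FAMILIES, NEURAL_FAMILIES, DUMMY_FAMILIES)
  if (!(object@family %in% fams))
    return(paste("unknown family:", object@family))
  if (!(object@task %in% c("classification", "regression")))
    return("task must be classification or regression")
  if (object@family == "logistic" && object@task != "classification")
    return("logistic is classification-only")
  if (object@family == "linear" && object@task != "regression")
    return("linear is regression-only")
  if (object@family == "constant_increase" && object@task != "classification")
    return("constant_increase is classification-only")
  if (object@family == "constant_mean" && object@task != "regression")
    return("constant_mean is regression-only")
  TRUE
})

#' Construct a ModelSpec
#'
#' @param family model family (see [ModelSpec-class]).
#' @param task `"classification"` or `"regression"`.
#' @param hyper named list of hyperparameters (family-specific; e.g. `k`
#'   for knn, `maxdepth` for dtree, `hidden` for mlp).
#' @param seed integer seed.
#' @return A validated [ModelSpec-class].
#' @examples
#' modelSpec("svm", "classification")
#' @export
modelSpec <- function(family, task = "classification", hyper = list(),
                      seed = 1L) {
  new("ModelSpec", family = family, task = task, hyper = hyper,
      seed = as.integer(seed))
}

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec: %s (%s), seed %d\n", object@family, object@task,
              object@seed))
})

#' Fitted model container
#'
#' @slot spec the generating [ModelSpec-class].
#' @slot fit opaque fitted state.
#' @slot trainingSummary list; neural families record the per-epoch
#'   train/validation loss curve and the early-stopping epoch.
#' @export
setClass("FittedModel",
  representation(spec = "ModelSpec", fit = "ANY", trainingSummary = "list"))

setMethod("show", "FittedModel", function(object) {
  cat(sprintf("FittedModel: %s (%s)\n", object@spec@family, object@spec@task))
})

#' @describeIn FittedModel per-epoch loss curve for neural families
#' @param x a `FittedModel`
#' @export
lossCurve <- function(x) x@trainingSummary$curve

supervisedParts <- function(set, task) {
  out <- if (is(set, "SupervisedSet"))
    list(X = set@X,
         y = if (task == "classification") set@yClass else set@yReg)
  else
    list(X = set$X,
         y = if (task == "classification") set$yClass else set$yReg)
  if (is.matrix(out$X) && is.null(colnames(out$X)))
    colnames(out$X) <- paste0("f", seq_len(ncol(out$X)))
  out
}

#' Fit a model
#'
#' Classical families fit in one pass through their backing package;
#' neural families train with Adam (binary cross-entropy for
#' classification, mean squared error for regression, ReLU hidden
#' activations) and early stopping on the validation loss, so `val` is
#' required for them. All fits are deterministic given the spec seed.
#'
#' @param spec a [ModelSpec-class].
#' @param train training [SupervisedSet-class] (or a list with elements
#'   `X` and `yClass`/`yReg`; the `cnn1d` raw path accepts a 3-D
#'   samples x channels x timepoints array as `X`).
#' @param val validation set, required for neural families.
#' @return A [FittedModel-class].
#' @export
fitModel <- function(spec, train, val = NULL) {
  validObject(spec)
  family <- spec@family; task <- spec@task; hyper <- spec@hyper
  tr <- supervisedParts(train, task)
  if (length(tr$y) == 0L) stop("empty training set")
  if (task == "classification" && length(unique(tr$y)) < 2L &&
      !(family %in% DUMMY_FAMILIES))
    stop("degenerate training labels: only one class present")
  if (family %in% NEURAL_FAMILIES && is.null(val))
    stop("neural families require a validation set")

  fit <- NULL
  summary <- list()
  if (family %in% NEURAL_FAMILIES) {
    if (family == "cnn1d" && is.matrix(tr$X) && is.null(hyper$kernels)) {
      hyper$kernels <- c(3L, 3L, 2L)   # short time axis on the lagged path
      hyper$pool <- hyper$pool %||% 1L
    }
    va <- supervisedParts(val, task)
    yNum <- function(y) if (task == "classification")
      as.numeric(y == "increase") else y
    Xp <- netPrepareInput(family, tr$X, hyper)
    Xvp <- netPrepareInput(family, va$X, hyper)
    fit <- netTrain(family, task, Xp, yNum(tr$y), Xvp, yNum(va$y),
                    hyper, spec@seed)
    summary <- list(curve = fit$curve, bestEpoch = fit$bestEpoch)
    fit$hyper <- hyper
  } else {
    fit <- withSeed(spec@seed, switch(family,
      logistic = {
        df <- data.frame(.y = tr$y == "increase", tr$X)
        suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
      },
      linear = {
        df <- data.frame(.y = tr$y, tr$X)
        suppressWarnings(stats::lm(.y ~ ., data = df))
      },
      knn = list(X = tr$X, y = tr$y, k = hyper$k %||% 5L),
      dtree = {
        df <- data.frame(.y = tr$y, tr$X)
        rpart::rpart(.y ~ ., data = df,
                     method = if (task == "classification") "class" else "anova",
                     control = rpart::rpart.control(
                       maxdepth = hyper$maxdepth %||% 30L,
                       cp = hyper$cp %||% 0.01,
                       minsplit = hyper$minsplit %||% 20L, xval = 0L))
      },
      rforest = ranger::ranger(
        x = tr$X, y = if (task == "classification") factor(tr$y) else tr$y,
        num.trees = hyper$numTrees %||% 500L, seed = spec@seed,
        num.threads = 1L),
      svm = e1071::svm(
        x = tr$X, y = if (task == "classification") factor(tr$y) else tr$y,
        kernel = "radial", cost = hyper$cost %||% 1,
        scale = FALSE),
      gboost = {
        label <- if (task == "classification")
          as.numeric(tr$y == "increase") else tr$y
        xgboost::xgb.train(
          params = list(objective = if (task == "classification")
                          "binary:logistic" else "reg:squarederror",
                        max_depth = hyper$maxDepth %||% 6L,
                        eta = hyper$eta %||% 0.3, nthread = 1L,
                        seed = spec@seed),
          data = xgboost::xgb.DMatrix(tr$X, label = label),
          nrounds = hyper$nrounds %||% 100L, verbose = 0L)
      },
      constant_increase = list(),
      constant_mean = list()))
  }
  if (is.matrix(tr$X)) summary$featNames <- colnames(tr$X)
  new("FittedModel", spec = spec, fit = fit, trainingSummary = summary)
}

#' Predict from a FittedModel
#'
#' Classification returns a factor with levels `increase`, `decrease`;
#' regression returns numeric values. No missing outputs are produced.
#'
#' @param object a [FittedModel-class].
#' @param X samples x features matrix with the training feature dimension
#'   (or the matching 3-D array for the raw `cnn1d` path).
#' @param ... unused.
#' @return Factor or numeric vector of length `nrow(X)`.
#' @export
setMethod("predict", "FittedModel", function(object, X, ...) {
  spec <- object@spec
  family <- spec@family; task <- spec@task
  if (is(X, "SupervisedSet")) X <- X@X
  if (is.matrix(X) && is.null(colnames(X)) &&
      !is.null(object@trainingSummary$featNames))
    colnames(X) <- object@trainingSummary$featNames
  asLabel <- function(p) factor(ifelse(p, "increase", "decrease"),
                                levels = c("increase", "decrease"))
  if (family %in% NEURAL_FAMILIES) {
    Xp <- netPrepareInput(family, X, object@fit$hyper)
    return(netPredict(family, task, object@fit$params, Xp, object@fit$hyper))
  }
  switch(family,
    constant_increase = asLabel(rep(TRUE, nrow(X))),
    constant_mean = rep(0, nrow(X)),
    logistic = {
      p <- suppressWarnings(stats::predict(object@fit,
             newdata = data.frame(X), type = "response"))
      asLabel(p >= 0.5)
    },
    linear = unname(suppressWarnings(stats::predict(object@fit,
              newdata = data.frame(X)))),
    knn = {
      f <- object@fit
      if (task == "classification")
        withSeed(spec@seed,
          factor(as.character(class::knn(f$X, X, f$y, k = f$k)),
                 levels = c("increase", "decrease")))
      else {
        m <- caret::knnreg(f$X, f$y, k = f$k)
        unname(stats::predict(m, X))
      }
    },
    dtree = {
      if (task == "classification")
        factor(as.character(stats::predict(object@fit,
                 newdata = data.frame(X), type = "class")),
               levels = c("increase", "decrease"))
      else unname(stats::predict(object@fit, newdata = data.frame(X)))
    },
    rforest = {
      p <- stats::predict(object@fit, data = X, num.threads = 1L,
                          seed = spec@seed)$predictions
      if (task == "classification")
        factor(as.character(p), levels = c("increase", "decrease"))
      else unname(p)
    },
    svm = {
      p <- stats::predict(object@fit, newdata = X)
      if (task == "classification")
        factor(as.character(p), levels = c("increase", "decrease"))
      else unname(p)
    },
    gboost = {
      p <- stats::predict(object@fit, newdata = xgboost::xgb.DMatrix(X))
      if (task == "classification") asLabel(p >= 0.5) else unname(p)
    })
})

#' Metric of a prediction set
#'
#' Accuracy for classification, mean absolute error for regression.
#'
#' @param pred predictions from [predict()].
#' @param truth true labels / values.
#' @param task `"classification"` or `"regression"`.
#' @return Single numeric metric.
#' @export
predictionMetric <- function(pred, truth, task) {
  if (task == "classification") mean(as.character(pred) == as.character(truth))
  else mean(abs(pred - truth))
}

#' Grid-tune a hyperparameter
#'
#' Fits every grid point on the training set, scores it on the validation
#' set (accuracy, higher better, for classification; MAE, lower better,
#' for regression) and returns the spec of the best point. Exact ties are
#' broken toward the simplest model, i.e. the earliest point of the grid
#' sorted ascending (fewer neighbors, shallower tree).
#'
#' @param spec a [ModelSpec-class].
#' @param grid named list, one entry per hyperparameter, each a vector of
#'   candidate values.
#' @param train,val [SupervisedSet-class]s.
#' @return The winning [ModelSpec-class], with the score in
#'   `hyper$.valMetric`.
#' @export
tuneModel <- function(spec, grid, train, val) {
  if (length(grid) == 0L || any(lengths(grid) == 0L))
    stop("empty tuning grid")
  points <- expand.grid(lapply(grid, sort), KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  va <- supervisedParts(val, spec@task)
  best <- NULL
  for (i in seq_len(nrow(points))) {
    hyper <- utils::modifyList(spec@hyper, as.list(points[i, , drop = FALSE]))
    cand <- modelSpec(spec@family, spec@task, hyper, spec@seed)
    fitted <- fitModel(cand, train,
                       val = if (spec@family %in% NEURAL_FAMILIES) val else NULL)
    metric <- predictionMetric(predict(fitted, va$X), va$y, spec@task)
    better <- is.null(best) ||
      (spec@task == "classification" && metric > best$metric) ||
      (spec@task == "regression" && metric < best$metric)
    if (better) best <- list(spec = cand, metric = metric)
  }
  best$spec@hyper$.valMetric <- best$metric
  best$spec
}
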