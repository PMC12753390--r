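test_that("spec validation enforces family/task compatibility", {
  expect_s4_class(modelSpec("svm", "regression"), "ModelSpec")
  expect_error(modelSpec("logistic", "regression"), "classification-only")
  expect_error(modelSpec("linear", "classification"), "regression-only")
  expect_error(modelSpec("nonsense"), "unknown family")
})

test_that("every classification family separates a linearly separable 2-D set", {
  toy <- toy2D()
  tr <- list(X = toy$X, yClass = toy$yClass)
  for (fam in c("logistic", "knn", "dtree", "rforest", "svm", "gboost")) {
    fm <- fitModel(modelSpec(fam, "classification",
                             list(k = 3L, cp = 0.001, minsplit = 4L)), tr)
    acc <- mean(predict(fm, tr$X) == tr$yClass)
    expect_gte(acc, 0.95)
  }
  # memorizing 1-NN returns training labels exactly
  fm1 <- fitModel(modelSpec("knn", "classification", list(k = 1L)), tr)
  expect_equal(predict(fm1, tr$X), tr$yClass)
})

test_that("regression on exact linear data is recovered by the linear family", {
  set.seed(14)
  X <- matrix(rnorm(60 * 3), 60)
  y <- drop(X %*% c(1, -2, 0.5)) + 3
  tr <- list(X = X, yReg = y)
  fm <- fitModel(modelSpec("linear", "regression"), tr)
  expect_lte(mean(abs(predict(fm, X) - y)), 1e-6)
})

test_that("fits and predictions are deterministic given the seed", {
  toy <- toyClassSet()
  for (fam in c("rforest", "gboost", "mlp")) {
    spec <- modelSpec(fam, "classification", seed = 99L)
    p1 <- predict(fitModel(spec, toy$train, toy$val), toy$val$X)
    p2 <- predict(fitModel(spec, toy$train, toy$val), toy$val$X)
    expect_identical(p1, p2)
  }
})

test_that("constant baselines predict increase and zero", {
  X <- matrix(0, 7, 2)
  inc <- fitModel(constantBaselines("classification"), list(
    X = X, yClass = factor(rep(c("increase", "decrease"), c(4, 3)),
                           levels = c("increase", "decrease"))))
  expect_true(all(predict(inc, X) == "increase"))
  mean0 <- fitModel(constantBaselines("regression"),
                    list(X = X, yReg = rnorm(7)))
  expect_true(all(predict(mean0, X) == 0))
  # accuracy equals the increase proportion
  y <- factor(rep(c("increase", "decrease"), c(12, 8)),
              levels = c("increase", "decrease"))
  expect_equal(predictionMetric(predict(inc, matrix(0, 20, 2)), y,
                                "classification"), 0.6)
})

test_that("neural families require validation data and record loss curves", {
  toy <- toyClassSet()
  expect_error(fitModel(modelSpec("mlp", "classification"), toy$train),
               "validation")
  fm <- fitModel(modelSpec("mlp", "classification"), toy$train, toy$val)
  curve <- lossCurve(fm)
  expect_true(all(c("epoch", "train", "val") %in% names(curve)))
  expect_gte(nrow(curve), 5L)
  acc <- mean(predict(fm, toy$val$X) == toy$val$yClass)
  expect_gte(acc, 0.7)
})

test_that("the feature-sequence neural families learn a separable rule", {
  toy <- toyClassSet()
  hypers <- list(mlp = list(), gru = list(width = 16L),
                 transformer = list(dModel = 16L, dFF = 32L, nBlocks = 1L))
  for (fam in names(hypers)) {
    fm <- fitModel(modelSpec(fam, "classification", hypers[[fam]], seed = 5L),
                   toy$train, toy$val)
    acc <- mean(predict(fm, toy$val$X) == toy$val$yClass)
    expect_gte(acc, 0.7)
  }
})

test_that("the 1-D CNN learns a translation-invariant rule over its time axis", {
  # the label depends on channel 1's average across the 6 time steps, the
  # pattern the convolution + global-pooling bias is built for
  set.seed(27)
  n <- 220L
  X <- matrix(rnorm(n * 36), n)
  y <- factor(ifelse(rowMeans(X[, 1:6]) > 0, "increase", "decrease"),
              levels = c("increase", "decrease"))
  tr <- list(X = X[1:140, ], yClass = y[1:140])
  va <- list(X = X[141:n, ], yClass = y[141:n])
  fm <- fitModel(modelSpec("cnn1d", "classification", seed = 5L), tr, va)
  expect_gte(mean(predict(fm, va$X) == va$yClass), 0.7)
})

test_that("autodiff gradients match finite differences for every architecture", {
  for (fam in c("mlp", "gru", "transformer", "cnn1d")) {
    set.seed(3)
    n <- 7L; tLen <- 6L; nFeat <- 4L
    hyper <- switch(fam,
      mlp = list(hidden = c(5L, 3L)), gru = list(width = 4L, tLen = tLen),
      transformer = list(dModel = 8L, dFF = 10L, nBlocks = 2L, nHeads = 2L,
                         tLen = tLen),
      cnn1d = list(filters = c(3L, 3L), kernels = c(3L, 2L), pool = 2L,
                   tLen = tLen))
    X <- matrix(rnorm(n * nFeat * tLen), n)
    y <- rbinom(n, 1, 0.5)
    Xp <- eegbold:::netPrepareInput(fam, X, hyper)
    inputDim <- switch(fam, mlp = ncol(X), gru = list(nFeat = nFeat),
                       transformer = list(nFeat = nFeat),
                       cnn1d = list(nChan = nFeat))
    params <- eegbold:::netInitParams(fam, inputDim, hyper)
    tape <- eegbold:::agTape()
    P <- lapply(params, function(p) eegbold:::agParam(tape, p))
    z <- eegbold:::netForward(fam, tape, P, Xp, hyper)
    loss <- eegbold:::netLossNode("classification", tape, z, y)
    eegbold:::agBackward(tape, loss)
    worst <- 0
    for (nm in names(params)) {
      g <- if (is.null(P[[nm]]$grad)) as.numeric(params[[nm]] * 0)
           else as.numeric(P[[nm]]$grad)
      for (i in sample(length(params[[nm]]), min(3L, length(params[[nm]])))) {
        eps <- 1e-5
        up <- params; up[[nm]][i] <- up[[nm]][i] + eps
        dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
        num <- (eegbold:::netEvalLoss(fam, "classification", up, Xp, y, hyper) -
                  eegbold:::netEvalLoss(fam, "classification", dn, Xp, y, hyper)) /
               (2 * eps)
        worst <- max(worst, abs(num - g[i]) / max(1e-6, abs(num) + abs(g[i])))
      }
    }
    expect_lt(worst, 1e-5)
  }
})

test_that("grid tuning returns the validation optimum with simplest-tie rule", {
  # k = 5 constructed optimal: noisy labels around a smooth boundary
  set.seed(15)
  n <- 200L
  X <- matrix(runif(n * 2, -1, 1), n)
  yProb <- 1 / (1 + exp(-4 * X[, 1]))
  y <- factor(ifelse(runif(n) < yProb, "increase", "decrease"),
              levels = c("increase", "decrease"))
  tr <- list(X = X[1:120, ], yClass = y[1:120])
  va <- list(X = X[121:200, ], yClass = y[121:200])
  grids <- lapply(c(1L, 5L, 25L), function(k)
    predictionMetric(predict(fitModel(modelSpec("knn", "classification",
                                                list(k = k)), tr), va$X),
                     va$yClass, "classification"))
  bestK <- c(1L, 5L, 25L)[which.max(unlist(grids))]   # exhaustive oracle
  tuned <- tuneModel(modelSpec("knn", "classification"),
                     list(k = c(1L, 5L, 25L)), tr, va)
  expect_equal(tuned@hyper$k, bestK)

  # single-point grid returns that point
  one <- tuneModel(modelSpec("dtree", "classification"),
                   list(maxdepth = 4L), tr, va)
  expect_equal(one@hyper$maxdepth, 4L)

  # exact ties break toward the smallest complexity
  trSep <- toyClassSet()$train
  tie <- tuneModel(modelSpec("knn", "classification"),
                   list(k = c(7L, 3L, 5L)), trSep,
                   list(X = trSep$X[1:4, ], yClass = trSep$yClass[1:4]))
  expect_equal(tie@hyper$k, 3L)
  expect_error(tuneModel(modelSpec("knn", "classification"), list(),
                         trSep, trSep), "empty")
})

test_that("label shuffling drives test accuracy to chance", {
  set.seed(16)
  accs <- replicate(20, {
    n <- 160L
    X <- matrix(rnorm(n * 10), n)
    y <- factor(sample(c("increase", "decrease"), n, TRUE),
                levels = c("increase", "decrease"))
    tr <- list(X = X[1:80, ], yClass = sample(y[1:80]))
    fm <- fitModel(modelSpec("svm", "classification"), tr)
    mean(predict(fm, X[81:160, ]) == y[81:160])
  })
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})

test_that("degenerate single-class training labels raise an error", {
  X <- matrix(rnorm(20), 10)
  y <- factor(rep("increase", 10), levels = c("increase", "decrease"))
  expect_error(fitModel(modelSpec("svm", "classification"),
                        list(X = X, yClass = y)), "single|degenerate")
})
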