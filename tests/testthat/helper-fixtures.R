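# Small study configurations and shared helpers for the suite.

tinyConfig <- function(seed = 11L, couplingGain = 3, ...) {
  syntheticConfig(nSubjects = 2L, nRegions = 4L, nChannels = 2L,
                  nScans = 60L, blockLenScans = 10L,
                  couplingGain = couplingGain, noiseSd = 0.5,
                  seed = seed, ...)
}

scaledConfig <- function(seed, couplingGain = 0) {
  syntheticConfig(nSubjects = 3L, nRegions = 8L, nChannels = 2L,
                  nScans = 120L, blockLenScans = 20L,
                  couplingGain = couplingGain, seed = seed)
}

# exhaustive signed-rank oracle: one-sided P(W+ >= observed) over all 2^n
# equally likely sign assignments
bruteForceSignedRankP <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  wObs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
  mean(signs %*% r >= wObs)
}

# separable toy classification set (36 features so the lag-reshaping
# families see a 6-step x 6-unit grid)
toyClassSet <- function(n = 220L, p = 36L, nTrain = 140L, seed = 4L) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n)
  y <- factor(ifelse(X[, 1] + X[, 7] > 0, "increase", "decrease"),
              levels = c("increase", "decrease"))
  tr <- seq_len(nTrain); va <- (nTrain + 1L):n
  list(train = list(X = X[tr, ], yClass = y[tr], yReg = X[tr, 1]),
       val = list(X = X[va, ], yClass = y[va], yReg = X[va, 1]))
}

# 2-D linearly separable set with a margin
toy2D <- function(n = 80L, seed = 26L) {
  set.seed(seed)
  X <- matrix(runif(n * 2, -1, 1), n)
  keep <- abs(rowSums(X)) > 0.2
  X <- X[keep, ]
  list(X = X, yClass = factor(ifelse(rowSums(X) > 0, "increase", "decrease"),
                              levels = c("increase", "decrease")))
}
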