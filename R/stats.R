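#' One-sided Wilcoxon signed-rank test with matched-pairs effect sizes
#'
#' Tests whether the paired metric improves on the paired baseline in the
#' favorable direction (`"greater"`: higher is better, e.g. accuracy;
#' `"less"`: lower is better, e.g. MAE). Zero differences are discarded
#' (classic signed-rank convention). For up to 25 informative pairs the
#' exact null distribution of the signed-rank sum is used (computed by
#' dynamic programming over sign assignments, valid with midranks);
#' beyond that a normal approximation with continuity correction and tie
#' correction. Also returns the matched-pairs rank-biserial correlation
#' `RBC = (W+ - W-) / (W+ + W-)` and the common-language effect size
#' (proportion of pairs with a favorable difference, ties counting 1/2,
#' over all pairs).
#'
#' @param metric numeric vector of per-pair model metrics.
#' @param baseline numeric vector of per-pair baseline metrics.
#' @param direction `"greater"` or `"less"`.
#' @param exactMax use the exact null up to this many informative pairs.
#' @return List with `p`, `rbc`, `cles`, `statistic` (W+), `nInformative`.
#' @export
wilcoxonOneSided <- function(metric, baseline, direction = c("greater", "less"),
                             exactMax = 25L) {
  direction <- match.arg(direction)
  if (length(metric) != length(baseline)) stop("length mismatch")
  d <- metric - baseline
  if (direction == "less") d <- -d
  cles <- mean(ifelse(d > 0, 1, ifelse(d == 0, 0.5, 0)))
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero: test undefined")
  if (n < 5L) stop("fewer than 5 informative pairs")
  r <- rank(abs(d))
  wPlus <- sum(r[d > 0])
  wMinus <- sum(r[d < 0])
  if (n <= exactMax) {
    p <- signedRankTailGE(r, wPlus)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (wPlus - mu - 0.5) / sqrt(sigma2)
    p <- stats::pnorm(z, lower.tail = FALSE)
  }
  list(p = p, rbc = (wPlus - wMinus) / (wPlus + wMinus), cles = cles,
       statistic = wPlus, nInformative = n)
}

# P(W+ >= w) under the signed-rank null for rank vector r (midranks
# allowed); exact convolution over the 2^n equally likely sign assignments
signedRankTailGE <- function(r, w) {
  r2 <- round(2 * r)
  total <- sum(r2)
  f <- numeric(total + 1L)   # index i -> probability of doubled sum i-1
  f[1L] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), f[seq_len(length(f) - ri)])
    f <- (f + shifted) / 2
  }
  w2 <- round(2 * w)
  sum(f[(w2 + 1L):(total + 1L)])
}

#' McNemar p-value for a discordant pair count
#'
#' Exact doubled binomial tail when the discordant total `b + c` is at
#' most `exactMax` (default 25), capped at 1; otherwise the
#' continuity-corrected chi-square approximation.
#'
#' @param b,c discordant counts (model-only-correct, baseline-only-correct).
#' @param exactMax threshold for the exact branch.
#' @return Two-sided p-value.
#' @examples
#' mcnemarP(8, 2)   # 0.109375
#' @export
mcnemarP <- function(b, c, exactMax = 25L) {
  n <- b + c
  if (n == 0) return(1)
  if (n <= exactMax)
    return(min(1, 2 * stats::pbinom(min(b, c), n, 0.5)))
  stat <- (abs(b - c) - 1)^2 / n
  stats::pchisq(stat, df = 1L, lower.tail = FALSE)
}

#' Resampled-baseline configuration
#'
#' @param nIterationsWilcoxon resampling iterations for the Wilcoxon path
#'   (default 1000).
#' @param nIterationsMcnemar resampling iterations for the McNemar path
#'   (default 10000).
#' @param seed integer seed.
#' @return A list of class `ResampledBaselineConfig`.
#' @export
resampledBaselineConfig <- function(nIterationsWilcoxon = 1000L,
                                    nIterationsMcnemar = 10000L,
                                    seed = 1L) {
  if (nIterationsWilcoxon < 1L || nIterationsMcnemar < 1L)
    stop("iteration counts must be >= 1")
  structure(list(nIterationsWilcoxon = as.integer(nIterationsWilcoxon),
                 nIterationsMcnemar = as.integer(nIterationsMcnemar),
                 seed = as.integer(seed)),
            class = "ResampledBaselineConfig")
}

#' Iterated McNemar test against a resampled baseline
#'
#' Per iteration, a baseline prediction is drawn per scan from the
#' empirical distribution of the true labels (invalid predictions must be
#' excluded beforehand), the model-vs-baseline 2x2 correctness table is
#' pooled over all items, and the McNemar p-value is computed
#' ([mcnemarP()]). Returns every iteration's p-value plus a summary:
#' median p, proportion of iterations with p < 0.05, and a 20-bin
#' histogram of p on `[0, 1]`.
#'
#' @param predictions factor/character vector of model predictions.
#' @param truths aligned true labels.
#' @param cfg a [resampledBaselineConfig()].
#' @return List with `p` (vector), `medianP`, `propSignificant`,
#'   `histogram` (data.frame of bin mid and count).
#' @export
mcnemarVsResampledBaseline <- function(predictions, truths,
                                       cfg = resampledBaselineConfig()) {
  predictions <- as.character(predictions)
  truths <- as.character(truths)
  if (length(predictions) == 0L)
    stop("empty prediction set after exclusions")
  if (length(predictions) != length(truths)) stop("length mismatch")
  n <- length(truths)
  labs <- sort(unique(truths))
  probs <- as.numeric(table(factor(truths, levels = labs))) / n
  modelCorrect <- predictions == truths
  p <- withSeed(cfg$seed, {
    vapply(seq_len(cfg$nIterationsMcnemar), function(i) {
      base <- sample(labs, n, replace = TRUE, prob = probs)
      baseCorrect <- base == truths
      mcnemarP(sum(modelCorrect & !baseCorrect),
               sum(!modelCorrect & baseCorrect))
    }, numeric(1))
  })
  list(p = p, medianP = stats::median(p), propSignificant = mean(p < 0.05),
       histogram = pvalueHistogram(p))
}

#' Iterated one-sided Wilcoxon test against a resampled baseline
#'
#' Per iteration, baseline labels are drawn from the empirical truth
#' distribution, per-pair accuracies are computed for model and baseline,
#' and a one-sided Wilcoxon signed-rank test (model accuracy greater) is
#' run across pairs.
#'
#' @param predictions,truths aligned label vectors (invalids excluded).
#' @param pairIds grouping vector (e.g. subject.region) defining the pairs.
#' @param cfg a [resampledBaselineConfig()].
#' @return List with `p` (vector), `medianP`, `propSignificant`.
#' @export
wilcoxonVsResampledBaseline <- function(predictions, truths, pairIds,
                                        cfg = resampledBaselineConfig()) {
  predictions <- as.character(predictions)
  truths <- as.character(truths)
  n <- length(truths)
  labs <- sort(unique(truths))
  probs <- as.numeric(table(factor(truths, levels = labs))) / n
  grp <- factor(pairIds)
  modelAcc <- tapply(predictions == truths, grp, mean)
  p <- withSeed(cfg$seed, {
    vapply(seq_len(cfg$nIterationsWilcoxon), function(i) {
      base <- sample(labs, n, replace = TRUE, prob = probs)
      baseAcc <- tapply(base == truths, grp, mean)
      out <- tryCatch(
        wilcoxonOneSided(as.numeric(modelAcc), as.numeric(baseAcc),
                         "greater")$p,
        error = function(e) NA_real_)
      out
    }, numeric(1))
  })
  p <- p[!is.na(p)]
  list(p = p, medianP = stats::median(p), propSignificant = mean(p < 0.05))
}

#' 20-bin p-value histogram
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param bins number of equal bins (default 20).
#' @return data.frame with `binMid` and `count`.
#' @export
pvalueHistogram <- function(p, bins = 20L) {
  breaks <- seq(0, 1, length.out = bins + 1L)
  counts <- tabulate(pmin(findInterval(p, breaks, rightmost.closed = TRUE),
                          bins), nbins = bins)
  data.frame(binMid = (breaks[-1] + breaks[-(bins + 1L)]) / 2, count = counts)
}
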