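#' Z-normalize every unit of a series
#'
#' Subtracts the per-column mean and divides by the per-column standard
#' deviation. The population SD (denominator n, `ddof = 0`) is used by
#' default so that short series are scaled exactly; set `ddof = 1` for the
#' sample SD. Constant columns cannot be scaled: they are set to all zeros
#' and flagged degenerate.
#'
#' @param x a [SeriesMatrix-class].
#' @param ddof delta degrees of freedom for the SD denominator (n - ddof).
#' @return A [SeriesMatrix-class] with columns of mean 0 and SD 1
#'   (non-degenerate columns).
#' @examples
#' sm <- SeriesMatrix(c(1, 3), timeStep = 2)
#' seriesValues(zscoreNormalize(sm))   # -1, 1
#' @export
zscoreNormalize <- function(x, ddof = 0) {
  stopifnot(is(x, "SeriesMatrix"))
  v <- x@values
  if (nrow(v) < 2L)
    stop("zscoreNormalize() needs at least 2 time points per unit")
  mu <- colMeans(v)
  centered <- sweep(v, 2L, mu)
  sd <- sqrt(colSums(centered^2) / (nrow(v) - ddof))
  degenerate <- sd == 0
  sd[degenerate] <- 1
  out <- sweep(centered, 2L, sd, "/")
  out[, degenerate] <- 0
  res <- x
  res@values <- out
  res@degenerate <- x@degenerate | degenerate
  validObject(res)
  res
}

#' Replace outlying time points with the previous value
#'
#' Entries whose absolute value exceeds `thresholdStd` are flagged in a
#' single pass over the input, then replaced left-to-right by the value at
#' the previous time point. Replacement cascades: if the previous point was
#' itself replaced, its replacement value is carried forward. A flagged
#' first time point has no predecessor and is left unchanged (but still
#' flagged and counted). The input is expected to be z-normalized already,
#' so the threshold is in SD units.
#'
#' @param x a [SeriesMatrix-class], typically the output of
#'   [zscoreNormalize()].
#' @param thresholdStd positive absolute z threshold (3 for BOLD series,
#'   4 for EEG band powers).
#' @return A list with elements `series` (the corrected
#'   [SeriesMatrix-class]) and `report` (an [OutlierReport-class]).
#' @examples
#' sm <- zscoreNormalize(SeriesMatrix(rnorm(50), timeStep = 2))
#' res <- replaceOutliersWithPrevious(sm, thresholdStd = 3)
#' outlierProportions(res$report)
#' @export
replaceOutliersWithPrevious <- function(x, thresholdStd) {
  stopifnot(is(x, "SeriesMatrix"))
  if (length(thresholdStd) != 1L || !is.finite(thresholdStd) || thresholdStd <= 0)
    stop("thresholdStd must be a single positive number")
  v <- x@values
  flags <- abs(v) > thresholdStd
  out <- v
  if (nrow(v) >= 2L) {
    for (t in 2:nrow(v)) {
      hit <- flags[t, ]
      if (any(hit)) out[t, hit] <- out[t - 1L, hit]
    }
  }
  res <- x
  res@values <- out
  report <- new("OutlierReport", flags = flags,
                proportionPerUnit = colMeans(flags),
                thresholdStd = as.numeric(thresholdStd))
  list(series = res, report = report)
}

#' Remove a linear drift from every unit
#'
#' Subtracts the per-column least-squares straight line over time, leaving
#' each column orthogonal to the constant and linear-time regressors.
#'
#' @param x a [SeriesMatrix-class] with at least 3 time points.
#' @return The detrended [SeriesMatrix-class].
#' @examples
#' sm <- SeriesMatrix(2 * seq_len(10) + 1, timeStep = 2)
#' max(abs(seriesValues(removeDrift(sm))))   # ~0
#' @export
removeDrift <- function(x) {
  stopifnot(is(x, "SeriesMatrix"))
  v <- x@values
  if (nrow(v) < 3L)
    stop("removeDrift() needs at least 3 time points")
  t <- seq_len(nrow(v))
  res <- x
  resid <- matrix(stats::lm.fit(cbind(1, t), v)$residuals,
                  nrow(v), ncol(v), dimnames = dimnames(v))
  # a numerically exact linear fit leaves only rounding noise: snap to zero
  # so downstream normalization sees a genuinely degenerate column
  exact <- apply(resid, 2L, stats::sd) < 1e-10 * (apply(v, 2L, stats::sd) + 1e-300)
  resid[, exact] <- 0
  res@values <- resid
  res
}

#' Write / read a SeriesMatrix as TSV
#'
#' Tab-separated table with a header row of unit labels and a leading
#' `scan` index column.
#'
#' @param x a [SeriesMatrix-class].
#' @param path output file.
#' @return `writeSeriesMatrix` returns `path` invisibly; `readSeriesMatrix`
#'   returns a [SeriesMatrix-class].
#' @export
writeSeriesMatrix <- function(x, path) {
  df <- data.frame(scan = seq_len(nrow(x@values)) - 1L, x@values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSeriesMatrix
#' @param timeStep seconds per row for the reconstructed object.
#' @export
readSeriesMatrix <- function(path, timeStep) {
  df <- utils::read.delim(path, check.names = FALSE)
  SeriesMatrix(as.matrix(df[, -1, drop = FALSE]), timeStep = timeStep)
}

#' Write an OutlierReport (JSON summary + TSV flag matrix)
#'
#' @param report an [OutlierReport-class].
#' @param jsonPath path for the JSON summary (threshold, per-unit
#'   proportions).
#' @param flagsPath optional path for the TSV flag matrix.
#' @return `jsonPath`, invisibly.
#' @export
writeOutlierReport <- function(report, jsonPath, flagsPath = NULL) {
  summary <- list(thresholdStd = report@thresholdStd,
                  proportionPerUnit = as.list(stats::setNames(
                    report@proportionPerUnit,
                    colnames(report@flags) %||% paste0("unit", seq_along(report@proportionPerUnit)))))
  jsonlite::write_json(summary, jsonPath, auto_unbox = TRUE, digits = NA)
  if (!is.null(flagsPath))
    utils::write.table(report@flags * 1L, flagsPath, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(jsonPath)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
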