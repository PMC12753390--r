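#' Lagged band-power feature matrix
#'
#' The sample for scan t (t from `nLags` to T-1, 0-based) concatenates the
#' band powers at scans `t - nLags ... t` in fixed (time step, channel,
#' band) order: the lag index varies fastest, then channel, then band. The
#' first `nLags` scans are dropped entirely (no zero padding), giving
#' `T - nLags` samples of dimension `channels * bands * (nLags + 1)`.
#'
#' @param bp a [BandPowerTensor-class] or a scans x channels x bands array.
#' @param nLags number of preceding scans to include (default 5, i.e. a
#'   10 s window at TR 2 s, spanning the hemodynamic response peak).
#' @return List with `X` (samples x features, with descriptive column
#'   names) and `scans` (0-based scan index of each sample).
#' @export
buildFeatures <- function(bp, nLags = 5L) {
  v <- if (is(bp, "BandPowerTensor")) bp@values else bp
  d <- dim(v)
  if (length(d) != 3L) stop("band powers must be scans x channels x bands")
  if (d[1] <= nLags)
    stop(sprintf("need more than nLags = %d scans, got %d", nLags, d[1]))
  scans <- seq(nLags + 1L, d[1])               # 1-based rows; 0-based t >= nLags
  steps <- 0:nLags
  X <- matrix(0, length(scans), d[2] * d[3] * (nLags + 1L))
  col <- 0L
  nm <- character(ncol(X))
  chn <- dimnames(v)[[2]] %||% paste0("ch", seq_len(d[2]))
  bnd <- dimnames(v)[[3]] %||% paste0("band", seq_len(d[3]))
  for (b in seq_len(d[3])) for (ch in seq_len(d[2])) for (k in steps) {
    col <- col + 1L
    X[, col] <- v[scans - nLags + k, ch, b]
    nm[col] <- sprintf("%s.%s.lag%d", chn[ch], bnd[b], nLags - k)
  }
  colnames(X) <- nm
  list(X = X, scans = scans - 1L)
}

#' Span of the lagged feature window
#'
#' The `nLags` preceding scans reach back `nLags * trS` seconds before the
#' current scan (10 s for the default 5 lags at TR 2 s).
#'
#' @param nLags number of preceding scans.
#' @param trS repetition time, seconds.
#' @return Window span in seconds.
#' @export
featureWindowSpan <- function(nLags = 5L, trS = 2) nLags * trS

#' Direction labels and value targets for one region
#'
#' The class label at scan t is `increase` when
#' `value(t) - value(t-1) >= 0` and `decrease` otherwise (ties labeled
#' increase; defined for t >= 1). The regression target at scan t is the
#' normalized BOLD value itself.
#'
#' @param bold a [RegionTimeSeries-class] or a scans x regions matrix.
#' @param region region label (or column index).
#' @return List with `yClass` (factor, aligned to scans `1..T-1`,
#'   0-based), `yReg` (full series) and `scans` (0-based scan index of
#'   each class label).
#' @export
buildTargets <- function(bold, region) {
  v <- if (is(bold, "RegionTimeSeries")) bold@values else bold
  if (is.vector(v)) v <- matrix(v, ncol = 1L, dimnames = list(NULL, region))
  if (is.character(region) && !(region %in% colnames(v)))
    stop("unknown region label: ", region)
  series <- v[, region]
  if (length(series) < 2L) stop("need at least 2 scans")
  delta <- diff(series)
  yClass <- factor(ifelse(delta >= 0, "increase", "decrease"),
                   levels = c("increase", "decrease"))
  list(yClass = yClass, yReg = series, scans = seq_along(delta))
}

#' Assemble a SupervisedSet for one (subject, condition, region)
#'
#' Aligns [buildFeatures()] with [buildTargets()]: only scans
#' `t >= nLags` are kept, the class label is the change from t-1 into t,
#' and the regression target is the value at t.
#'
#' @param bp a [BandPowerTensor-class] or array (see [buildFeatures()]).
#' @param bold a [RegionTimeSeries-class] or matrix.
#' @param region region label.
#' @param subject,condition index metadata recorded per sample.
#' @param nLags lag depth (default 5).
#' @return A [SupervisedSet-class].
#' @export
buildSupervisedSet <- function(bp, bold, region, subject = "sub-01",
                               condition = "cond", nLags = 5L) {
  feat <- buildFeatures(bp, nLags)
  tgt <- buildTargets(bold, region)
  keep <- feat$scans           # 0-based, all >= nLags >= 1
  new("SupervisedSet", X = feat$X,
      yClass = tgt$yClass[match(keep, tgt$scans)],
      yReg = unname(tgt$yReg[keep + 1L]),
      index = data.frame(subject = subject, condition = condition,
                         region = region, scan = keep))
}

#' Stack raw EEG segments into lagged samples
#'
#' For the raw-signal convolutional path: the sample for scan t stacks the
#' raw segments for scans `t - nLags ... t`, keeping channels as the
#' leading axis so the network can treat EEG channels as input channels.
#'
#' @param signal channels x samples matrix.
#' @param sfreqHz sampling rate, Hz.
#' @param trS repetition time, seconds.
#' @param nScans number of scans covered by the recording.
#' @param nLags lag depth (default 5).
#' @return Array samples x channels x timepoints, where timepoints =
#'   `(nLags + 1) * trS * sfreqHz`, plus a `scans` attribute (0-based).
#' @export
buildRawSegments <- function(signal, sfreqHz, trS, nScans, nLags = 5L) {
  segs <- segmentToScans(signal, sfreqHz, trS, nScans)
  if (nScans <= nLags) stop("need more than nLags scans")
  sps <- ncol(segs[[1]])
  nCh <- nrow(segs[[1]])
  scans <- seq(nLags + 1L, nScans)
  out <- array(0, dim = c(length(scans), nCh, (nLags + 1L) * sps))
  for (i in seq_along(scans)) {
    t <- scans[i]
    out[i, , ] <- do.call(cbind, segs[(t - nLags):t])
  }
  attr(out, "scans") <- scans - 1L
  out
}
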