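#' Hemodynamic response function parameters
#'
#' Double-gamma parameterization of the canonical HRF: a gamma-shaped
#' response peaking around `peakDelayS` minus one dispersion, minus a
#' scaled gamma undershoot. The kernel is normalized to unit peak.
#'
#' @param peakDelayS delay of the positive response, seconds (default 6).
#' @param undershootDelayS delay of the undershoot, seconds (default 16).
#' @param peakDispS dispersion of the positive response (default 1).
#' @param undershootDispS dispersion of the undershoot (default 1).
#' @param undershootRatio relative undershoot amplitude (default 1/6).
#' @param durationS kernel support, seconds (default 32).
#' @return A named list of class `HRFParams`.
#' @examples
#' h <- makeHRF(hrfParams(), trS = 2)
#' @export
hrfParams <- function(peakDelayS = 6, undershootDelayS = 16,
                      peakDispS = 1, undershootDispS = 1,
                      undershootRatio = 1 / 6, durationS = 32) {
  p <- list(peakDelayS = peakDelayS, undershootDelayS = undershootDelayS,
            peakDispS = peakDispS, undershootDispS = undershootDispS,
            undershootRatio = undershootRatio, durationS = durationS)
  if (any(unlist(p) <= 0)) stop("all HRF parameters must be positive")
  class(p) <- "HRFParams"
  p
}

hrfDense <- function(params, t) {
  g1 <- stats::dgamma(t, shape = params$peakDelayS / params$peakDispS,
                      scale = params$peakDispS)
  g2 <- stats::dgamma(t, shape = params$undershootDelayS / params$undershootDispS,
                      scale = params$undershootDispS)
  g1 - params$undershootRatio * g2
}

#' Sample a double-gamma HRF kernel
#'
#' Evaluates the double-gamma kernel on the scan grid
#' `0, trS, 2 trS, ..., durationS` and rescales it to unit peak
#' (`max(kernel) == 1`). The value at t = 0 is exactly 0 (gamma density
#' with shape > 1).
#'
#' @param params an `HRFParams` list from [hrfParams()].
#' @param trS sampling step in seconds (the fMRI repetition time).
#' @return Numeric kernel vector with unit peak.
#' @examples
#' h <- makeHRF(hrfParams(), trS = 2)
#' which.max(h)   # peak near 6 s
#' @export
makeHRF <- function(params, trS) {
  if (!inherits(params, "HRFParams")) params <- do.call(hrfParams, params)
  if (trS <= 0) stop("trS must be positive")
  tGrid <- seq(0, params$durationS, by = trS)
  v <- hrfDense(params, tGrid)
  if (!all(is.finite(v))) stop("HRF kernel is not finite; check parameters")
  v / max(v)
}
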