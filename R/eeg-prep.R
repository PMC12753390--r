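#' Default EEG frequency bands
#'
#' delta 1-4, theta 4-8, alpha 8-12, sigma 12-16, beta 16-30 and gamma
#' 30-40 Hz.
#'
#' @return data.frame with columns `name`, `lowHz`, `highHz`.
#' @export
defaultBands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "sigma", "beta", "gamma"),
             lowHz = c(1, 4, 8, 12, 16, 30),
             highHz = c(4, 8, 12, 16, 30, 40))
}

#' Cut a recording into scan-aligned segments
#'
#' Segment t covers the half-open interval `[t * trS, (t+1) * trS)` of the
#' recording; every segment holds exactly `trS * sfreqHz` samples and
#' trailing excess samples are dropped.
#'
#' @param signal channels x samples numeric matrix (uV).
#' @param sfreqHz sampling rate, Hz.
#' @param trS fMRI repetition time, seconds.
#' @param nScans number of segments to produce.
#' @return List of `nScans` channels x samples matrices.
#' @export
segmentToScans <- function(signal, sfreqHz, trS, nScans) {
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1L)
  sps <- round(trS * sfreqHz)
  needed <- nScans * sps
  if (ncol(signal) < needed)
    stop(sprintf("recording too short: %d samples needed for %d scans, %d available (shortfall %d)",
                 needed, nScans, ncol(signal), needed - ncol(signal)))
  lapply(seq_len(nScans) - 1L, function(t)
    signal[, t * sps + seq_len(sps), drop = FALSE])
}

# one-sided Welch PSD of a single-channel vector
welchPSD <- function(x, sfreqHz, windowSec, overlap) {
  win <- round(windowSec * sfreqHz)
  if (win > length(x))
    stop("analysis window longer than the segment")
  step <- max(1L, round(win * (1 - overlap)))
  starts <- seq(1L, length(x) - win + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(win) - 1) / (win - 1))   # Hamming
  scale <- 1 / (sfreqHz * sum(w^2))
  nF <- win %/% 2L + 1L
  segs <- vapply(starts, function(s) x[s + seq_len(win) - 1L] * w,
                 numeric(win))
  spec <- Mod(stats::mvfft(segs))^2 * scale
  psd <- rowMeans(spec[seq_len(nF), , drop = FALSE])
  onesided <- c(1, rep(2, nF - 2L), if (win %% 2L == 0L) 1 else 2)
  list(freq = (seq_len(nF) - 1L) * sfreqHz / win, psd = psd * onesided)
}

#' Band powers of scan-aligned EEG segments
#'
#' Per segment and channel, a Welch power spectral density (Hamming
#' windows of `windowSec` seconds at `overlap` fractional overlap, mean
#' across windows), integrated over each band with the trapezoid rule on
#' the closed `[lowHz, highHz]` frequency grid. A band edge shared by two
#' bands receives half weight in each, so total power is conserved and no
#' energy is double-counted. Powers are absolute, in uV^2.
#'
#' @param segments list of channels x samples matrices
#'   (see [segmentToScans()]).
#' @param bands data.frame as [defaultBands()].
#' @param sfreqHz sampling rate, Hz.
#' @param windowSec Welch window length, seconds (default 1).
#' @param overlap fractional window overlap (default 0.5).
#' @return Array scans x channels x bands.
#' @examples
#' seg <- matrix(2 * sin(2 * pi * 10 * (0:399) / 200), nrow = 1)
#' bp <- computeBandPowers(list(seg), sfreqHz = 200)
#' bp[1, 1, "alpha"]   # ~ amplitude^2 / 2 = 2
#' @export
computeBandPowers <- function(segments, bands = defaultBands(), sfreqHz,
                              windowSec = 1, overlap = 0.5) {
  if (max(bands$highHz) > sfreqHz / 2)
    stop("band edge above the Nyquist frequency")
  if (any(bands$lowHz <= 0) || any(bands$lowHz >= bands$highHz))
    stop("bands must satisfy 0 < lowHz < highHz")
  nCh <- nrow(segments[[1]])
  out <- array(0, dim = c(length(segments), nCh, nrow(bands)),
               dimnames = list(NULL,
                               rownames(segments[[1]]) %||% paste0("ch", seq_len(nCh)),
                               bands$name))
  for (t in seq_along(segments)) {
    seg <- segments[[t]]
    for (ch in seq_len(nCh)) {
      sp <- welchPSD(as.numeric(seg[ch, ]), sfreqHz, windowSec, overlap)
      for (b in seq_len(nrow(bands))) {
        sel <- sp$freq >= bands$lowHz[b] & sp$freq <= bands$highHz[b]
        out[t, ch, b] <- pracma::trapz(sp$freq[sel], sp$psd[sel])
      }
    }
  }
  out
}

#' Normalize a band-power tensor
#'
#' Z-normalizes each channel-band pair across scans
#' (see [zscoreNormalize()]), then replaces outliers beyond |z| > 4 with
#' the previous segment's value ([replaceOutliersWithPrevious()]).
#'
#' @param tensor scans x channels x bands array (raw band powers or
#'   generator latents).
#' @param thresholdStd outlier threshold in SD units (default 4).
#' @param ddof SD denominator convention (see [zscoreNormalize()]).
#' @return A [BandPowerTensor-class] with the outlier report attached.
#' @export
normalizeBandPowers <- function(tensor, thresholdStd = 4, ddof = 0) {
  d <- dim(tensor)
  if (length(d) != 3L) stop("tensor must be scans x channels x bands")
  chn <- dimnames(tensor)[[2]] %||% paste0("ch", seq_len(d[2]))
  bnd <- dimnames(tensor)[[3]] %||% paste0("band", seq_len(d[3]))
  labels <- as.vector(outer(chn, bnd, paste, sep = "."))
  sm <- SeriesMatrix(matrix(tensor, d[1], d[2] * d[3]), timeStep = 1,
                     unitLabels = labels)
  res <- replaceOutliersWithPrevious(zscoreNormalize(sm, ddof = ddof),
                                     thresholdStd = thresholdStd)
  new("BandPowerTensor",
      values = array(res$series@values, dim = d,
                     dimnames = list(NULL, chn, bnd)),
      normalized = TRUE, outliers = res$report)
}

#' Write a band-power tensor as long-format TSV plus JSON sidecar
#'
#' @param bpt a [BandPowerTensor-class].
#' @param tsvPath output TSV (columns scan, channel, band, value).
#' @param jsonPath optional JSON sidecar (bands, normalization, threshold).
#' @return `tsvPath`, invisibly.
#' @export
writeBandPowerTensor <- function(bpt, tsvPath, jsonPath = NULL) {
  v <- bpt@values
  d <- dim(v)
  long <- data.frame(scan = rep(seq_len(d[1]), times = d[2] * d[3]),
                     channel = rep(rep(dimnames(v)[[2]], each = d[1]), times = d[3]),
                     band = rep(dimnames(v)[[3]], each = d[1] * d[2]),
                     value = as.vector(v))
  utils::write.table(long, tsvPath, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(list(bands = dimnames(v)[[3]],
                              normalized = bpt@normalized,
                              thresholdStd = bpt@outliers@thresholdStd),
                         jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(tsvPath)
}
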