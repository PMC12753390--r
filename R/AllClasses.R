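#' @import methods
NULL

#' Time-by-unit series container
#'
#' A plain numeric matrix of time points (rows) by measurement units
#' (columns: EEG channel-band pairs or fMRI regions), together with the
#' sampling step and unit labels. All preprocessing primitives
#' ([zscoreNormalize()], [removeDrift()], [replaceOutliersWithPrevious()])
#' operate on this container so EEG and BOLD series are treated identically.
#'
#' @slot values numeric matrix, time x unit; no missing entries.
#' @slot timeStep seconds per row (> 0).
#' @slot unitLabels character, one unique label per column.
#' @slot degenerate logical, one flag per column; set by
#'   [zscoreNormalize()] for constant columns that were mapped to zero.
#' @export
setClass("SeriesMatrix",
  representation(values = "matrix", timeStep = "numeric",
                 unitLabels = "character", degenerate = "logical"))

setValidity("SeriesMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (anyNA(v) || any(!is.finite(v))) return("values must be finite with no missing entries")
  if (length(object@timeStep) != 1L || object@timeStep <= 0)
    return("timeStep must be a single positive number")
  if (length(object@unitLabels) != ncol(v))
    return("unitLabels length must match the number of columns")
  if (anyDuplicated(object@unitLabels))
    return("unitLabels must be unique")
  if (length(object@degenerate) != ncol(v))
    return("degenerate flags must match the number of columns")
  TRUE
})

#' Construct a SeriesMatrix
#'
#' @param values numeric matrix (time x unit) or a vector (single unit).
#' @param timeStep seconds per row.
#' @param unitLabels optional column labels; defaults to existing colnames
#'   or `unit1..unitK`.
#' @return A [SeriesMatrix-class] object.
#' @examples
#' sm <- SeriesMatrix(cbind(a = rnorm(10), b = rnorm(10)), timeStep = 2)
#' @export
SeriesMatrix <- function(values, timeStep, unitLabels = NULL) {
  if (is.vector(values)) values <- matrix(values, ncol = 1L)
  if (is.null(unitLabels)) {
    unitLabels <- colnames(values)
    if (is.null(unitLabels)) unitLabels <- paste0("unit", seq_len(ncol(values)))
  }
  colnames(values) <- unitLabels
  new("SeriesMatrix", values = values, timeStep = as.numeric(timeStep),
      unitLabels = unitLabels, degenerate = rep(FALSE, ncol(values)))
}

#' @describeIn SeriesMatrix the underlying time x unit matrix
#' @param x a `SeriesMatrix`
#' @export
seriesValues <- function(x) x@values

#' @describeIn SeriesMatrix seconds per row
#' @export
timeStep <- function(x) x@timeStep

#' @describeIn SeriesMatrix column labels
#' @export
unitLabels <- function(x) x@unitLabels

#' @describeIn SeriesMatrix logical flags for constant (degenerate) columns
#' @export
degenerateUnits <- function(x) x@degenerate

setMethod("show", "SeriesMatrix", function(object) {
  cat(sprintf("SeriesMatrix: %d time points x %d units (timeStep = %g s)\n",
              nrow(object@values), ncol(object@values), object@timeStep))
  if (any(object@degenerate))
    cat("  degenerate units:", paste(object@unitLabels[object@degenerate],
                                     collapse = ", "), "\n")
})

#' Outlier detection/replacement report
#'
#' @slot flags logical matrix time x unit: TRUE where the input exceeded the
#'   threshold (flags are computed on the input values, before replacement).
#' @slot proportionPerUnit numeric vector in `[0, 1]`, equal to the column
#'   means of `flags`.
#' @slot thresholdStd the absolute z-value threshold, as configured.
#' @export
setClass("OutlierReport",
  representation(flags = "matrix", proportionPerUnit = "numeric",
                 thresholdStd = "numeric"))

setValidity("OutlierReport", function(object) {
  if (!is.logical(object@flags)) return("flags must be logical")
  if (length(object@proportionPerUnit) != ncol(object@flags))
    return("proportionPerUnit length must match flag columns")
  if (max(abs(object@proportionPerUnit - colMeans(object@flags))) > 1e-12)
    return("proportionPerUnit must equal the column means of flags")
  if (length(object@thresholdStd) != 1L || object@thresholdStd <= 0)
    return("thresholdStd must be a single positive number")
  TRUE
})

#' @describeIn OutlierReport proportion of flagged time points per unit
#' @param x an `OutlierReport`
#' @export
outlierProportions <- function(x) x@proportionPerUnit

#' @describeIn OutlierReport the logical flag matrix
#' @export
outlierFlags <- function(x) x@flags

setMethod("show", "OutlierReport", function(object) {
  cat(sprintf("OutlierReport: threshold |z| > %g; %d/%d entries flagged\n",
              object@thresholdStd, sum(object@flags), length(object@flags)))
})

#' Scan-aligned EEG band powers
#'
#' Band powers per fMRI scan, EEG channel and frequency band, optionally
#' z-normalized per channel-band pair with previous-value outlier
#' replacement (threshold |z| > 4).
#'
#' @slot values numeric array, scans x channels x bands, with dimnames.
#' @slot normalized logical flag.
#' @slot outliers an [OutlierReport-class] (empty report before
#'   normalization).
#' @export
setClass("BandPowerTensor",
  representation(values = "array", normalized = "logical",
                 outliers = "OutlierReport"))

setValidity("BandPowerTensor", function(object) {
  if (length(dim(object@values)) != 3L)
    return("values must be a scans x channels x bands array")
  if (anyNA(object@values) || any(!is.finite(object@values)))
    return("values must be finite")
  TRUE
})

emptyOutlierReport <- function() {
  new("OutlierReport", flags = matrix(logical(0), 0, 0),
      proportionPerUnit = numeric(0), thresholdStd = 1)
}

#' @describeIn BandPowerTensor the scans x channels x bands array
#' @param x a `BandPowerTensor`
#' @export
bandPowerArray <- function(x) x@values

#' @describeIn BandPowerTensor the attached outlier report
#' @export
bandPowerOutliers <- function(x) x@outliers

setMethod("show", "BandPowerTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf("BandPowerTensor: %d scans x %d channels x %d bands (%s)\n",
              d[1], d[2], d[3],
              if (object@normalized) "normalized" else "raw"))
})

#' Region-by-scan BOLD series
#'
#' Normalized, detrended, outlier-corrected average BOLD per atlas region.
#'
#' @slot values numeric matrix, scans x regions.
#' @slot regionNames character labels, one per column.
#' @slot trS repetition time in seconds.
#' @slot outliers an [OutlierReport-class].
#' @export
setClass("RegionTimeSeries",
  representation(values = "matrix", regionNames = "character",
                 trS = "numeric", outliers = "OutlierReport"))

setValidity("RegionTimeSeries", function(object) {
  if (ncol(object@values) != length(object@regionNames))
    return("regionNames must match the number of columns")
  if (anyNA(object@values) || any(!is.finite(object@values)))
    return("values must be finite")
  if (object@trS <= 0) return("trS must be positive")
  TRUE
})

#' @describeIn RegionTimeSeries the scans x regions matrix
#' @param x a `RegionTimeSeries`
#' @export
regionValues <- function(x) x@values

#' @describeIn RegionTimeSeries region labels
#' @export
regionNames <- function(x) x@regionNames

setMethod("show", "RegionTimeSeries", function(object) {
  cat(sprintf("RegionTimeSeries: %d scans x %d regions (TR = %g s)\n",
              nrow(object@values), ncol(object@values), object@trS))
})

#' Synthetic study configuration
#'
#' Parameters of the synthetic multi-subject EEG-fMRI study generator. The
#' defaults emulate the layout of a 9-subject, 3-condition neurofeedback
#' study: TR 2 s, 64-channel EEG sampled at 200 Hz, 49 cortical regions,
#' and alternating rest/task blocks.
#'
#' @slot nSubjects number of subjects (default 9).
#' @slot conditions ordered condition labels (default eegfmriNF, eegNF,
#'   fmriNF).
#' @slot nRegions number of atlas regions (default 49).
#' @slot nChannels number of EEG channels (default 64).
#' @slot trS repetition time, seconds (default 2).
#' @slot sfreqHz EEG sampling rate, Hz (default 200).
#' @slot nScans scans per session (default 200); must be divisible by
#'   `blockLenScans`.
#' @slot blockLenScans scans per rest/task block (default 20).
#' @slot couplingGain global EEG-to-BOLD coupling amplitude (>= 0).
#' @slot noiseSd BOLD white-noise SD (> 0).
#' @slot driftSlopeSd SD of the per-region linear drift slope, units per
#'   scan (>= 0).
#' @slot outlierRate rate of injected spike outliers in both modalities.
#' @slot blockAmp task-block mean shift added to the modulated channel-band
#'   latents.
#' @slot arCoef AR(1) coefficient of the band-power latents.
#' @slot seed master seed; per-subject/condition/stage substreams are
#'   derived from it.
#' @export
setClass("SyntheticConfig",
  representation(nSubjects = "integer", conditions = "character",
                 nRegions = "integer", nChannels = "integer",
                 trS = "numeric", sfreqHz = "numeric", nScans = "integer",
                 blockLenScans = "integer", couplingGain = "numeric",
                 noiseSd = "numeric", driftSlopeSd = "numeric",
                 outlierRate = "numeric", blockAmp = "numeric",
                 arCoef = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  if (object@nSubjects < 1L || object@nRegions < 1L || object@nChannels < 1L ||
      object@nScans < 1L || object@blockLenScans < 1L)
    return("all counts must be >= 1")
  if (length(object@conditions) < 1L || anyDuplicated(object@conditions))
    return("conditions must be non-empty and unique")
  if (object@nScans %% object@blockLenScans != 0L)
    return("nScans must be divisible by blockLenScans")
  if (object@trS <= 0 || object@sfreqHz <= 0) return("trS and sfreqHz must be positive")
  if (object@couplingGain < 0) return("couplingGain must be >= 0")
  if (object@noiseSd <= 0) return("noiseSd must be > 0")
  if (object@driftSlopeSd < 0) return("driftSlopeSd must be >= 0")
  if (object@outlierRate < 0 || object@outlierRate >= 1)
    return("outlierRate must be in [0, 1)")
  if (abs(object@arCoef) >= 1) return("arCoef must satisfy |arCoef| < 1")
  TRUE
})

#' Construct a SyntheticConfig
#'
#' @param nSubjects,conditions,nRegions,nChannels,trS,sfreqHz,nScans,blockLenScans,couplingGain,noiseSd,driftSlopeSd,outlierRate,blockAmp,arCoef,seed
#'   see [SyntheticConfig-class].
#' @return A validated [SyntheticConfig-class].
#' @examples
#' cfg <- syntheticConfig(nSubjects = 2, nRegions = 4, nChannels = 2,
#'                        nScans = 40, seed = 7)
#' @export
syntheticConfig <- function(nSubjects = 9L,
                            conditions = c("eegfmriNF", "eegNF", "fmriNF"),
                            nRegions = 49L, nChannels = 64L,
                            trS = 2, sfreqHz = 200, nScans = 200L,
                            blockLenScans = 20L, couplingGain = 1,
                            noiseSd = 1, driftSlopeSd = 0.01,
                            outlierRate = 5e-4, blockAmp = 1,
                            arCoef = 0.5, seed = 1L) {
  new("SyntheticConfig", nSubjects = as.integer(nSubjects),
      conditions = as.character(conditions), nRegions = as.integer(nRegions),
      nChannels = as.integer(nChannels), trS = as.numeric(trS),
      sfreqHz = as.numeric(sfreqHz), nScans = as.integer(nScans),
      blockLenScans = as.integer(blockLenScans),
      couplingGain = as.numeric(couplingGain), noiseSd = as.numeric(noiseSd),
      driftSlopeSd = as.numeric(driftSlopeSd),
      outlierRate = as.numeric(outlierRate), blockAmp = as.numeric(blockAmp),
      arCoef = as.numeric(arCoef), seed = as.integer(seed))
}

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(paste0("SyntheticConfig: %d subjects x %d conditions, ",
                     "%d scans (TR %g s), %d channels, %d regions\n"),
              object@nSubjects, length(object@conditions), object@nScans,
              object@trS, object@nChannels, object@nRegions))
  cat(sprintf("  couplingGain %g, noiseSd %g, outlierRate %g, seed %d\n",
              object@couplingGain, object@noiseSd, object@outlierRate,
              object@seed))
})

#' Synthetic EEG-fMRI study with ground truth
#'
#' @slot config the generating [SyntheticConfig-class].
#' @slot sessions named list (`sub-01.eegfmriNF`, ...), each a list with
#'   `bandPowers` (scans x channels x bands array), `bold`
#'   (scans x regions matrix) and optionally `rawEEG`
#'   (channels x samples matrix).
#' @slot truth list with per-subject coupling weight arrays
#'   (region x channel x band), the HRF parameters/kernel and the block
#'   design vector (0 = rest, 1 = task).
#' @export
setClass("SyntheticStudy",
  representation(config = "SyntheticConfig", sessions = "list",
                 truth = "list"))

#' @describeIn SyntheticStudy list of per-(subject, condition) sessions
#' @param x a `SyntheticStudy`
#' @export
studySessions <- function(x) x@sessions

#' @describeIn SyntheticStudy generating ground truth (coupling, HRF, block
#'   design)
#' @export
studyTruth <- function(x) x@truth

#' @describeIn SyntheticStudy the generating configuration
#' @export
studyConfig <- function(x) x@config

setMethod("show", "SyntheticStudy", function(object) {
  cat(sprintf("SyntheticStudy: %d sessions (%d subjects x %d conditions)\n",
              length(object@sessions), object@config@nSubjects,
              length(object@config@conditions)))
})

#' Supervised learning set
#'
#' Lagged band-power features with direction labels and regression targets,
#' indexed by (subject, condition, region, scan).
#'
#' @slot X numeric samples x features matrix.
#' @slot yClass factor with levels `increase`, `decrease`.
#' @slot yReg numeric regression target (the normalized BOLD value).
#' @slot index data.frame with columns subject, condition, region, scan.
#' @export
setClass("SupervisedSet",
  representation(X = "matrix", yClass = "factor", yReg = "numeric",
                 index = "data.frame"))

setValidity("SupervisedSet", function(object) {
  n <- nrow(object@X)
  if (length(object@yClass) != n || length(object@yReg) != n ||
      nrow(object@index) != n)
    return("X, yClass, yReg and index must have equal sample counts")
  if (!identical(levels(object@yClass), c("increase", "decrease")))
    return("yClass levels must be increase, decrease")
  TRUE
})

#' @describeIn SupervisedSet number of samples
#' @param x a `SupervisedSet`
#' @export
nSamples <- function(x) nrow(x@X)

setMethod("show", "SupervisedSet", function(object) {
  cat(sprintf("SupervisedSet: %d samples x %d features\n",
              nrow(object@X), ncol(object@X)))
})
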