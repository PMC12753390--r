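#' Average 4D BOLD voxels within atlas regions
#'
#' Entry (t, r) is the unweighted mean over voxels labeled r at scan t.
#' Background voxels (label 0) are excluded. A region listed in
#' `regionNames` but absent from the label volume yields a sentinel column
#' of zeros and a warning; the affected regions are recorded in the
#' `emptyRegions` attribute so partial-coverage volumes still run.
#'
#' @param bold4d 4D numeric array (x, y, z, scans) or a NIfTI path/image
#'   readable by [RNifti::readNifti()].
#' @param labels integer volume of the same spatial shape (0 = background),
#'   or a NIfTI path/image.
#' @param regionNames labels for values `1..R`; defaults to
#'   `region1..regionR` with `R = max(labels)`.
#' @return Matrix scans x regions with an `emptyRegions` attribute.
#' @export
roiAverage <- function(bold4d, labels, regionNames = NULL) {
  if (is.character(bold4d)) bold4d <- RNifti::readNifti(bold4d)
  if (is.character(labels)) labels <- RNifti::readNifti(labels)
  bold4d <- unclass(bold4d); labels <- unclass(labels)
  if (!identical(dim(bold4d)[1:3], dim(labels)[1:3]))
    stop("spatial shapes of bold4d and labels differ")
  lab <- as.integer(labels)
  nR <- if (is.null(regionNames)) max(lab) else length(regionNames)
  if (is.null(regionNames)) regionNames <- paste0("region", seq_len(nR))
  nScans <- dim(bold4d)[4]
  voxMat <- matrix(bold4d, ncol = nScans)      # voxels x scans
  counts <- tabulate(lab, nbins = nR)
  out <- matrix(0, nScans, nR, dimnames = list(NULL, regionNames))
  for (r in seq_len(nR)) {
    vox <- lab == r
    if (counts[r] > 0)
      out[, r] <- colMeans(voxMat[vox, , drop = FALSE])
  }
  empty <- regionNames[counts == 0]
  if (length(empty))
    warning("empty atlas regions set to sentinel 0: ",
            paste(empty, collapse = ", "))
  attr(out, "emptyRegions") <- empty
  out
}

#' Preprocess a region-by-scan BOLD matrix
#'
#' Applies, in order: linear drift removal ([removeDrift()]),
#' z-normalization ([zscoreNormalize()]) and previous-value outlier
#' replacement at |z| > 3 ([replaceOutliersWithPrevious()]).
#'
#' @param m scans x regions numeric matrix (e.g. from [roiAverage()] or a
#'   synthetic session).
#' @param trS repetition time, seconds.
#' @param thresholdStd outlier threshold in SD units (default 3).
#' @param ddof SD denominator convention (see [zscoreNormalize()]).
#' @return A [RegionTimeSeries-class] with the outlier report attached.
#' @export
preprocessBold <- function(m, trS = 2, thresholdStd = 3, ddof = 0) {
  if (is.vector(m)) m <- matrix(m, ncol = 1L)
  if (nrow(m) < 3L) stop("preprocessBold() needs at least 3 scans")
  names <- colnames(m) %||% paste0("region", seq_len(ncol(m)))
  sm <- SeriesMatrix(m, timeStep = trS, unitLabels = names)
  res <- replaceOutliersWithPrevious(zscoreNormalize(removeDrift(sm), ddof = ddof),
                                     thresholdStd = thresholdStd)
  new("RegionTimeSeries", values = res$series@values, regionNames = names,
      trS = as.numeric(trS), outliers = res$report)
}

#' Write a RegionTimeSeries as TSV plus JSON sidecar
#'
#' @param rts a [RegionTimeSeries-class].
#' @param tsvPath output TSV (scan rows x region columns).
#' @param jsonPath optional JSON sidecar (TR, outlier threshold).
#' @return `tsvPath`, invisibly.
#' @export
writeRegionTimeSeries <- function(rts, tsvPath, jsonPath = NULL) {
  utils::write.table(rts@values, tsvPath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(list(trS = rts@trS,
                              thresholdStd = rts@outliers@thresholdStd,
                              processing = c("removeDrift", "zscoreNormalize",
                                             "replaceOutliersWithPrevious")),
                         jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(tsvPath)
}
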