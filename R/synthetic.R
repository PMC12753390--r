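#' @title Synthetic EEG-fMRI study generator
#' @description Internal seed-stream helpers plus the exported simulation
#'   operations. One master seed drives hierarchical substreams keyed by
#'   (subject, condition, stage), so adding a subject or requesting an
#'   extra stage never perturbs previously generated sessions.
#' @name synthetic
NULL

# deterministic 31-bit substream seed from the master seed and a key string
substreamSeed <- function(master, ...) {
  key <- paste(c(master, ...), collapse = "/")
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483629
  as.integer(h + 1)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Alternating rest/task block design
#'
#' @param nScans total scans; must be divisible by `blockLenScans`.
#' @param blockLenScans scans per block.
#' @return Integer vector of 0 (rest) / 1 (task), starting with rest.
#' @export
blockDesign <- function(nScans, blockLenScans) {
  if (nScans %% blockLenScans != 0)
    stop("nScans must be divisible by blockLenScans")
  rep(rep_len(c(0L, 1L), nScans / blockLenScans), each = blockLenScans)
}

# channel-band pairs whose mean shifts during task blocks: alpha and beta
# bands of the first half of the montage (motor-imagery-like modulation)
modulatedMask <- function(nChannels, bands = defaultBands()) {
  mask <- matrix(FALSE, nChannels, nrow(bands),
                 dimnames = list(NULL, bands$name))
  mod <- bands$name %in% c("alpha", "beta")
  mask[seq_len(ceiling(nChannels / 2)), mod] <- TRUE
  mask
}

#' Simulate band-power latents
#'
#' Stationary AR(1) series (unit marginal variance) per channel-band pair,
#' plus a block-design mean shift of `blockAmp` on the modulated
#' channel-band subset (alpha and beta bands of the first half of the
#' montage).
#'
#' @param cfg a [SyntheticConfig-class].
#' @param streamSeed integer seed for this draw (derive one per session).
#' @return Array scans x channels x bands with dimnames.
#' @export
simulateBandPowerLatents <- function(cfg, streamSeed = cfg@seed) {
  validObject(cfg)
  bands <- defaultBands()
  nB <- nrow(bands)
  nU <- cfg@nChannels * nB
  rho <- cfg@arCoef
  lat <- withSeed(streamSeed, {
    innov <- matrix(stats::rnorm(cfg@nScans * nU, sd = sqrt(1 - rho^2)),
                    cfg@nScans, nU)
    innov[1L, ] <- stats::rnorm(nU)   # stationary start
    apply(innov, 2L, function(e) stats::filter(e, rho, method = "recursive"))
  })
  design <- blockDesign(cfg@nScans, cfg@blockLenScans)
  mask <- modulatedMask(cfg@nChannels, bands)
  lat <- lat + outer(design, as.numeric(mask)) * cfg@blockAmp
  array(lat, dim = c(cfg@nScans, cfg@nChannels, nB),
        dimnames = list(NULL, paste0("ch", seq_len(cfg@nChannels)),
                        bands$name))
}

#' Random sparse coupling weights
#'
#' Each region is coupled to `nCoupled` distinct channel-band pairs with
#' standard-normal weights; all other weights are zero.
#'
#' @param cfg a [SyntheticConfig-class].
#' @param nCoupled coupled channel-band pairs per region.
#' @param streamSeed integer seed.
#' @return Array region x channel x band.
#' @export
simulateCoupling <- function(cfg, nCoupled = 3L, streamSeed = cfg@seed) {
  bands <- defaultBands()
  nU <- cfg@nChannels * nrow(bands)
  nCoupled <- min(nCoupled, nU)
  W <- withSeed(streamSeed, {
    w <- matrix(0, cfg@nRegions, nU)
    for (r in seq_len(cfg@nRegions))
      w[r, sample.int(nU, nCoupled)] <- stats::rnorm(nCoupled)
    w
  })
  array(W, dim = c(cfg@nRegions, cfg@nChannels, nrow(bands)),
        dimnames = list(paste0("region", seq_len(cfg@nRegions)),
                        paste0("ch", seq_len(cfg@nChannels)), bands$name))
}

# causal convolution truncated at the session start
causalConvolve <- function(x, kernel) {
  n <- length(x)
  y <- stats::convolve(x, rev(kernel), type = "open")[seq_len(n)]
  y
}

#' Simulate regional BOLD from band-power latents
#'
#' Each region's series is the causal convolution (truncated at scan 0, no
#' pre-session history) of the coupling-weighted channel-band sum with the
#' HRF kernel, scaled by `couplingGain`, plus a linear drift with a random
#' per-region slope and white measurement noise.
#'
#' @param latents scans x channels x bands array.
#' @param coupling region x channel x band weight array.
#' @param hrf HRF kernel sampled at the TR (see [makeHRF()]).
#' @param cfg a [SyntheticConfig-class].
#' @param streamSeed integer seed for drift slopes and noise.
#' @return Matrix scans x regions.
#' @export
simulateBold <- function(latents, coupling, hrf, cfg,
                         streamSeed = cfg@seed) {
  d <- dim(latents)
  dc <- dim(coupling)
  if (length(d) != 3L || length(dc) != 3L || !all(d[2:3] == dc[2:3]))
    stop("latents and coupling have inconsistent channel/band dimensions")
  nScans <- d[1]
  latMat <- matrix(latents, nScans, d[2] * d[3])
  wMat <- t(matrix(coupling, dc[1], dc[2] * dc[3]))
  drive <- latMat %*% wMat                     # scans x regions
  signal <- apply(drive, 2L, causalConvolve, kernel = hrf) * cfg@couplingGain
  withSeed(streamSeed, {
    slopes <- stats::rnorm(dc[1], sd = cfg@driftSlopeSd)
    noise <- matrix(stats::rnorm(nScans * dc[1], sd = cfg@noiseSd),
                    nScans, dc[1])
    bold <- signal + outer(seq_len(nScans) - 1, slopes) + noise
    colnames(bold) <- dimnames(coupling)[[1]]
    bold
  })
}

# inject rare spike outliers (6 column SDs) at rate cfg@outlierRate
injectOutliers <- function(m, rate, streamSeed) {
  if (rate <= 0) return(m)
  withSeed(streamSeed, {
    hits <- which(stats::runif(length(m)) < rate)
    if (length(hits)) {
      cols <- (hits - 1) %/% nrow(m) + 1
      mu <- colMeans(m)[cols]
      sd <- apply(m, 2, stats::sd)[cols]
      m[hits] <- mu + sample(c(-1, 1), length(hits), TRUE) * 6 * sd
    }
    m
  })
}

#' Generate a complete synthetic study
#'
#' Fills every subject x condition session with a band-power tensor and a
#' BOLD matrix carrying known hemodynamically delayed EEG-to-BOLD
#' coupling. Coupling weights are drawn once per subject and shared across
#' that subject's conditions (so cross-condition generalization is
#' possible); per-session noise, drift and outliers come from independent
#' substreams. Optionally realizes raw EEG: per scan, each channel is a
#' sum of band-centre sinusoids whose squared amplitudes equal
#' `2 * pmax(latent + rawPowerOffset, 0)` plus broadband noise, so Welch
#' band powers recover `latent + rawPowerOffset`.
#'
#' @param cfg a [SyntheticConfig-class].
#' @param hrf optional HRF parameters ([hrfParams()]).
#' @param nCoupled coupled channel-band pairs per region.
#' @param rawEEG logical; also realize a raw EEG signal per session.
#' @param rawPowerOffset additive offset making latent band powers positive
#'   before raw-signal synthesis (mean latent power in uV^2).
#' @param rawNoiseSd broadband noise SD of the raw signal (uV).
#' @return A [SyntheticStudy-class].
#' @examples
#' study <- generateStudy(syntheticConfig(nSubjects = 1, nRegions = 3,
#'   nChannels = 2, nScans = 40, seed = 7))
#' @export
generateStudy <- function(cfg, hrf = hrfParams(), nCoupled = 3L,
                          rawEEG = FALSE, rawPowerOffset = 5,
                          rawNoiseSd = 0.1) {
  validObject(cfg)
  kernel <- makeHRF(hrf, cfg@trS)
  subjects <- sprintf("sub-%02d", seq_len(cfg@nSubjects))
  coupling <- lapply(subjects, function(s)
    simulateCoupling(cfg, nCoupled, substreamSeed(cfg@seed, s, "coupling")))
  names(coupling) <- subjects
  sessions <- list()
  for (s in subjects) {
    for (cond in cfg@conditions) {
      lat <- simulateBandPowerLatents(cfg, substreamSeed(cfg@seed, s, cond, "eeg"))
      bold <- simulateBold(lat, coupling[[s]], kernel, cfg,
                           substreamSeed(cfg@seed, s, cond, "bold"))
      d <- dim(lat)
      latFlat <- matrix(lat, d[1], d[2] * d[3])
      latFlat <- injectOutliers(latFlat, cfg@outlierRate,
                                substreamSeed(cfg@seed, s, cond, "eegout"))
      lat <- array(latFlat, dim = d, dimnames = dimnames(lat))
      bold <- injectOutliers(bold, cfg@outlierRate,
                             substreamSeed(cfg@seed, s, cond, "boldout"))
      sess <- list(bandPowers = lat, bold = bold, rawEEG = NULL)
      if (rawEEG)
        sess$rawEEG <- synthesizeRawEEG(lat, cfg, rawPowerOffset, rawNoiseSd,
                                        substreamSeed(cfg@seed, s, cond, "raw"))
      sessions[[paste(s, cond, sep = ".")]] <- sess
    }
  }
  new("SyntheticStudy", config = cfg, sessions = sessions,
      truth = list(coupling = coupling, hrfParams = hrf, hrfKernel = kernel,
                   blockDesign = blockDesign(cfg@nScans, cfg@blockLenScans),
                   rawPowerOffset = if (rawEEG) rawPowerOffset else NULL))
}

synthesizeRawEEG <- function(latents, cfg, powerOffset, noiseSd, streamSeed) {
  bands <- defaultBands()
  centers <- (bands$lowHz + bands$highHz) / 2
  spScan <- round(cfg@trS * cfg@sfreqHz)
  nSamples <- cfg@nScans * spScan
  tau <- (seq_len(spScan) - 1) / cfg@sfreqHz
  withSeed(streamSeed, {
    sig <- matrix(stats::rnorm(cfg@nChannels * nSamples, sd = noiseSd),
                  cfg@nChannels, nSamples)
    for (scan in seq_len(cfg@nScans)) {
      idx <- (scan - 1) * spScan + seq_len(spScan)
      for (ch in seq_len(cfg@nChannels)) {
        amp <- sqrt(2 * pmax(latents[scan, ch, ] + powerOffset, 0))
        phase <- stats::runif(length(centers), 0, 2 * pi)
        comp <- vapply(seq_along(centers), function(b)
          amp[b] * sin(2 * pi * centers[b] * tau + phase[b]),
          numeric(spScan))
        sig[ch, idx] <- sig[ch, idx] + rowSums(comp)
      }
    }
    rownames(sig) <- paste0("ch", seq_len(cfg@nChannels))
    sig
  })
}

#' Write a synthetic study to a BIDS-inspired directory
#'
#' Per session, BOLD and band powers as TSV; ground-truth coupling and the
#' configuration as JSON.
#'
#' @param study a [SyntheticStudy-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- study@config
  for (key in names(study@sessions)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    sdir <- file.path(dir, parts[1], parts[2])
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    sess <- study@sessions[[key]]
    utils::write.table(sess$bold, file.path(sdir, "bold.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    bp <- sess$bandPowers
    long <- data.frame(scan = rep(seq_len(dim(bp)[1]), times = dim(bp)[2] * dim(bp)[3]),
                       channel = rep(rep(dimnames(bp)[[2]], each = dim(bp)[1]),
                                     times = dim(bp)[3]),
                       band = rep(dimnames(bp)[[3]], each = dim(bp)[1] * dim(bp)[2]),
                       value = as.vector(bp))
    utils::write.table(long, file.path(sdir, "band_powers.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  truth <- list(
    config = list(nSubjects = cfg@nSubjects, conditions = cfg@conditions,
                  nRegions = cfg@nRegions, nChannels = cfg@nChannels,
                  trS = cfg@trS, sfreqHz = cfg@sfreqHz, nScans = cfg@nScans,
                  blockLenScans = cfg@blockLenScans,
                  couplingGain = cfg@couplingGain, noiseSd = cfg@noiseSd,
                  driftSlopeSd = cfg@driftSlopeSd,
                  outlierRate = cfg@outlierRate, seed = cfg@seed),
    hrfParams = unclass(study@truth$hrfParams),
    blockDesign = study@truth$blockDesign,
    coupling = lapply(study@truth$coupling, as.vector))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
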