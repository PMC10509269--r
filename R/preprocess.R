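# Spectral preprocessing: subsetting, paraffin channel removal, outlier
# pixels, despiking, ALS baseline, normalization.

#' Preprocessing configuration
#'
#' Bundles the spectral-QC parameters. FFPE paraffin residue produces sharp
#' bands at 1064, 1132, 1294 and 1441 cm^-1; those channels are dropped in a
#' +/- `paraffinWindow` cm^-1 window. Technical outlier pixels are flagged by
#' a MAD rule on per-pixel total intensity. Cosmic-ray spikes are replaced by
#' a windowed median; baseline is asymmetric least squares.
#'
#' @param outlierK MAD multiplier for the outlier rule (default 5).
#' @param paraffinCenters paraffin band centres, cm^-1.
#' @param paraffinWindow half-width around each centre, cm^-1 (default 10).
#' @param despikeWindow odd sliding-window width in channels (default 5).
#' @param despikeZ robust z threshold for spike replacement (default 8).
#' @param baseline `"none"` or `"als"` (asymmetric least squares).
#' @param baselineLambda ALS smoothness (default 1e5).
#' @param baselineP ALS asymmetry (default 0.01).
#' @param normalize `"none"` or `"total"` (total-intensity scaling + log1p).
#' @return A validated list of class `PreprocessConfig`.
#' @export
preprocessConfig <- function(outlierK = 5,
                             paraffinCenters = c(1064, 1132, 1294, 1441),
                             paraffinWindow = 10,
                             despikeWindow = 5L, despikeZ = 8,
                             baseline = c("none", "als"),
                             baselineLambda = 1e5, baselineP = 0.01,
                             normalize = c("total", "none")) {
  baseline <- match.arg(baseline)
  normalize <- match.arg(normalize)
  if (outlierK <= 0) stop("outlierK must be > 0")
  if (paraffinWindow < 0) stop("paraffinWindow must be >= 0")
  if (despikeWindow <= 0) stop("despikeWindow must be > 0")
  if (despikeWindow %% 2L == 0L) stop("despikeWindow must be odd")
  cfg <- list(outlierK = outlierK, paraffinCenters = paraffinCenters,
              paraffinWindow = paraffinWindow,
              despikeWindow = as.integer(despikeWindow), despikeZ = despikeZ,
              baseline = baseline, baselineLambda = baselineLambda,
              baselineP = baselineP, normalize = normalize)
  class(cfg) <- "PreprocessConfig"
  cfg
}

#' Restrict a scan to a wavenumber interval
#'
#' Keeps exactly the channels with `lo <= wavenumber <= hi` (closed
#' interval). The biological "fingerprint" window is 400-1800 cm^-1.
#'
#' @param map a [SpectralMap-class].
#' @param lo,hi interval bounds, cm^-1, `lo < hi`.
#' @return The subsetted [SpectralMap-class].
#' @export
subsetSpectrum <- function(map, lo = 400, hi = 1800) {
  if (lo >= hi) stop("lo must be < hi")
  keep <- wavenumbers(map) >= lo & wavenumbers(map) <= hi
  if (!any(keep))
    stop(sprintf("no channels in the requested interval [%g, %g] cm-1", lo, hi))
  map@wavenumbers <- map@wavenumbers[keep]
  map@intensities <- map@intensities[, keep, drop = FALSE]
  validObject(map)
  .addProvenance(map, "subsetSpectrum", list(lo = lo, hi = hi))
}

#' Drop paraffin-contaminated channels
#'
#' Removes every channel within `window` cm^-1 (closed interval) of any of
#' the given band centres.
#'
#' @param map a [SpectralMap-class].
#' @param centers band centres, cm^-1 (defaults: the four paraffin bands).
#' @param window half-width, cm^-1, `>= 0`.
#' @return The reduced [SpectralMap-class].
#' @export
removeParaffinChannels <- function(map, centers = c(1064, 1132, 1294, 1441),
                                   window = 10) {
  if (window < 0) stop("window must be >= 0")
  wn <- wavenumbers(map)
  drop <- Reduce(`|`, lapply(centers, function(c0) abs(wn - c0) <= window))
  if (all(drop)) stop("paraffin removal would drop all channels")
  if (!any(drop)) return(.addProvenance(map, "removeParaffinChannels",
                                        list(centers = centers, window = window,
                                             dropped = 0L)))
  map@wavenumbers <- wn[!drop]
  map@intensities <- map@intensities[, !drop, drop = FALSE]
  validObject(map)
  .addProvenance(map, "removeParaffinChannels",
                 list(centers = centers, window = window, dropped = sum(drop)))
}

#' Flag technical outlier pixels by total intensity
#'
#' A pixel is flagged when its total intensity deviates from the median of
#' per-pixel totals by more than `k` times the MAD (scaled by 1.4826). When
#' the MAD is zero, any pixel deviating from the median is flagged.
#'
#' @param map a [SpectralMap-class] with at least 3 pixels.
#' @param k MAD multiplier (default 5).
#' @return Logical per-pixel vector, `TRUE` = outlier.
#' @export
detectOutlierPixels <- function(map, k = 5) {
  if (nPixels(map) < 3L) stop("need at least 3 pixels")
  totals <- rowSums(intensities(map))
  med <- stats::median(totals)
  m <- stats::mad(totals)  # constant = 1.4826
  if (m == 0) totals != med else abs(totals - med) > k * m
}

#' Apply the outlier rule to the QC mask
#'
#' Flagged pixels get `qcMask = FALSE` but remain addressable for spatial
#' plots; downstream matrices exclude them.
#'
#' @inheritParams detectOutlierPixels
#' @return The [SpectralMap-class] with an updated mask.
#' @export
maskOutlierPixels <- function(map, k = 5) {
  out <- detectOutlierPixels(map, k)
  map@qcMask <- map@qcMask & !out
  .addProvenance(map, "maskOutlierPixels", list(k = k, flagged = sum(out)))
}

# windowed-median despiking of one spectrum: channels whose robust z-score
# within a sliding window exceeds z are replaced by the window median
.despikeSpectrum <- function(y, window, z) {
  n <- length(y)
  half <- window %/% 2L
  out <- y
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    w <- y[lo:hi]
    med <- stats::median(w)
    s <- stats::mad(w)
    if (s == 0) s <- .Machine$double.eps
    if (abs(y[i] - med) / s > z) out[i] <- med
  }
  out
}

#' Asymmetric-least-squares baseline of one spectrum
#'
#' Whittaker smoother with asymmetric weights (p for points above the
#' baseline, 1-p below), second-difference penalty `lambda`.
#'
#' @param y numeric spectrum.
#' @param lambda smoothness (default 1e5).
#' @param p asymmetry (default 0.01).
#' @param maxIter weight-update iterations (default 10).
#' @return The estimated baseline, same length as `y`.
#' @export
baselineALS <- function(y, lambda = 1e5, p = 0.01, maxIter = 10L) {
  n <- length(y)
  if (n < 4L) return(rep(min(y), n))
  D <- diff(diag(n), differences = 2L)
  P <- lambda * crossprod(D)
  w <- rep(1, n)
  zfit <- y
  for (it in seq_len(maxIter)) {
    zfit <- solve(diag(w) + P, w * y)
    wNew <- ifelse(y > zfit, p, 1 - p)
    if (all(wNew == w)) break
    w <- wNew
  }
  zfit
}

#' Despike, baseline-correct and normalize a scan
#'
#' Order of operations: despike -> baseline -> normalize. Despiking replaces
#' channels whose robust z-score within a sliding window exceeds
#' `cfg$despikeZ` by the window median; the ALS baseline (if enabled) is
#' subtracted per spectrum; normalization follows [normalizeSpectra()].
#'
#' @param map a [SpectralMap-class].
#' @param cfg a [preprocessConfig()] list.
#' @return The preprocessed [SpectralMap-class].
#' @export
preprocessRaw <- function(map, cfg = preprocessConfig()) {
  if (!inherits(cfg, "PreprocessConfig")) stop("cfg must come from preprocessConfig()")
  X <- intensities(map)
  if (cfg$despikeZ < Inf) {
    X <- t(apply(X, 1L, .despikeSpectrum, window = cfg$despikeWindow,
                 z = cfg$despikeZ))
    map@intensities <- X
    map <- .addProvenance(map, "despike",
                          list(window = cfg$despikeWindow, z = cfg$despikeZ))
  }
  if (cfg$baseline == "als") {
    B <- t(apply(X, 1L, baselineALS, lambda = cfg$baselineLambda,
                 p = cfg$baselineP))
    map@intensities <- X - B
    map <- .addProvenance(map, "baselineALS",
                          list(lambda = cfg$baselineLambda, p = cfg$baselineP))
  }
  if (cfg$normalize == "total") map <- normalizeSpectra(map, "total")
  map
}

#' Normalize pixel spectra
#'
#' `"total"` scales each retained pixel so its channel sum equals the median
#' pre-scaling total over retained pixels, then applies `log1p`; within-pixel
#' intensity ranks are preserved. Pixels with zero total are left unscaled
#' (warning). `"none"` is the identity.
#'
#' @param map a [SpectralMap-class].
#' @param mode `"total"` or `"none"`.
#' @return The normalized [SpectralMap-class].
#' @export
normalizeSpectra <- function(map, mode = c("total", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(map)
  X <- intensities(map)
  retained <- qcMask(map)
  totals <- rowSums(X)
  target <- stats::median(totals[retained])
  zero <- totals == 0
  if (any(zero & retained))
    warning(sum(zero & retained), " pixel(s) with zero total left unscaled")
  scale <- ifelse(zero, 1, target / totals)
  map@intensities <- log1p(X * scale)
  .addProvenance(map, "normalize", list(mode = mode, target = target))
}

#' Drop QC-flagged pixels from a matrix view
#'
#' Convenience: the retained-pixel intensity matrix and the matching
#' 1-based pixel indices.
#'
#' @param map a [SpectralMap-class].
#' @return list with `matrix` (`nRetained x nChannels`) and `pixels`.
#' @export
retainedMatrix <- function(map) {
  keep <- which(qcMask(map))
  list(matrix = intensities(map)[keep, , drop = FALSE], pixels = keep)
}
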