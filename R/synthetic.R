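# Synthetic hyperspectral scenes: peak-library spectra at literature band
# positions, planted spatial regions and gradients, paraffin/glass/cosmic
# artifacts, paired MSI grids under a known similarity transform, and
# cell-label masks. Every generator is deterministic under its seed and
# returns the planted ground truth alongside the data.

#' Default and instrument-like wavenumber axes
#'
#' The desk-scale default covers the biological fingerprint window
#' (400-1800 cm^-1 at 2 cm^-1 spacing); the instrument-like preset covers
#' 300-3000 cm^-1 with 692 channels.
#'
#' @param preset `"fingerprint"` (default) or `"instrument"`.
#' @return numeric wavenumber axis.
#' @export
defaultAxis <- function(preset = c("fingerprint", "instrument")) {
  preset <- match.arg(preset)
  if (preset == "fingerprint") seq(400, 1800, by = 2)
  else seq(300, 3000, length.out = 692)
}

#' Built-in Raman signature library
#'
#' Named signatures, each a data.frame of (center cm^-1, amplitude, width,
#' shape). Band positions follow the literature: collagen 858/940/1249/1680
#' (hydroxyproline, C-C backbone, amide III, amide I), nucleic acids
#' 784/1096/1376/1580, paraffin 1064/1132/1294/1441, hemin 1372
#' (erythrocytes), cytochrome c at a configurable centre (reported at both
#' 1314 and 1318 cm^-1), and a two-hump glass background over 400-600 and
#' 1000-1200 cm^-1. Peak widths default to 8 cm^-1 SD; amplitudes are
#' relative.
#'
#' @param cytochromeCenter cytochrome c band centre (default 1314).
#' @param width default peak SD, cm^-1 (default 8).
#' @return named list of signature data.frames.
#' @export
signatureLibrary <- function(cytochromeCenter = 1314, width = 8) {
  sig <- function(centers, amps, widths = width, shape = "gaussian") {
    data.frame(center = centers, amplitude = amps,
               width = rep(widths, length.out = length(centers)),
               shape = rep(shape, length.out = length(centers)),
               stringsAsFactors = FALSE)
  }
  list(
    myocardium = sig(c(858, cytochromeCenter, 1449, 1660),
                     c(0.4, 1.0, 0.8, 0.9)),
    collagen = sig(c(858, 940, 1249, 1680), c(1.0, 0.8, 0.7, 0.9)),
    nucleic_acids = sig(c(784, 1096, 1376, 1580), c(0.9, 0.7, 0.8, 1.0)),
    paraffin = sig(c(1064, 1132, 1294, 1441), c(1.0, 0.9, 0.9, 1.2), widths = 5),
    hemin = sig(1372, 1.5),
    erythrocyte = sig(c(752, 1372, 1580), c(0.6, 1.5, 0.8)),
    leukocyte = sig(c(784, 1096, 1376, 1580, 1660), c(0.9, 0.7, 0.8, 1.0, 0.5)),
    cardiomyocyte = sig(c(858, cytochromeCenter, 1449, 1660),
                        c(0.4, 1.2, 0.8, 0.9)),
    glass = sig(c(500, 1100), c(0.5, 0.5), widths = 60)
  )
}

# evaluate one signature's noise-free spectrum on an axis
.signatureSpectrum <- function(signature, axis, amplitudeScale = 1) {
  y <- numeric(length(axis))
  for (i in seq_len(nrow(signature))) {
    c0 <- signature$center[i]; a <- signature$amplitude[i] * amplitudeScale
    w <- signature$width[i]
    y <- y + if (identical(signature$shape[i], "lorentzian"))
      a * w^2 / ((axis - c0)^2 + w^2)
    else
      a * exp(-(axis - c0)^2 / (2 * w^2))
  }
  y
}

#' Generate a single synthetic spectrum
#'
#' Sum of the signature's peak shapes plus an optional baseline plus i.i.d.
#' Gaussian noise; reproducible under the seed.
#'
#' @param signature a signature data.frame (see [signatureLibrary()]).
#' @param axis wavenumber axis.
#' @param noiseSD Gaussian noise SD (default 0).
#' @param baseline numeric offset, a length-2 `(intercept, slope per cm^-1)`
#'   linear ramp, or a full-length vector.
#' @param seed RNG seed (default 1).
#' @return numeric spectrum on `axis`.
#' @export
generateSpectrum <- function(signature, axis, noiseSD = 0, baseline = 0,
                             seed = 1L) {
  if (any(signature$center < min(axis) | signature$center > max(axis)))
    stop("signature centres must lie within the axis")
  set.seed(seed)
  b <- if (length(baseline) == 2L)
    baseline[1L] + baseline[2L] * (axis - min(axis))
  else rep(baseline, length.out = length(axis))
  .signatureSpectrum(signature, axis) + b +
    stats::rnorm(length(axis), sd = noiseSD)
}

#' Scene specification for the synthetic generators
#'
#' @param gridShape `(rows, cols)` (default `c(40, 40)`).
#' @param pixelSize micrometres per pixel (default 1).
#' @param axis wavenumber axis (default [defaultAxis()]).
#' @param background signature name for unassigned pixels (default
#'   `"myocardium"`).
#' @param regions list of region specs; each a list with `shape`
#'   (`"rect"` or `"ellipse"`), geometry (`rows`/`cols` 0-based inclusive
#'   ranges for rect; `center`/`radii` for ellipse), `signature` (name),
#'   optional `amplitude` (default 1) and `jitterSD` (per-pixel amplitude
#'   jitter SD, default the scene's). Listed order wins on overlap.
#' @param jitterSD default per-pixel amplitude jitter SD (default 0.05).
#' @param noiseSD channel noise SD, relative to unit peak amplitude
#'   (default 0.02).
#' @param intensityScale multiplier mapping the unit-amplitude peak library
#'   to detector-count-like intensities (default 100).
#' @param cosmicRate expected cosmic-ray spikes per pixel (default 0).
#' @param glassAmplitude glass background amplitude (default 0).
#' @param baselineDrift linear baseline slope per cm^-1 (default 0).
#' @param seed RNG seed (default 1).
#' @param library signature library (default [signatureLibrary()]).
#' @return A validated list of class `SceneSpec`.
#' @export
sceneSpec <- function(gridShape = c(40L, 40L), pixelSize = 1,
                      axis = defaultAxis(), background = "myocardium",
                      regions = list(), jitterSD = 0.05, noiseSD = 0.02,
                      intensityScale = 100, cosmicRate = 0,
                      glassAmplitude = 0, baselineDrift = 0,
                      seed = 1L, library = signatureLibrary()) {
  if (cosmicRate < 0 || noiseSD < 0 || jitterSD < 0)
    stop("rates and noise levels must be >= 0")
  for (r in regions) {
    if (!r$signature %in% names(library))
      stop("unknown signature: ", r$signature)
    if (identical(r$shape, "rect")) {
      if (any(r$rows < 0) || any(r$cols < 0) ||
          max(r$rows) >= gridShape[1L] || max(r$cols) >= gridShape[2L])
        stop("rect region outside grid")
    }
  }
  spec <- list(gridShape = as.integer(gridShape), pixelSize = pixelSize,
               axis = axis, background = background, regions = regions,
               jitterSD = jitterSD, noiseSD = noiseSD,
               intensityScale = intensityScale,
               cosmicRate = cosmicRate, glassAmplitude = glassAmplitude,
               baselineDrift = baselineDrift, seed = as.integer(seed),
               library = library)
  class(spec) <- "SceneSpec"
  spec
}

#' Read a SceneSpec from YAML
#'
#' @param path YAML file with the [sceneSpec()] fields (axis given as
#'   `axis: {from, to, by}`).
#' @return A `SceneSpec` list.
#' @export
readSceneSpec <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$axis) && is.list(y$axis))
    y$axis <- seq(y$axis$from, y$axis$to, by = y$axis$by)
  args <- y[intersect(names(y), names(formals(sceneSpec)))]
  do.call(sceneSpec, args)
}

# region membership: per-pixel region index (0 = background), last wins
.regionLabels <- function(spec) {
  nr <- spec$gridShape[1L]; nc <- spec$gridShape[2L]
  lab <- matrix(0L, nr, nc)
  for (i in seq_along(spec$regions)) {
    r <- spec$regions[[i]]
    if (identical(r$shape, "ellipse")) {
      rows <- matrix(seq_len(nr) - 1L, nr, nc)
      cols <- matrix(seq_len(nc) - 1L, nr, nc, byrow = TRUE)
      inR <- ((rows - r$center[1L]) / r$radii[1L])^2 +
             ((cols - r$center[2L]) / r$radii[2L])^2 <= 1
    } else {
      inR <- matrix(FALSE, nr, nc)
      inR[r$rows[1L]:r$rows[2L] + 1L, r$cols[1L]:r$cols[2L] + 1L] <- TRUE
    }
    lab[inR] <- i
  }
  as.integer(t(lab))  # row-major vector
}

#' Generate a synthetic tissue section
#'
#' Every pixel draws its region's signature spectrum with per-pixel
#' amplitude jitter; glass background, linear baseline drift, channel noise
#' and cosmic-ray spikes are injected per the spec. Overlapping regions are
#' resolved in listed order (last wins).
#'
#' @param spec a [sceneSpec()] list.
#' @return list with `map` (a [SpectralMap-class]) and `truth` (list with
#'   `regionLabels` per pixel (0 = background), `regionSignatures`,
#'   `cosmicPixels`).
#' @export
generateSection <- function(spec) {
  stopifnot(inherits(spec, "SceneSpec"))
  set.seed(spec$seed)
  axis <- spec$axis
  n <- prod(spec$gridShape)
  lab <- .regionLabels(spec)
  sigNames <- c(spec$background,
                vapply(spec$regions, `[[`, "", "signature"))
  amps <- c(1, vapply(spec$regions, function(r)
    if (is.null(r$amplitude)) 1 else r$amplitude, 0))
  jit <- c(spec$jitterSD, vapply(spec$regions, function(r)
    if (is.null(r$jitterSD)) spec$jitterSD else r$jitterSD, 0))
  base <- lapply(sigNames, function(s)
    .signatureSpectrum(spec$library[[s]], axis))
  glass <- if (spec$glassAmplitude > 0)
    spec$glassAmplitude * .signatureSpectrum(spec$library$glass, axis)
  else numeric(length(axis))
  drift <- spec$baselineDrift * (axis - min(axis))
  X <- matrix(0, n, length(axis))
  for (i in seq_len(n)) {
    g <- lab[i] + 1L
    a <- amps[g] * max(0, 1 + stats::rnorm(1L, sd = jit[g]))
    X[i, ] <- a * base[[g]] + glass + drift +
      stats::rnorm(length(axis), sd = spec$noiseSD)
  }
  X[X < 0] <- 0
  X <- X * spec$intensityScale
  cosmic <- integer(0)
  if (spec$cosmicRate > 0) {
    nSpike <- stats::rpois(n, spec$cosmicRate)
    cosmic <- which(nSpike > 0)
    for (i in cosmic) {
      ch <- sample.int(length(axis), min(nSpike[i], length(axis)))
      X[i, ch] <- X[i, ch] +
        spec$intensityScale * stats::runif(length(ch), 20, 60)
    }
  }
  map <- SpectralMap(axis, X, spec$gridShape, pixelSize = spec$pixelSize,
                     provenance = list(list(op = "generateSection",
                                            seed = spec$seed)))
  list(map = map,
       truth = list(regionLabels = lab, regionSignatures = sigNames,
                    cosmicPixels = cosmic))
}

#' Generate a gradient scene for trajectory dynamics
#'
#' Two vertical half-scene regions: the left one static, the right one with
#' its signature amplitudes ramping linearly along the column axis,
#' modulated by patchy foci (a square wave of period `patchPeriod` pixels
#' and contrast `patchContrast`) and elevated per-pixel jitter. The patchy
#' substructure emulates crossing discrete fibrotic foci: it is what makes
#' per-pixel log2 derivatives large enough to clear the 0.4 dynamics
#' threshold, which a smooth tens-of-micrometre ramp alone cannot. The
#' planted dynamic wavenumbers are the ramped signature's band centres.
#'
#' @param gridShape `(rows, cols)` (default `c(20, 60)`).
#' @param staticSignature,rampSignature signature names (defaults
#'   `"myocardium"`, `"collagen"`).
#' @param rampFrom,rampTo amplitude multipliers at the ramp start/end
#'   (defaults 0.2, 2).
#' @param rampJitterSD jitter in the ramped region (default 0.1).
#' @param patchPeriod focal-patch half-period in pixels (default 5).
#' @param patchContrast focal amplitude contrast in the ramped region
#'   (default 0.6).
#' @param noiseSD channel noise SD, relative to unit peak amplitude
#'   (default 0.02).
#' @param intensityScale multiplier mapping the unit-amplitude peak library
#'   to detector-count-like intensities (default 100).
#' @param axis wavenumber axis (default [defaultAxis()]).
#' @param seed RNG seed (default 1).
#' @return list with `map`, `truth` (regionLabels, dynamicWavenumbers,
#'   rampColumns).
#' @export
generateGradientScene <- function(gridShape = c(20L, 60L),
                                  staticSignature = "myocardium",
                                  rampSignature = "collagen",
                                  rampFrom = 0.2, rampTo = 2,
                                  rampJitterSD = 0.1, patchPeriod = 5L,
                                  patchContrast = 0.6, noiseSD = 0.01,
                                  intensityScale = 100,
                                  axis = defaultAxis(), seed = 1L) {
  lib <- signatureLibrary()
  set.seed(seed)
  nr <- gridShape[1L]; nc <- gridShape[2L]
  half <- nc %/% 2L
  n <- nr * nc
  lab <- integer(n)
  X <- matrix(0, n, length(axis))
  baseStatic <- .signatureSpectrum(lib[[staticSignature]], axis)
  baseRamp <- .signatureSpectrum(lib[[rampSignature]], axis)
  for (i in seq_len(n)) {
    row <- (i - 1L) %/% nc; col <- (i - 1L) %% nc
    if (col < half) {
      a <- max(0, 1 + stats::rnorm(1L, sd = 0.03))
      X[i, ] <- a * baseStatic
    } else {
      lab[i] <- 1L
      frac <- (col - half) / max(nc - 1L - half, 1L)
      amp <- rampFrom + (rampTo - rampFrom) * frac
      patch <- 1 + patchContrast * (2 * (((col - half) %/% patchPeriod) %% 2L) - 1)
      a <- max(0, amp * patch * (1 + stats::rnorm(1L, sd = rampJitterSD)))
      X[i, ] <- a * baseRamp
    }
    X[i, ] <- X[i, ] + stats::rnorm(length(axis), sd = noiseSD)
  }
  X[X < 0] <- 0
  X <- X * intensityScale
  map <- SpectralMap(axis, X, gridShape,
                     provenance = list(list(op = "generateGradientScene",
                                            seed = seed)))
  list(map = map,
       truth = list(regionLabels = lab,
                    dynamicWavenumbers = lib[[rampSignature]]$center,
                    rampColumns = c(half, nc - 1L)))
}

#' Generate a paired Raman + MSI scene under a known transform
#'
#' The Raman section comes from the spec at fine resolution; the MSI map
#' lives on a coarser grid whose physical frame maps into the Raman frame
#' through the planted similarity transform. MSI intensities are derived
#' from the region identity under each transformed MSI pixel centre using
#' an independent per-region m/z feature set. Landmarks (exact point pairs
#' under the transform) are emitted for registration.
#'
#' @param spec a [sceneSpec()] (use `pixelSize = 10` for the instrument's
#'   10 um Raman pixels).
#' @param transform the planted [AffineTransform2D-class] mapping MSI
#'   physical coordinates into the Raman frame (default identity).
#' @param msiPixelSize MSI pixel edge, micrometres (default 50).
#' @param nMz number of m/z features (default 40).
#' @param msiNoiseSD MSI channel noise SD (default 0.02).
#' @param nLandmarks landmark pairs to emit (default 4).
#' @param seed RNG seed (default 1).
#' @return list with `raman` ([SpectralMap-class]), `msi` ([MSIMap-class]),
#'   `landmarks` (list src/dst), `truth` (transform, raman/msi region
#'   labels, msiRegionProfiles).
#' @export
generateMultimodalPair <- function(spec, transform = AffineTransform2D(),
                                   msiPixelSize = 50, nMz = 40L,
                                   msiNoiseSD = 0.02, nLandmarks = 4L,
                                   seed = 1L) {
  sec <- generateSection(spec)
  raman <- sec$map
  set.seed(seed + 1L)
  extent <- rev(gridShape(raman)) * pixelSize(raman)  # (x, y) um
  inv <- invertTransform(transform)
  # MSI grid sized to cover the Raman extent in the MSI frame
  cornersRaman <- rbind(c(0, 0), c(extent[1L], 0), c(0, extent[2L]), extent)
  cornersMsi <- applyTransform(inv, cornersRaman)
  msiShape <- c(ceiling(max(cornersMsi[, 2L]) / msiPixelSize),
                ceiling(max(cornersMsi[, 1L]) / msiPixelSize))
  msiShape <- pmax(msiShape, 1L)
  nRegions <- length(spec$regions) + 1L
  mz <- sort(stats::runif(nMz, 75, 1000))
  profiles <- matrix(stats::runif(nRegions * nMz, 0, 0.2), nRegions, nMz)
  for (g in seq_len(nRegions)) {
    on <- sample.int(nMz, max(3L, nMz %/% 5L))
    profiles[g, on] <- profiles[g, on] + stats::runif(length(on), 0.8, 1.5)
  }
  nMsi <- prod(msiShape)
  ramanLab <- sec$truth$regionLabels
  shapeR <- gridShape(raman)
  msiLab <- integer(nMsi)
  Xmsi <- matrix(0, nMsi, nMz)
  centersMsi <- cbind(
    ((seq_len(nMsi) - 1L) %% msiShape[2L] + 0.5) * msiPixelSize,
    ((seq_len(nMsi) - 1L) %/% msiShape[2L] + 0.5) * msiPixelSize)
  inRaman <- applyTransform(transform, centersMsi)
  for (i in seq_len(nMsi)) {
    col <- floor(inRaman[i, 1L] / pixelSize(raman))
    row <- floor(inRaman[i, 2L] / pixelSize(raman))
    g <- if (col >= 0 && col < shapeR[2L] && row >= 0 && row < shapeR[1L])
      ramanLab[row * shapeR[2L] + col + 1L] + 1L else 1L
    msiLab[i] <- g - 1L
    Xmsi[i, ] <- profiles[g, ] * max(0, 1 + stats::rnorm(1L, sd = 0.05)) +
      stats::rnorm(nMz, sd = msiNoiseSD)
  }
  Xmsi[Xmsi < 0] <- 0
  msi <- MSIMap(mz, Xmsi, msiShape, pixelSize = msiPixelSize,
                normalization = "none")
  src <- cbind(stats::runif(nLandmarks, 0, msiShape[2L] * msiPixelSize),
               stats::runif(nLandmarks, 0, msiShape[1L] * msiPixelSize))
  list(raman = raman, msi = msi,
       landmarks = list(src = src, dst = applyTransform(transform, src)),
       truth = list(transform = transform, ramanRegionLabels = ramanLab,
                    msiRegionLabels = msiLab, msiRegionProfiles = profiles))
}

#' Generate a cell-typing scene with an aligned label mask
#'
#' Circular cells of each requested type are placed (best-effort, no
#' mandatory overlap) on a background tissue; the returned label image is
#' aligned to the Raman grid. The erythrocyte signature carries the 1372
#' cm^-1 hemin band.
#'
#' @param types signature names used as cell types (default cardiomyocyte,
#'   erythrocyte, leukocyte).
#' @param cellsPerType cells per type (default 8).
#' @param cellRadius cell radius in pixels (default 3).
#' @param gridShape `(rows, cols)` (default `c(60, 60)`).
#' @param background background signature (default `"collagen"`).
#' @param noiseSD channel noise SD, relative to unit peak amplitude
#'   (default 0.02).
#' @param intensityScale multiplier mapping the unit-amplitude peak library
#'   to detector-count-like intensities (default 100).
#' @param jitterSD per-pixel amplitude jitter SD (default 0.05).
#' @param axis wavenumber axis (default [defaultAxis()]).
#' @param seed RNG seed (default 1).
#' @param maxTries placement attempts per cell (default 200).
#' @return list with `map`, `labels` (a [CellLabelImage-class]), `truth`
#'   (cell centres per type).
#' @export
generateCelltypeScene <- function(types = c("cardiomyocyte", "erythrocyte",
                                            "leukocyte"),
                                  cellsPerType = 8L, cellRadius = 3L,
                                  gridShape = c(60L, 60L),
                                  background = "collagen", noiseSD = 0.02,
                                  jitterSD = 0.05, intensityScale = 100,
                                  axis = defaultAxis(),
                                  seed = 1L, maxTries = 200L) {
  lib <- signatureLibrary()
  stopifnot(all(types %in% names(lib)))
  set.seed(seed)
  nr <- gridShape[1L]; nc <- gridShape[2L]
  lab <- matrix(0L, nr, nc)
  centres <- list()
  for (t in seq_along(types)) {
    placed <- 0L
    tries <- 0L
    cc <- matrix(NA_real_, 0L, 2L)
    while (placed < cellsPerType && tries < maxTries * cellsPerType) {
      tries <- tries + 1L
      cr <- stats::runif(1L, cellRadius, nr - 1 - cellRadius)
      ccol <- stats::runif(1L, cellRadius, nc - 1 - cellRadius)
      rows <- matrix(seq_len(nr) - 1L, nr, nc)
      cols <- matrix(seq_len(nc) - 1L, nr, nc, byrow = TRUE)
      disk <- (rows - cr)^2 + (cols - ccol)^2 <= cellRadius^2
      if (any(lab[disk] != 0L)) next
      lab[disk] <- t
      cc <- rbind(cc, c(cr, ccol))
      placed <- placed + 1L
    }
    if (placed < cellsPerType)
      message("placed ", placed, "/", cellsPerType, " cells of type ",
              types[t])
    centres[[types[t]]] <- cc
  }
  labVec <- as.integer(t(lab))  # row-major
  n <- nr * nc
  base <- lapply(c(background, types), function(s)
    .signatureSpectrum(lib[[s]], axis))
  X <- matrix(0, n, length(axis))
  for (i in seq_len(n)) {
    g <- labVec[i] + 1L
    a <- max(0, 1 + stats::rnorm(1L, sd = jitterSD))
    X[i, ] <- a * base[[g]] + stats::rnorm(length(axis), sd = noiseSD)
  }
  X[X < 0] <- 0
  X <- X * intensityScale
  map <- SpectralMap(axis, X, gridShape,
                     provenance = list(list(op = "generateCelltypeScene",
                                            seed = seed)))
  labels <- CellLabelImage(labVec, gridShape,
                           setNames(types, as.character(seq_along(types))))
  list(map = map, labels = labels, truth = list(cellCentres = centres))
}
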