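#' @import methods
#' @importFrom stats median mad prcomp p.adjust wilcox.test t.test quantile
#'   rnorm runif sd var dist cor predict setNames aggregate complete.cases
#' @importFrom utils read.table write.table head tail
#' @useDynLib spectromics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' SpectralMap: a hyperspectral Raman scan on a regular pixel grid
#'
#' The central container of the package: one Raman spectrum per pixel of a
#' rectangular scan. Intensities are stored as a pixels x channels matrix;
#' the wavenumber axis (Raman shift, cm^-1) is strictly increasing. Pixels
#' live on an `nrow x ncol` grid with a physical edge length in micrometres;
#' pixel `(row, col)` (0-based) has physical centre
#' `((col + 0.5) * pixelSize, (row + 0.5) * pixelSize)` with y increasing
#' downward. A per-pixel QC mask marks retained pixels; flagged pixels stay
#' addressable so spatial plots keep their place. The provenance list records
#' every applied operation with its parameters, append-only.
#'
#' @slot wavenumbers numeric, strictly increasing Raman shifts (cm^-1).
#' @slot intensities numeric matrix, `nPixels x nChannels`.
#' @slot gridShape integer of length 2, `(rows, cols)`.
#' @slot pixelSize numeric(1), micrometres per pixel edge.
#' @slot pixelIndex integer matrix `nPixels x 2` of 0-based `(row, col)`.
#' @slot qcMask logical per pixel; `TRUE` = retained.
#' @slot provenance list of applied operations.
#' @exportClass SpectralMap
setClass("SpectralMap",
  representation(
    wavenumbers = "numeric",
    intensities = "matrix",
    gridShape = "integer",
    pixelSize = "numeric",
    pixelIndex = "matrix",
    qcMask = "logical",
    provenance = "list"
  )
)

setValidity("SpectralMap", function(object) {
  msg <- character()
  wn <- object@wavenumbers
  if (length(wn) < 2L) msg <- c(msg, "wavenumber axis needs at least 2 channels")
  if (any(!is.finite(wn))) msg <- c(msg, "wavenumbers must be finite")
  if (any(diff(wn) <= 0)) msg <- c(msg, "wavenumbers must be strictly increasing")
  if (ncol(object@intensities) != length(wn))
    msg <- c(msg, "ncol(intensities) must equal length(wavenumbers)")
  if (length(object@gridShape) != 2L || any(object@gridShape < 1L))
    msg <- c(msg, "gridShape must be two positive integers")
  if (nrow(object@intensities) != prod(object@gridShape))
    msg <- c(msg, "nrow(intensities) must equal prod(gridShape)")
  if (!identical(dim(object@pixelIndex), c(nrow(object@intensities), 2L)))
    msg <- c(msg, "pixelIndex must be nPixels x 2")
  else {
    key <- object@pixelIndex[, 1L] * object@gridShape[2L] + object@pixelIndex[, 2L]
    if (anyDuplicated(key)) msg <- c(msg, "duplicate (row, col) in pixelIndex")
    if (any(object@pixelIndex[, 1L] < 0L | object@pixelIndex[, 1L] >= object@gridShape[1L]) ||
        any(object@pixelIndex[, 2L] < 0L | object@pixelIndex[, 2L] >= object@gridShape[2L]))
      msg <- c(msg, "pixelIndex out of grid bounds")
  }
  if (length(object@qcMask) != nrow(object@intensities))
    msg <- c(msg, "qcMask must have one entry per pixel")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Construct a SpectralMap
#'
#' @param wavenumbers strictly increasing Raman shifts (cm^-1).
#' @param intensities `nPixels x nChannels` matrix, pixels in row-major grid
#'   order unless `pixelIndex` says otherwise.
#' @param gridShape `(rows, cols)`.
#' @param pixelSize micrometres per pixel edge (default 1).
#' @param pixelIndex optional 0-based `(row, col)` per pixel; defaults to
#'   row-major order.
#' @param qcMask optional logical per pixel, default all retained.
#' @param provenance optional list of prior operations.
#' @return A [SpectralMap-class] object.
#' @export
SpectralMap <- function(wavenumbers, intensities, gridShape, pixelSize = 1,
                        pixelIndex = NULL, qcMask = NULL, provenance = list()) {
  gridShape <- as.integer(gridShape)
  intensities <- as.matrix(intensities)
  if (is.null(pixelIndex)) {
    n <- prod(gridShape)
    pixelIndex <- cbind(
      row = as.integer((seq_len(n) - 1L) %/% gridShape[2L]),
      col = as.integer((seq_len(n) - 1L) %% gridShape[2L])
    )
  }
  storage.mode(pixelIndex) <- "integer"
  if (is.null(qcMask)) qcMask <- rep(TRUE, nrow(intensities))
  new("SpectralMap",
    wavenumbers = as.numeric(wavenumbers), intensities = intensities,
    gridShape = gridShape, pixelSize = as.numeric(pixelSize),
    pixelIndex = pixelIndex, qcMask = qcMask, provenance = provenance)
}

#' MSIMap: a MALDI mass-spectrometry imaging scan
#'
#' Per-pixel mass spectra on a (coarser) regular grid: an increasing m/z axis
#' and a pixels x features intensity matrix. After RMS normalization each
#' retained spectrum has root-mean-square 1.
#'
#' @slot mzAxis numeric, increasing m/z values.
#' @slot intensities numeric matrix `nPixels x nMz`.
#' @slot gridShape integer `(rows, cols)`.
#' @slot pixelSize numeric(1), micrometres per pixel edge.
#' @slot normalization character, e.g. `"none"` or `"rms"`.
#' @exportClass MSIMap
setClass("MSIMap",
  representation(
    mzAxis = "numeric",
    intensities = "matrix",
    gridShape = "integer",
    pixelSize = "numeric",
    normalization = "character"
  )
)

setValidity("MSIMap", function(object) {
  msg <- character()
  if (length(object@mzAxis) < 1L) msg <- c(msg, "empty m/z axis")
  if (any(diff(object@mzAxis) <= 0)) msg <- c(msg, "m/z axis must be increasing")
  if (ncol(object@intensities) != length(object@mzAxis))
    msg <- c(msg, "ncol(intensities) must equal length(mzAxis)")
  if (nrow(object@intensities) != prod(object@gridShape))
    msg <- c(msg, "nrow(intensities) must equal prod(gridShape)")
  if (length(msg)) msg else TRUE
})

#' Construct an MSIMap
#' @param mzAxis increasing m/z values.
#' @param intensities `nPixels x nMz` matrix in row-major grid order.
#' @param gridShape `(rows, cols)`.
#' @param pixelSize micrometres per pixel edge (default 50).
#' @param normalization normalization record (default `"none"`).
#' @return An [MSIMap-class] object.
#' @export
MSIMap <- function(mzAxis, intensities, gridShape, pixelSize = 50,
                   normalization = "none") {
  new("MSIMap",
    mzAxis = as.numeric(mzAxis), intensities = as.matrix(intensities),
    gridShape = as.integer(gridShape), pixelSize = as.numeric(pixelSize),
    normalization = normalization)
}

#' AffineTransform2D: similarity transform between physical frames
#'
#' Maps a point `p` (micrometres) to `s * R(theta) %*% p + t`. Used to carry
#' MSI or immunofluorescence pixel centres into the Raman coordinate frame.
#'
#' @slot theta rotation angle in radians (counter-clockwise in the x-right,
#'   y-down image convention).
#' @slot scale isotropic scale factor, > 0.
#' @slot translation numeric(2), `(tx, ty)` in micrometres.
#' @exportClass AffineTransform2D
setClass("AffineTransform2D",
  representation(theta = "numeric", scale = "numeric", translation = "numeric"))

setValidity("AffineTransform2D", function(object) {
  msg <- character()
  if (length(object@scale) != 1L || !is.finite(object@scale) || object@scale <= 0)
    msg <- c(msg, "scale must be a positive scalar")
  if (length(object@theta) != 1L || !is.finite(object@theta))
    msg <- c(msg, "theta must be a finite scalar")
  if (length(object@translation) != 2L || any(!is.finite(object@translation)))
    msg <- c(msg, "translation must be two finite numbers")
  if (length(msg)) msg else TRUE
})

#' Construct an AffineTransform2D
#' @param theta rotation in radians.
#' @param scale isotropic scale (> 0).
#' @param translation `(tx, ty)` in micrometres.
#' @return An [AffineTransform2D-class] object.
#' @export
AffineTransform2D <- function(theta = 0, scale = 1, translation = c(0, 0)) {
  new("AffineTransform2D", theta = as.numeric(theta), scale = as.numeric(scale),
      translation = as.numeric(translation))
}

#' Embedding: low-dimensional representation of retained pixel spectra
#'
#' @slot scores matrix `nRetainedPixels x nDims`.
#' @slot loadings matrix `nChannels x nDims` (orthonormal columns for PCA).
#' @slot explainedVariance per-dimension fraction of total variance,
#'   non-increasing, summing to at most 1.
#' @slot center per-channel centering values used.
#' @slot scaling per-channel scale values used (1s if unscaled).
#' @slot pixels integer indices (1-based, into the map's pixel rows) of the
#'   retained pixels the score rows refer to.
#' @slot method character, e.g. `"pca"`.
#' @exportClass Embedding
setClass("Embedding",
  representation(
    scores = "matrix", loadings = "matrix", explainedVariance = "numeric",
    center = "numeric", scaling = "numeric", pixels = "integer",
    method = "character"
  )
)

setValidity("Embedding", function(object) {
  msg <- character()
  if (nrow(object@scores) != length(object@pixels))
    msg <- c(msg, "one score row per retained pixel required")
  ev <- object@explainedVariance
  if (length(ev) && (any(diff(ev) > 1e-8) || sum(ev) > 1 + 1e-8))
    msg <- c(msg, "explainedVariance must be non-increasing and sum to <= 1")
  if (length(msg)) msg else TRUE
})

#' ClusterLabels: per-pixel integer cluster assignments with provenance
#'
#' Labels are dense in `0..k-1` and ordered by descending cluster size
#' (label 0 is the largest cluster). One label per retained pixel; the
#' `pixels` slot records which map rows the labels refer to.
#'
#' @slot labels integer vector of labels in `0..k-1`.
#' @slot k number of clusters.
#' @slot pixels integer indices of the labelled (retained) pixels.
#' @slot method character, the producing method.
#' @slot params list of parameters used.
#' @slot seed integer seed used, if any.
#' @exportClass ClusterLabels
setClass("ClusterLabels",
  representation(labels = "integer", k = "integer", pixels = "integer",
                 method = "character", params = "list", seed = "integer"))

setValidity("ClusterLabels", function(object) {
  msg <- character()
  if (length(object@labels) != length(object@pixels))
    msg <- c(msg, "one label per pixel required")
  if (length(object@labels)) {
    u <- sort(unique(object@labels))
    if (!identical(u, seq(0L, object@k - 1L)))
      msg <- c(msg, "labels must be dense in 0..k-1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct ClusterLabels (relabelled dense, size-ordered)
#'
#' Any integer labelling is accepted; labels are re-coded to `0..k-1` in
#' order of descending cluster size (ties by first appearance).
#'
#' @param labels integer-like cluster ids, one per retained pixel.
#' @param pixels 1-based indices of the labelled pixels in the parent map.
#' @param method name of the producing method.
#' @param params parameter list.
#' @param seed RNG seed used (or `NA`).
#' @return A [ClusterLabels-class] object.
#' @export
ClusterLabels <- function(labels, pixels, method = "manual", params = list(),
                          seed = NA_integer_) {
  labels <- as.integer(labels)
  tab <- sort(table(labels), decreasing = TRUE)
  recode <- setNames(seq_along(tab) - 1L, names(tab))
  dense <- unname(recode[as.character(labels)])
  new("ClusterLabels", labels = as.integer(dense), k = length(tab),
      pixels = as.integer(pixels), method = method, params = params,
      seed = as.integer(seed))
}

#' GridGraph: neighbourhood structure of the pixel lattice
#'
#' @slot shape integer `(rows, cols)`.
#' @slot connectivity 4 (orthogonal) or 8 (orthogonal + diagonal).
#' @slot neighbors list of integer vectors; `neighbors[[i]]` holds the
#'   1-based pixel indices adjacent to pixel `i` (row-major order).
#' @exportClass GridGraph
setClass("GridGraph",
  representation(shape = "integer", connectivity = "integer",
                 neighbors = "list"))

#' PrincipalTree: pseudotime tree in embedding space
#'
#' @slot nodePositions matrix `nNodes x nDims` of latent node coordinates.
#' @slot edges integer matrix `nEdges x 2` of tree edges (node indices).
#' @slot nodeAssignment integer per pixel: hard assignment to nearest node.
#' @slot root integer, root node index.
#' @slot pseudotime numeric per pixel: geodesic distance of its node from
#'   the root along the tree.
#' @slot branchPoints integer node indices with degree >= 3.
#' @slot pixels integer indices of the embedded pixels.
#' @exportClass PrincipalTree
setClass("PrincipalTree",
  representation(nodePositions = "matrix", edges = "matrix",
                 nodeAssignment = "integer", root = "integer",
                 pseudotime = "numeric", branchPoints = "integer",
                 pixels = "integer"))

setValidity("PrincipalTree", function(object) {
  msg <- character()
  m <- nrow(object@nodePositions)
  if (nrow(object@edges) != m - 1L)
    msg <- c(msg, "a tree on m nodes must have m-1 edges")
  if (any(object@pseudotime < 0)) msg <- c(msg, "pseudotime must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Trajectory: straight-line path across the pixel grid
#'
#' Pixels are the Bresenham rasterization of the segment from `start` to
#' `end` (inclusive); consecutive pixels are 8-connected and unique.
#' `distance` is the cumulative Euclidean distance between successive pixel
#' centres in micrometres.
#'
#' @slot start integer `(row, col)`, 0-based.
#' @slot end integer `(row, col)`, 0-based.
#' @slot pixels integer matrix `nPositions x 2` of 0-based `(row, col)`.
#' @slot distance numeric, cumulative distance (micrometres), starts at 0.
#' @exportClass Trajectory
setClass("Trajectory",
  representation(start = "integer", end = "integer", pixels = "matrix",
                 distance = "numeric"))

setValidity("Trajectory", function(object) {
  msg <- character()
  if (any(diff(object@distance) < 0)) msg <- c(msg, "distance must be non-decreasing")
  if (nrow(object@pixels) != length(object@distance))
    msg <- c(msg, "one cumulative distance per pixel required")
  key <- paste(object@pixels[, 1L], object@pixels[, 2L])
  if (anyDuplicated(key)) msg <- c(msg, "trajectory pixels must be unique")
  if (length(msg)) msg else TRUE
})

#' TrajectoryProfile: per-wavenumber intensity dynamics along a trajectory
#'
#' For each wavenumber the series is `log2((I + eps) / (mean I + eps))` with
#' the mean taken over the trajectory (eps = 1), plus a loess fit and a
#' pointwise 0.95 confidence band.
#'
#' @slot trajectory the [Trajectory-class] profiled.
#' @slot wavenumbers channels profiled.
#' @slot series matrix `nPositions x nChannels` of log2-normalized series.
#' @slot fitted matrix of loess fits, same shape as `series`.
#' @slot ciLower,ciUpper matrices bounding the 0.95 confidence band.
#' @slot clusterAt integer per position: cluster label at that pixel (NA if
#'   unlabelled).
#' @slot positions numeric, distance (micrometres) of each retained position.
#' @exportClass TrajectoryProfile
setClass("TrajectoryProfile",
  representation(trajectory = "Trajectory", wavenumbers = "numeric",
                 series = "matrix", fitted = "matrix", ciLower = "matrix",
                 ciUpper = "matrix", clusterAt = "integer",
                 positions = "numeric"))

#' CellLabelImage: per-pixel cell-type annotations aligned to a Raman grid
#'
#' @slot labels integer per pixel: 0 = background, otherwise an id in the
#'   legend. Row-major grid order.
#' @slot gridShape integer `(rows, cols)`, equal to the Raman map's.
#' @slot legend named character: `names()` are the ids (as characters),
#'   values the cell-type names.
#' @exportClass CellLabelImage
setClass("CellLabelImage",
  representation(labels = "integer", gridShape = "integer",
                 legend = "character"))

setValidity("CellLabelImage", function(object) {
  msg <- character()
  if (length(object@labels) != prod(object@gridShape))
    msg <- c(msg, "labels must cover the full grid")
  ids <- setdiff(unique(object@labels), 0L)
  if (!all(as.character(ids) %in% names(object@legend)))
    msg <- c(msg, "all non-background ids must appear in the legend")
  if (length(msg)) msg else TRUE
})

#' Construct a CellLabelImage
#' @param labels integer per pixel (0 = background), row-major.
#' @param gridShape `(rows, cols)`.
#' @param legend named character mapping id -> type name.
#' @return A [CellLabelImage-class] object.
#' @export
CellLabelImage <- function(labels, gridShape, legend) {
  new("CellLabelImage", labels = as.integer(labels),
      gridShape = as.integer(gridShape), legend = legend)
}

#' ReferenceSpectrumSet: per-cell-type mean reference spectra
#'
#' @slot spectra matrix `nTypes x nChannels`, each row unit L2 norm.
#' @slot wavenumbers channel axis.
#' @slot nPixels integer per type: contributing pixel count.
#' @exportClass ReferenceSpectrumSet
setClass("ReferenceSpectrumSet",
  representation(spectra = "matrix", wavenumbers = "numeric",
                 nPixels = "integer"))

setValidity("ReferenceSpectrumSet", function(object) {
  msg <- character()
  if (ncol(object@spectra) != length(object@wavenumbers))
    msg <- c(msg, "spectra width must equal wavenumber axis length")
  if (nrow(object@spectra) != length(object@nPixels))
    msg <- c(msg, "one pixel count per reference spectrum required")
  if (length(msg)) msg else TRUE
})
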