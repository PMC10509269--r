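#' Accessor generics
#'
#' Standard accessors for the package's S4 containers.
#'
#' @param x an object.
#' @param value replacement value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("pixelIndex", function(x) standardGeneric("pixelIndex"))

#' @rdname accessors
#' @export
setGeneric("qcMask", function(x) standardGeneric("qcMask"))

#' @rdname accessors
#' @export
setGeneric("qcMask<-", function(x, value) standardGeneric("qcMask<-"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("nPixels", function(x) standardGeneric("nPixels"))

#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("mzAxis", function(x) standardGeneric("mzAxis"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("embeddingScores", function(x) standardGeneric("embeddingScores"))

#' @rdname accessors
#' @export
setGeneric("pseudotime", function(x) standardGeneric("pseudotime"))

#' @rdname accessors
#' @export
setGeneric("branchPoints", function(x) standardGeneric("branchPoints"))

#' Apply a 2-D similarity transform to points
#'
#' @param transform an [AffineTransform2D-class].
#' @param points numeric matrix `n x 2` of `(x, y)` coordinates in
#'   micrometres (a length-2 vector is treated as one point).
#' @return Transformed coordinates, same shape as the input.
#' @export
setGeneric("applyTransform", function(transform, points)
  standardGeneric("applyTransform"))

#' Invert a 2-D similarity transform
#' @param transform an [AffineTransform2D-class].
#' @return The inverse [AffineTransform2D-class].
#' @export
setGeneric("invertTransform", function(transform)
  standardGeneric("invertTransform"))
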