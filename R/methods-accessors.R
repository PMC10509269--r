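# Accessors and show() methods for the S4 containers.

#' @rdname accessors
#' @aliases wavenumbers,SpectralMap-method
setMethod("wavenumbers", "SpectralMap", function(x) x@wavenumbers)

#' @rdname accessors
setMethod("wavenumbers", "ReferenceSpectrumSet", function(x) x@wavenumbers)

#' @rdname accessors
setMethod("intensities", "SpectralMap", function(x) x@intensities)

#' @rdname accessors
setMethod("intensities", "MSIMap", function(x) x@intensities)

#' @rdname accessors
setMethod("gridShape", "SpectralMap", function(x) x@gridShape)

#' @rdname accessors
setMethod("gridShape", "MSIMap", function(x) x@gridShape)

#' @rdname accessors
setMethod("gridShape", "CellLabelImage", function(x) x@gridShape)

#' @rdname accessors
setMethod("pixelSize", "SpectralMap", function(x) x@pixelSize)

#' @rdname accessors
setMethod("pixelSize", "MSIMap", function(x) x@pixelSize)

#' @rdname accessors
setMethod("pixelIndex", "SpectralMap", function(x) x@pixelIndex)

#' @rdname accessors
setMethod("qcMask", "SpectralMap", function(x) x@qcMask)

#' @rdname accessors
setReplaceMethod("qcMask", "SpectralMap", function(x, value) {
  x@qcMask <- as.logical(value)
  validObject(x)
  x
})

#' @rdname accessors
setMethod("provenance", "SpectralMap", function(x) x@provenance)

#' @rdname accessors
setMethod("nPixels", "SpectralMap", function(x) nrow(x@intensities))

#' @rdname accessors
setMethod("nPixels", "MSIMap", function(x) nrow(x@intensities))

#' @rdname accessors
setMethod("nChannels", "SpectralMap", function(x) ncol(x@intensities))

#' @rdname accessors
setMethod("mzAxis", "MSIMap", function(x) x@mzAxis)

#' @rdname accessors
setMethod("clusterLabels", "ClusterLabels", function(x) x@labels)

#' @rdname accessors
setMethod("clusterLabels", "CellLabelImage", function(x) x@labels)

#' @rdname accessors
setMethod("embeddingScores", "Embedding", function(x) x@scores)

#' @rdname accessors
setMethod("pseudotime", "PrincipalTree", function(x) x@pseudotime)

#' @rdname accessors
setMethod("branchPoints", "PrincipalTree", function(x) x@branchPoints)

# internal: append a provenance record
.addProvenance <- function(map, op, params) {
  map@provenance <- c(map@provenance, list(c(list(op = op), params)))
  map
}

#' Physical pixel-centre coordinates
#'
#' Centre of pixel `(row, col)` is `((col + 0.5) * pixelSize,
#' (row + 0.5) * pixelSize)` micrometres, y increasing downward.
#'
#' @param x a [SpectralMap-class] or [MSIMap-class].
#' @return numeric matrix `nPixels x 2` of `(x, y)` centres in micrometres.
#' @export
pixelCenters <- function(x) {
  if (is(x, "SpectralMap")) {
    idx <- x@pixelIndex
  } else {
    shape <- gridShape(x)
    n <- prod(shape)
    idx <- cbind((seq_len(n) - 1L) %/% shape[2L], (seq_len(n) - 1L) %% shape[2L])
  }
  ps <- pixelSize(x)
  cbind(x = (idx[, 2L] + 0.5) * ps, y = (idx[, 1L] + 0.5) * ps)
}

setMethod("show", "SpectralMap", function(object) {
  cat("SpectralMap:", nrow(object@intensities), "pixels x",
      ncol(object@intensities), "channels\n")
  cat("  grid:", object@gridShape[1L], "x", object@gridShape[2L],
      sprintf("at %g um/px", object@pixelSize), "\n")
  cat(sprintf("  wavenumbers: %.1f-%.1f cm-1\n",
              min(object@wavenumbers), max(object@wavenumbers)))
  cat("  retained pixels:", sum(object@qcMask), "/", length(object@qcMask), "\n")
  if (length(object@provenance))
    cat("  provenance:", paste(vapply(object@provenance, `[[`, "", "op"),
                               collapse = " -> "), "\n")
})

setMethod("show", "MSIMap", function(object) {
  cat("MSIMap:", nrow(object@intensities), "pixels x",
      ncol(object@intensities), "m/z features\n")
  cat("  grid:", object@gridShape[1L], "x", object@gridShape[2L],
      sprintf("at %g um/px", object@pixelSize), "\n")
  cat(sprintf("  m/z: %.4f-%.4f; normalization: %s\n",
              min(object@mzAxis), max(object@mzAxis), object@normalization))
})

setMethod("show", "AffineTransform2D", function(object) {
  cat(sprintf("AffineTransform2D: theta=%.6g rad, scale=%.6g, t=(%.6g, %.6g) um\n",
              object@theta, object@scale,
              object@translation[1L], object@translation[2L]))
})

setMethod("show", "Embedding", function(object) {
  cat("Embedding (", object@method, "): ", nrow(object@scores), " pixels x ",
      ncol(object@scores), " dims\n", sep = "")
})

setMethod("show", "ClusterLabels", function(object) {
  cat("ClusterLabels:", length(object@labels), "pixels,", object@k,
      "clusters (method:", object@method, ")\n")
  print(table(object@labels))
})

setMethod("show", "PrincipalTree", function(object) {
  cat("PrincipalTree:", nrow(object@nodePositions), "nodes,",
      length(object@branchPoints), "branch point(s), root node",
      object@root, "\n")
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: (%d,%d) -> (%d,%d), %d pixels, %.1f um\n",
              object@start[1L], object@start[2L], object@end[1L],
              object@end[2L], nrow(object@pixels), max(object@distance)))
})

setMethod("show", "CellLabelImage", function(object) {
  cat("CellLabelImage:", object@gridShape[1L], "x", object@gridShape[2L],
      "with", length(object@legend), "types\n")
})

setMethod("show", "ReferenceSpectrumSet", function(object) {
  cat("ReferenceSpectrumSet:", nrow(object@spectra), "types x",
      ncol(object@spectra), "channels\n")
})
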