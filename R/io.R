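# I/O for the Raman TSV dialect and the small exchange formats.
#
# Raman TSV dialect: UTF-8, tab-separated; header row `wavenumber_cm-1`
# followed by pixel columns named `x{col}_y{row}` (0-based); one row per
# spectral channel; decimal point `.`, no thousands separators. An optional
# JSON sidecar (`<path>.meta.json`) carries pixel_size_um and grid_shape.

#' Read a Raman scan from the TSV dialect
#'
#' The file stores channels as rows and pixels as columns (a 300x300 scan
#' with 692 channels is 692 rows by 90,000 pixel columns). Grid shape is
#' reconstructed from the `x{col}_y{row}` column names; the sidecar JSON, if
#' present, supplies the physical pixel size.
#'
#' @param path TSV file path.
#' @param pixelSize micrometres per pixel edge; overrides the sidecar.
#'   Default 1 when no sidecar is present.
#' @return A [SpectralMap-class].
#' @export
readRamanMatrix <- function(path, pixelSize = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "numeric")
  if (ncol(tab) < 2L)
    stop("Raman TSV needs a wavenumber column plus at least one pixel column")
  if (!identical(names(tab)[1L], "wavenumber_cm-1"))
    stop("first column must be named 'wavenumber_cm-1'")
  wn <- tab[[1L]]
  if (any(!is.finite(wn)) || any(diff(wn) <= 0))
    stop("wavenumber column must be finite and strictly increasing")
  pixNames <- names(tab)[-1L]
  m <- regmatches(pixNames, regexec("^x([0-9]+)_y([0-9]+)$", pixNames))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("malformed pixel column name(s): ", paste(head(pixNames[bad], 3L), collapse = ", "))
  col <- vapply(m, function(z) as.integer(z[2L]), 1L)
  row <- vapply(m, function(z) as.integer(z[3L]), 1L)
  shape <- c(max(row) + 1L, max(col) + 1L)
  key <- row * shape[2L] + col
  if (anyDuplicated(key)) stop("duplicate pixel coordinates in header")
  if (length(key) != prod(shape))
    stop("missing pixel coordinates: expected ", prod(shape), " pixels, found ",
         length(key))
  # reorder pixels row-major
  ord <- order(key)
  inten <- t(as.matrix(tab[, -1L, drop = FALSE]))[ord, , drop = FALSE]
  dimnames(inten) <- NULL
  ps <- pixelSize
  sidecar <- paste0(path, ".meta.json")
  if (is.null(ps) && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    ps <- meta$pixel_size_um
  }
  if (is.null(ps)) ps <- 1
  SpectralMap(wn, inten, shape, pixelSize = ps,
              provenance = list(list(op = "read", path = path)))
}

#' Write a Raman scan in the TSV dialect
#'
#' @param map a [SpectralMap-class].
#' @param path output TSV path; a `<path>.meta.json` sidecar with
#'   `pixel_size_um` and `grid_shape` is written alongside.
#' @return `path`, invisibly.
#' @export
writeRamanMatrix <- function(map, path) {
  idx <- pixelIndex(map)
  key <- idx[, 1L] * gridShape(map)[2L] + idx[, 2L]
  ord <- order(key)
  inten <- t(intensities(map)[ord, , drop = FALSE])
  cols <- sprintf("x%d_y%d", idx[ord, 2L], idx[ord, 1L])
  df <- data.frame(wavenumbers(map), inten, check.names = FALSE)
  names(df) <- c("wavenumber_cm-1", cols)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(pixel_size_um = pixelSize(map), grid_shape = gridShape(map)),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export / import the per-pixel QC mask as CSV (row, col, retained)
#'
#' @param map a [SpectralMap-class].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeQCMask <- function(map, path) {
  idx <- pixelIndex(map)
  utils::write.table(
    data.frame(row = idx[, 1L], col = idx[, 2L], retained = qcMask(map)),
    path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export cluster labels as CSV (row, col, label)
#'
#' @param labels a [ClusterLabels-class].
#' @param map the parent [SpectralMap-class] (for pixel coordinates).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeClusterCSV <- function(labels, map, path) {
  idx <- pixelIndex(map)[labels@pixels, , drop = FALSE]
  utils::write.table(
    data.frame(row = idx[, 1L], col = idx[, 2L], label = labels@labels),
    path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cluster labels from CSV (row, col, label)
#'
#' @param path CSV path.
#' @param gridShape `(rows, cols)` of the underlying grid; inferred from the
#'   maximum coordinates when omitted.
#' @return A [ClusterLabels-class]; `pixels` are row-major indices.
#' @export
readClusterCSV <- function(path, gridShape = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = ",")
  if (is.null(gridShape)) gridShape <- c(max(df$row) + 1L, max(df$col) + 1L)
  pix <- df$row * gridShape[2L] + df$col + 1L
  ClusterLabels(df$label, pix, method = "file", params = list(path = path))
}

#' Render a cluster labelling as an indexed PNG with a JSON palette
#'
#' Unlabelled (QC-dropped) pixels are black; clusters cycle through a fixed
#' qualitative palette stored next to the image.
#'
#' @param labels a [ClusterLabels-class].
#' @param map the parent [SpectralMap-class].
#' @param path PNG path; `<path>.palette.json` is written alongside.
#' @return `path`, invisibly.
#' @export
writeLabelImage <- function(labels, map, path) {
  shape <- gridShape(map)
  base <- c("#e41a1c", "#377eb8", "#4daf4a", "#984ea3", "#ff7f00",
            "#ffff33", "#a65628", "#f781bf", "#999999", "#66c2a5",
            "#fc8d62", "#8da0cb")
  pal <- rep(base, length.out = max(1L, labels@k))
  img <- array(0, dim = c(shape[1L], shape[2L], 3L))
  idx <- pixelIndex(map)[labels@pixels, , drop = FALSE]
  rgb <- t(grDevices::col2rgb(pal[labels@labels + 1L])) / 255
  for (ch in 1:3)
    img[cbind(idx[, 1L] + 1L, idx[, 2L] + 1L, ch)] <- rgb[, ch]
  png::writePNG(img, path)
  jsonlite::write_json(
    list(palette = as.list(setNames(pal[seq_len(labels@k)],
                                    as.character(seq_len(labels@k) - 1L)))),
    paste0(path, ".palette.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read landmark coordinate pairs from CSV
#'
#' Columns: `src_x, src_y, dst_x, dst_y` in micrometres.
#'
#' @param path CSV path.
#' @return list with matrices `src` and `dst` (`n x 2`).
#' @export
readLandmarks <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",")
  need <- c("src_x", "src_y", "dst_x", "dst_y")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns ", paste(need, collapse = ", "))
  list(src = cbind(df$src_x, df$src_y), dst = cbind(df$dst_x, df$dst_y))
}

#' Write / read an AffineTransform2D as JSON
#'
#' JSON keys: `theta_rad`, `scale`, `tx_um`, `ty_um`.
#'
#' @param transform an [AffineTransform2D-class].
#' @param path JSON path.
#' @return `path` (write) or the transform (read).
#' @export
writeTransformJSON <- function(transform, path) {
  jsonlite::write_json(
    list(theta_rad = transform@theta, scale = transform@scale,
         tx_um = transform@translation[1L], ty_um = transform@translation[2L]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTransformJSON
#' @export
readTransformJSON <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  AffineTransform2D(theta = j$theta_rad, scale = j$scale,
                    translation = c(j$tx_um, j$ty_um))
}

#' Read / write a CellLabelImage as indexed PNG + JSON legend
#'
#' The PNG stores `id / 255` grey values; the legend JSON maps ids to type
#' names.
#'
#' @param image a [CellLabelImage-class].
#' @param path PNG path; legend at `<path>.legend.json`.
#' @return `path` (write) or a [CellLabelImage-class] (read).
#' @export
writeCellLabelImage <- function(image, path) {
  shape <- gridShape(image)
  img <- matrix(image@labels / 255, nrow = shape[1L], ncol = shape[2L],
                byrow = TRUE)
  png::writePNG(img, path)
  jsonlite::write_json(as.list(image@legend), paste0(path, ".legend.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeCellLabelImage
#' @export
readCellLabelImage <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  labels <- as.integer(round(t(img) * 255))  # t(): row-major vector
  legend <- unlist(jsonlite::read_json(paste0(path, ".legend.json"),
                                       simplifyVector = TRUE))
  CellLabelImage(labels, dim(img), legend)
}
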