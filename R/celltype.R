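# Reference-spectrum cell typing: align immunofluorescence label masks to
# the Raman frame, build per-type reference spectra, match pixels by
# spectral similarity, and score sensitivity/specificity.

#' Single-channel intensity image for landmark picking
#'
#' Renders the intensities at the channel nearest to the requested
#' wavenumber as a `rows x cols` image; the hemin band at 1372 cm^-1 is the
#' usual erythrocyte landmark.
#'
#' @param map a [SpectralMap-class].
#' @param wavenumber requested Raman shift, cm^-1 (nearest channel used).
#' @return matrix `rows x cols` with attribute `wavenumber` recording the
#'   channel actually used.
#' @export
renderLandmarkImage <- function(map, wavenumber = 1372) {
  wn <- wavenumbers(map)
  j <- which.min(abs(wn - wavenumber))
  shape <- gridShape(map)
  img <- matrix(NA_real_, shape[1L], shape[2L])
  idx <- pixelIndex(map)
  img[cbind(idx[, 1L] + 1L, idx[, 2L] + 1L)] <- intensities(map)[, j]
  attr(img, "wavenumber") <- wn[j]
  img
}

#' Extract labelled pixel spectra per cell type
#'
#' Background (id 0) and QC-failed pixels are excluded; the per-type counts
#' are reported. Types with 0 retained pixels are omitted with a warning.
#'
#' @param map a [SpectralMap-class].
#' @param labels a [CellLabelImage-class] aligned to the map's grid.
#' @return named list of `nPixels x nChannels` matrices, one per type name.
#' @export
extractLabeledSpectra <- function(map, labels) {
  if (!identical(gridShape(map), gridShape(labels)))
    stop("label image grid must equal the Raman grid")
  shape <- gridShape(map)
  idx <- pixelIndex(map)
  rowMajor <- idx[, 1L] * shape[2L] + idx[, 2L] + 1L
  lab <- labels@labels[rowMajor]           # label per map pixel row
  keep <- qcMask(map) & lab != 0L
  out <- list()
  for (id in names(labels@legend)) {
    sel <- keep & lab == as.integer(id)
    if (!any(sel)) {
      warning("type '", labels@legend[[id]], "' has no retained pixels; omitted")
      next
    }
    out[[labels@legend[[id]]]] <- intensities(map)[sel, , drop = FALSE]
  }
  out
}

#' Build per-type reference spectra
#'
#' Each contributing spectrum is vector-normalized (unit L2), the per-type
#' mean taken, and the mean re-normalized to unit L2.
#'
#' @param collections named list from [extractLabeledSpectra()].
#' @param wavenumbers the channel axis the spectra live on.
#' @return A [ReferenceSpectrumSet-class].
#' @export
buildReferenceSpectra <- function(collections, wavenumbers) {
  if (!length(collections)) stop("need at least one type")
  refs <- t(vapply(collections, function(M) {
    nrm <- sqrt(rowSums(M^2))
    nrm[nrm == 0] <- 1
    m <- colMeans(M / nrm)
    m / sqrt(sum(m^2))
  }, numeric(length(wavenumbers))))
  new("ReferenceSpectrumSet", spectra = refs,
      wavenumbers = as.numeric(wavenumbers),
      nPixels = vapply(collections, nrow, 1L))
}

#' Match pixels to reference spectra by spectral similarity
#'
#' Per retained pixel, the best type is the argmax similarity over the
#' reference set; the pixel is assigned iff the score reaches the
#' threshold. Pearson correlation (scale-invariant) is the default metric;
#' constant pixel spectra are undefined under Pearson and stay unassigned.
#' Exact similarity ties are broken by reference order with a warning.
#'
#' @param map a [SpectralMap-class].
#' @param refs a [ReferenceSpectrumSet-class] on the same channel axis.
#' @param metric `"pearson"` (default) or `"cosine"`.
#' @param threshold minimum score for assignment (default 0.7).
#' @return data.frame with pixel (map row index), type (name or NA),
#'   score, assigned.
#' @export
matchCells <- function(map, refs, metric = c("pearson", "cosine"),
                       threshold = 0.7) {
  metric <- match.arg(metric)
  if (!nrow(refs@spectra)) stop("empty reference set")
  if (ncol(refs@spectra) != nChannels(map))
    stop("reference spectra and map are on different channel axes")
  rm <- retainedMatrix(map)
  X <- rm$matrix
  R <- refs@spectra
  if (metric == "cosine") {
    nX <- sqrt(rowSums(X^2)); nX[nX == 0] <- 1
    S <- (X / nX) %*% t(R / sqrt(rowSums(R^2)))
  } else {
    S <- suppressWarnings(stats::cor(t(X), t(R)))  # NA for constant pixels
  }
  best <- max.col(replace(S, is.na(S), -Inf), ties.method = "first")
  ties <- apply(S, 1L, function(r) sum(r == max(r), na.rm = TRUE) > 1L)
  if (any(ties, na.rm = TRUE))
    warning(sum(ties, na.rm = TRUE),
            " pixel(s) with tied similarity; first reference kept")
  score <- S[cbind(seq_len(nrow(S)), best)]
  assigned <- !is.na(score) & score >= threshold
  data.frame(pixel = rm$pixels,
             type = ifelse(assigned, rownames(R)[best], NA_character_),
             score = score, assigned = assigned,
             stringsAsFactors = FALSE)
}

#' Sensitivity and specificity of cell calls against a label mask
#'
#' One-vs-rest confusion per type, restricted to labelled pixels (ground
#' truth exists only where immunolabels exist). Types absent from the
#' truth get `NA` sensitivity.
#'
#' @param calls a [matchCells()] data.frame.
#' @param truth a [CellLabelImage-class].
#' @param map the parent [SpectralMap-class] (for grid coordinates).
#' @return data.frame per type: TP, FP, TN, FN, sensitivity, specificity.
#' @export
evaluateSensSpec <- function(calls, truth, map) {
  if (!identical(gridShape(map), gridShape(truth)))
    stop("truth grid must equal the Raman grid")
  shape <- gridShape(map)
  idx <- pixelIndex(map)
  rowMajor <- idx[, 1L] * shape[2L] + idx[, 2L] + 1L
  truthLab <- truth@labels[rowMajor]       # per map pixel row
  m <- match(calls$pixel, seq_len(nPixels(map)))
  tl <- truthLab[calls$pixel]
  labelled <- tl != 0L
  tlName <- rep(NA_character_, length(tl))
  tlName[labelled] <- truth@legend[as.character(tl[labelled])]
  callType <- calls$type
  types <- unname(truth@legend)
  out <- do.call(rbind, lapply(types, function(ty) {
    inTruth <- labelled & tlName == ty
    called <- labelled & !is.na(callType) & callType == ty
    TP <- sum(inTruth & called)
    FN <- sum(inTruth & !called)
    FP <- sum(!inTruth & labelled & called)
    TN <- sum(!inTruth & labelled & !called)
    data.frame(type = ty, TP = TP, FP = FP, TN = TN, FN = FN,
               sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
               specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
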