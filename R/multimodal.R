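# Raman-MALDI fusion: landmark similarity-transform registration,
# cross-resolution pixel-centre correspondence, imzML I/O with RMS
# normalization and ppm binning, weighted nearest-neighbour integration,
# and paired volcano / standardized-mean-difference statistics.

#' @rdname applyTransform
setMethod("applyTransform", "AffineTransform2D", function(transform, points) {
  p <- if (is.null(dim(points))) matrix(points, 1L) else as.matrix(points)
  R <- matrix(c(cos(transform@theta), sin(transform@theta),
                -sin(transform@theta), cos(transform@theta)), 2L, 2L)
  out <- transform@scale * p %*% t(R)
  out[, 1L] <- out[, 1L] + transform@translation[1L]
  out[, 2L] <- out[, 2L] + transform@translation[2L]
  if (is.null(dim(points))) drop(out) else out
})

#' @rdname invertTransform
setMethod("invertTransform", "AffineTransform2D", function(transform) {
  s <- 1 / transform@scale
  th <- -transform@theta
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  t2 <- -s * drop(R %*% transform@translation)
  AffineTransform2D(theta = th, scale = s, translation = t2)
})

#' Compose two similarity transforms (first `a`, then `b`)
#'
#' @param a,b [AffineTransform2D-class] objects.
#' @return The composite transform `p -> b(a(p))`.
#' @export
composeTransforms <- function(b, a) {
  th <- a@theta + b@theta
  s <- a@scale * b@scale
  t2 <- applyTransform(b, a@translation)
  AffineTransform2D(theta = th, scale = s, translation = t2)
}

#' Least-squares similarity transform from landmark pairs
#'
#' Closed-form (SVD-based) fit of rotation, isotropic scale and translation
#' minimizing the summed squared residuals `||dst - (s R src + t)||^2`.
#' Needs at least 2 non-coincident pairs.
#'
#' @param src,dst numeric `n x 2` matrices of matched landmark coordinates
#'   (micrometres), source and destination frames.
#' @return list with `transform` (an [AffineTransform2D-class]) and
#'   `rmsResidual` (micrometres).
#' @export
estimateSimilarityTransform <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) < 2L || nrow(dst) != nrow(src))
    stop("need at least 2 matched landmark pairs")
  if (max(dist(src)) == 0) stop("source landmarks are coincident")
  mx <- colMeans(src); my <- colMeans(dst)
  Xc <- sweep(src, 2L, mx); Yc <- sweep(dst, 2L, my)
  A <- t(Yc) %*% Xc
  sv <- svd(A)
  S <- diag(c(1, sign(det(sv$u %*% t(sv$v)))))
  R <- sv$u %*% S %*% t(sv$v)
  s <- sum(diag(S) * sv$d) / sum(Xc^2)
  t2 <- my - s * drop(R %*% mx)
  th <- atan2(R[2L, 1L], R[1L, 1L])
  tr <- AffineTransform2D(theta = th, scale = s, translation = t2)
  fit <- applyTransform(tr, src)
  list(transform = tr,
       rmsResidual = sqrt(mean(rowSums((dst - fit)^2))))
}

#' Pixel-centre correspondence between an MSI and a Raman grid
#'
#' Each MSI pixel centre is carried through the transform into the Raman
#' frame and matched to the Raman pixel whose centre is nearest; centres
#' landing farther than half a Raman pixel from any centre (out of bounds)
#' are listed unmatched.
#'
#' @param transform [AffineTransform2D-class] mapping MSI physical
#'   coordinates into the Raman frame.
#' @param msi an [MSIMap-class].
#' @param raman a [SpectralMap-class].
#' @return list with `pairs` (data.frame msi_pixel, raman_pixel; 1-based
#'   row-major indices) and `unmatched` (MSI pixel indices).
#' @export
mapPixelCenters <- function(transform, msi, raman) {
  centers <- applyTransform(transform, pixelCenters(msi))
  ps <- pixelSize(raman)
  shape <- gridShape(raman)
  col <- floor(centers[, 1L] / ps)
  row <- floor(centers[, 2L] / ps)
  inside <- col >= 0 & col < shape[2L] & row >= 0 & row < shape[1L]
  ramanPix <- rep(NA_integer_, nrow(centers))
  idx <- pixelIndex(raman)
  rowMajorOf <- idx[, 1L] * shape[2L] + idx[, 2L] + 1L
  ramanPix[inside] <- match(row[inside] * shape[2L] + col[inside] + 1L,
                            rowMajorOf)
  if (!any(inside))
    stop("no MSI pixel maps into the Raman extent; check the transform")
  list(pairs = data.frame(msi_pixel = which(inside),
                          raman_pixel = ramanPix[inside]),
       unmatched = which(!inside))
}

# ---------------------------------------------------------------------------
# imzML I/O (continuous and processed modes). The .ibd binary holds a
# 16-byte UUID header followed by the externally referenced arrays.

.IMZML_NS <- "http://psi.hupo.org/ms/mzml"

#' Write an MSIMap as an imzML/ibd pair
#'
#' Continuous mode stores the shared m/z axis once; processed mode stores a
#' per-pixel copy (the reader re-bins it). m/z values are 64-bit floats,
#' intensities 32-bit floats.
#'
#' @param msi an [MSIMap-class].
#' @param path output path ending in `.imzML`; the `.ibd` is written
#'   alongside.
#' @param mode `"continuous"` (default) or `"processed"`.
#' @return `path`, invisibly.
#' @export
writeImzML <- function(msi, path, mode = c("continuous", "processed")) {
  mode <- match.arg(mode)
  ibdPath <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibdPath, path)) ibdPath <- paste0(path, ".ibd")
  con <- file(ibdPath, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.raw(rep(0L, 16L)), con)  # UUID placeholder
  offset <- 16
  X <- intensities(msi)
  mz <- mzAxis(msi)
  shape <- gridShape(msi)
  n <- nrow(X)
  spec <- character(n)
  mzOffsets <- numeric(n)
  if (mode == "continuous") {
    writeBin(mz, con, size = 8L, endian = "little")
    mzOffsets[] <- offset
    offset <- offset + 8 * length(mz)
  }
  intOffsets <- numeric(n)
  for (i in seq_len(n)) {
    if (mode == "processed") {
      writeBin(mz, con, size = 8L, endian = "little")
      mzOffsets[i] <- offset
      offset <- offset + 8 * length(mz)
    }
    writeBin(as.numeric(X[i, ]), con, size = 4L, endian = "little")
    intOffsets[i] <- offset
    offset <- offset + 4 * length(mz)
  }
  xPos <- (seq_len(n) - 1L) %% shape[2L] + 1L
  yPos <- (seq_len(n) - 1L) %/% shape[2L] + 1L
  bda <- function(ref, off, len, bytes) paste0(
    '<binaryDataArray encodedLength="0">',
    '<referenceableParamGroupRef ref="', ref, '"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="', off, '"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="', len, '"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="', bytes, '"/>',
    '<binary/></binaryDataArray>')
  for (i in seq_len(n)) {
    spec[i] <- paste0(
      '<spectrum index="', i - 1L, '" id="spectrum=', i, '" defaultArrayLength="', length(mz), '">',
      '<scanList count="1"><scan>',
      '<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="', xPos[i], '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="', yPos[i], '"/>',
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      bda("mzArray", mzOffsets[i], length(mz), 8L * length(mz)),
      bda("intensityArray", intOffsets[i], length(mz), 4L * length(mz)),
      '</binaryDataArrayList></spectrum>')
  }
  modeAcc <- if (mode == "continuous") "IMS:1000030" else "IMS:1000031"
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="', .IMZML_NS, '" version="1.1">',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="IMS" accession="', modeAcc, '" name="', mode, '"/>',
    '</fileContent></fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitName="m/z"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000521" name="32-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    '<run id="run1"><spectrumList count="', n, '">',
    paste(spec, collapse = ""),
    '</spectrumList></run></mzML>')
  writeLines(xml, path)
  invisible(path)
}

# greedy ppm binning of sorted centroid m/z values: a new bin starts when
# the gap to the previous centroid exceeds the tolerance
.binMz <- function(mzAll, ppm) {
  o <- order(mzAll)
  mzSorted <- mzAll[o]
  bin <- integer(length(mzSorted))
  b <- 1L
  bin[1L] <- 1L
  for (i in seq_along(mzSorted)[-1L]) {
    if ((mzSorted[i] - mzSorted[i - 1L]) / mzSorted[i - 1L] * 1e6 > ppm)
      b <- b + 1L
    bin[i] <- b
  }
  out <- integer(length(mzAll))
  out[o] <- bin
  list(bin = out, centers = as.numeric(tapply(mzSorted, bin, mean)))
}

#' Read MALDI-MSI data from imzML
#'
#' Supports continuous and processed imzML. Spectra are RMS-normalized per
#' pixel (each retained spectrum gets root-mean-square 1); in processed
#' mode a common m/z axis is built by binning centroids within a ppm
#' tolerance (intensities summed per bin). An optional acquisition-range
#' filter keeps only m/z within `mzRange`.
#'
#' @param path `.imzML` file; the `.ibd` must sit alongside.
#' @param pixelSize micrometres per MSI pixel (default 50).
#' @param ppm binning tolerance for processed data (default 5).
#' @param mzRange optional `c(lo, hi)` filter, e.g. `c(75, 1000)`.
#' @param normalize apply RMS normalization (default TRUE).
#' @return An [MSIMap-class].
#' @export
readMSI <- function(path, pixelSize = 50, ppm = 5, mzRange = NULL,
                    normalize = TRUE) {
  doc <- xml2::read_xml(path)
  ns <- c(d = .IMZML_NS)
  ibdPath <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (!file.exists(ibdPath)) stop("missing .ibd next to ", path)
  fileContent <- xml2::xml_find_all(doc, ".//d:fileContent/d:cvParam", ns)
  modes <- xml2::xml_attr(fileContent, "name")
  continuous <- "continuous" %in% modes
  # encoding per referenceable param group
  groups <- xml2::xml_find_all(doc, ".//d:referenceableParamGroup", ns)
  enc <- list()
  for (g in groups) {
    id <- xml2::xml_attr(g, "id")
    names <- xml2::xml_attr(xml2::xml_find_all(g, "./d:cvParam", ns), "name")
    enc[[id]] <- if ("64-bit float" %in% names) 8L else 4L
  }
  specs <- xml2::xml_find_all(doc, ".//d:spectrum", ns)
  nSpec <- length(specs)
  if (!nSpec) stop("no spectra in ", path)
  con <- file(ibdPath, "rb")
  on.exit(close(con), add = TRUE)
  readArr <- function(offset, len, size) {
    seek(con, offset)
    readBin(con, "double", n = len, size = size, endian = "little")
  }
  xPos <- yPos <- integer(nSpec)
  mzL <- intL <- vector("list", nSpec)
  for (i in seq_len(nSpec)) {
    sp <- specs[[i]]
    pos <- xml2::xml_find_all(sp, ".//d:scan/d:cvParam", ns)
    pn <- xml2::xml_attr(pos, "name"); pv <- as.integer(xml2::xml_attr(pos, "value"))
    xPos[i] <- pv[pn == "position x"][1L]
    yPos[i] <- pv[pn == "position y"][1L]
    for (arr in xml2::xml_find_all(sp, ".//d:binaryDataArray", ns)) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(arr, "./d:referenceableParamGroupRef", ns), "ref")
      cv <- xml2::xml_find_all(arr, "./d:cvParam", ns)
      cn <- xml2::xml_attr(cv, "name"); cvv <- xml2::xml_attr(cv, "value")
      off <- as.numeric(cvv[cn == "external offset"][1L])
      len <- as.integer(cvv[cn == "external array length"][1L])
      vals <- readArr(off, len, enc[[ref]])
      if (ref == "mzArray") mzL[[i]] <- vals else intL[[i]] <- vals
    }
  }
  if (continuous) {
    mz <- mzL[[1L]]
    X <- do.call(rbind, intL)
  } else {
    allMz <- unlist(mzL)
    bins <- .binMz(allMz, ppm)
    mz <- bins$centers
    X <- matrix(0, nSpec, length(mz))
    pos0 <- 0L
    for (i in seq_len(nSpec)) {
      nI <- length(mzL[[i]])
      b <- bins$bin[pos0 + seq_len(nI)]
      for (j in seq_len(nI)) X[i, b[j]] <- X[i, b[j]] + intL[[i]][j]
      pos0 <- pos0 + nI
    }
  }
  if (!is.null(mzRange)) {
    keep <- mz >= mzRange[1L] & mz <= mzRange[2L]
    mz <- mz[keep]
    X <- X[, keep, drop = FALSE]
  }
  shape <- c(max(yPos), max(xPos))
  ord <- order((yPos - 1L) * shape[2L] + (xPos - 1L))
  X <- X[ord, , drop = FALSE]
  norm <- "none"
  if (normalize) {
    rms <- sqrt(rowMeans(X^2))
    nz <- rms > 0
    X[nz, ] <- X[nz, , drop = FALSE] / rms[nz]
    norm <- "rms"
  }
  MSIMap(mz, X, shape, pixelSize = pixelSize, normalization = norm)
}

# ---------------------------------------------------------------------------

# kNN indices and per-point kernel bandwidth (distance to the k-th
# neighbour) from a score matrix
.knnWithBandwidth <- function(X, k) {
  d <- as.matrix(stats::dist(X))
  diag(d) <- Inf
  nn <- t(apply(d, 1L, function(r) order(r)[seq_len(k)]))
  bw <- d[cbind(seq_len(nrow(X)), nn[, k])]
  bw[bw == 0] <- max(min(bw[bw > 0], na.rm = TRUE), 1e-8)
  list(nn = nn, bw = bw, dist = d)
}

#' Weighted nearest-neighbour integration of two modalities
#'
#' Per pixel, each modality's profile is predicted from the averages of its
#' within-modality and cross-modality k nearest neighbours; the modality
#' affinity is the relative prediction accuracy (the cross-minus-within
#' error gap scaled by the pixel's neighbourhood bandwidth, clamped to
#' `[-4, 4]`), mapped through a softmax (temperature 1) to weights summing
#' to 1. The joint similarity is the weighted sum of per-modality Gaussian
#' kernels with per-pixel bandwidth (twice the distance to the k-th
#' neighbour); the joint SNN graph is clustered by Louvain.
#'
#' @param embA,embB [Embedding-class] objects over the same pixel set (or
#'   bare score matrices).
#' @param k neighbours (default 20), `< nPixels`.
#' @param resolution Louvain resolution for the joint graph (default 0.8).
#' @param seed RNG seed (default 7).
#' @return list with `weights` (`n x 2`, columns A and B), `labels`
#'   (a [ClusterLabels-class]), and `jointNeighbors` (kNN indices in the
#'   joint space).
#' @export
wnnIntegrate <- function(embA, embB, k = 20L, resolution = 0.8, seed = 7L) {
  XA <- if (is(embA, "Embedding")) embA@scores else as.matrix(embA)
  XB <- if (is(embB, "Embedding")) embB@scores else as.matrix(embB)
  if (nrow(XA) != nrow(XB)) stop("modalities must cover the same pixel set")
  n <- nrow(XA)
  if (k >= n) stop("k must be < number of pixels")
  pixels <- if (is(embA, "Embedding")) embA@pixels else seq_len(n)
  kA <- .knnWithBandwidth(XA, k)
  kB <- .knnWithBandwidth(XB, k)
  predErr <- function(X, nn) {
    vapply(seq_len(n), function(i)
      sqrt(sum((X[i, ] - colMeans(X[nn[i, ], , drop = FALSE]))^2)), 0)
  }
  eAw <- predErr(XA, kA$nn); eAc <- predErr(XA, kB$nn)
  eBw <- predErr(XB, kB$nn); eBc <- predErr(XB, kA$nn)
  # bandwidth-scaled accuracy gap, clamped so the softmax cannot saturate
  # on the noise of two equally informative modalities
  sA <- pmin(pmax((eAc - eAw) / kA$bw, -4), 4)
  sB <- pmin(pmax((eBc - eBw) / kB$bw, -4), 4)
  wA <- 1 / (1 + exp(sB - sA))
  weights <- cbind(A = wA, B = 1 - wA)
  # kernel bandwidth 2 x d_k keeps within-cluster similarities flat so a
  # modality that cannot separate two planted groups does not pollute the
  # joint neighbourhood
  simA <- exp(-(kA$dist / (2 * kA$bw))^2)
  simB <- exp(-(kB$dist / (2 * kB$bw))^2)
  joint <- weights[, 1L] * simA + weights[, 2L] * simB
  diag(joint) <- 0
  nnJ <- t(apply(joint, 1L, function(r) order(r, decreasing = TRUE)[seq_len(k)]))
  sets <- lapply(seq_len(n), function(i) c(i, nnJ[i, ]))
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (i in seq_len(n)) {
    for (j in nnJ[i, ]) {
      if (j > i) {
        jac <- length(intersect(sets[[i]], sets[[j]])) /
               length(union(sets[[i]], sets[[j]]))
        if (jac > 0) { from <- c(from, i); to <- c(to, j); w <- c(w, jac) }
      }
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- w
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- .groupSingletons(as.integer(igraph::membership(comm)), g)
  labels <- ClusterLabels(memb, pixels, method = "wnn",
                          params = list(k = k, resolution = resolution),
                          seed = seed)
  list(weights = weights, labels = labels, jointNeighbors = nnJ)
}

#' Paired volcano and standardized-mean-difference statistics
#'
#' Per feature (wavenumber or m/z): log2 fold change of group means
#' (pseudo-value 1), a paired t-test across samples, and the standardized
#' mean difference (Cohen's d with pooled SD). Samples are columns, paired
#' across the two groups. Zero-variance differences give p = 1 when the
#' mean difference is 0 and p = 0 (flagged degenerate) otherwise.
#'
#' @param groupA,groupB numeric `nFeatures x nSamples` matrices of
#'   cluster-averaged feature values per sample.
#' @param featureIds optional feature names (wavenumber or m/z).
#' @return data.frame with feature, log2fc, p_paired, smd, degenerate.
#' @export
volcanoStats <- function(groupA, groupB, featureIds = NULL) {
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  if (!all(dim(groupA) == dim(groupB)))
    stop("groups must have identical feature x sample layout")
  if (ncol(groupA) < 2L) stop("need at least 2 paired samples")
  nF <- nrow(groupA); nS <- ncol(groupA)
  if (is.null(featureIds)) featureIds <- seq_len(nF)
  log2fc <- log2(rowMeans(groupA) + 1) - log2(rowMeans(groupB) + 1)
  p <- numeric(nF); degen <- logical(nF); smd <- numeric(nF)
  for (f in seq_len(nF)) {
    d <- groupA[f, ] - groupB[f, ]
    if (stats::sd(d) == 0) {
      if (mean(d) == 0) p[f] <- 1 else { p[f] <- 0; degen[f] <- TRUE }
    } else {
      p[f] <- stats::t.test(groupA[f, ], groupB[f, ], paired = TRUE)$p.value
    }
    sp <- sqrt(((nS - 1) * stats::var(groupA[f, ]) +
                (nS - 1) * stats::var(groupB[f, ])) / (2 * nS - 2))
    smd[f] <- if (sp == 0) 0 else (mean(groupA[f, ]) - mean(groupB[f, ])) / sp
  }
  data.frame(feature = featureIds, log2fc = log2fc, p_paired = p, smd = smd,
             degenerate = degen)
}
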