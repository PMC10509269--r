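# Clustering-comparison metrics: IoU (Jaccard) matrices with row/column-max
# averaging, adjusted Rand index, and target-cluster detection benchmarks.

# coerce a labelling (ClusterLabels or integer vector) to an integer vector
.labelVector <- function(x) {
  if (is(x, "ClusterLabels")) x@labels else as.integer(x)
}

#' IoU matrix between two labelings
#'
#' `IoU(a, b) = |mask_a intersect mask_b| / |mask_a union mask_b|` for every
#' cluster pair of the two labelings over the same pixel set.
#' `meanMaxIoU` averages the per-row and per-column maxima jointly
#' (`N_A + N_B` values).
#'
#' @param labelsA,labelsB [ClusterLabels-class] objects or integer vectors
#'   over the same pixels.
#' @return list with `iou` (`N_A x N_B` matrix), `rowMax`, `colMax`,
#'   `meanMaxIoU`.
#' @export
iouMatrix <- function(labelsA, labelsB) {
  a <- .labelVector(labelsA); b <- .labelVector(labelsB)
  if (length(a) != length(b)) stop("labelings must cover the same pixel set")
  if (!length(a)) stop("empty labeling")
  ua <- sort(unique(a)); ub <- sort(unique(b))
  ct <- table(factor(a, ua), factor(b, ub))
  na <- rowSums(ct); nb <- colSums(ct)
  # IoU = inter / (|A| + |B| - inter)
  iou <- matrix(0, length(ua), length(ub), dimnames = list(ua, ub))
  for (i in seq_along(ua)) for (j in seq_along(ub))
    iou[i, j] <- ct[i, j] / (na[i] + nb[j] - ct[i, j])
  rowMax <- apply(iou, 1L, max)
  colMax <- apply(iou, 2L, max)
  list(iou = iou, rowMax = rowMax, colMax = colMax,
       meanMaxIoU = mean(c(rowMax, colMax)))
}

#' Adjusted Rand index between two labelings
#'
#' Standard ARI from the contingency table; 1 for identical partitions,
#' ~0 for independent ones, invariant to label permutation.
#'
#' @param labelsA,labelsB [ClusterLabels-class] objects or integer vectors
#'   over the same pixels.
#' @return numeric ARI.
#' @export
adjustedRand <- function(labelsA, labelsB) {
  a <- .labelVector(labelsA); b <- .labelVector(labelsB)
  if (length(a) != length(b)) stop("labelings must cover the same pixel set")
  ct <- table(a, b)
  n <- length(a)
  sumIJ <- sum(choose(ct, 2))
  sumI <- sum(choose(rowSums(ct), 2))
  sumJ <- sum(choose(colSums(ct), 2))
  expected <- sumI * sumJ / choose(n, 2)
  maxIdx <- (sumI + sumJ) / 2
  if (maxIdx == expected) return(ifelse(sumIJ == expected, 1, 0))
  (sumIJ - expected) / (maxIdx - expected)
}

#' Detection benchmark for one target cluster against a truth mask
#'
#' Pixels in `targetCluster` are positive calls; standard confusion
#' arithmetic against a boolean truth mask over the same pixels. Undefined
#' ratios (empty truth or empty complement) are reported as `NA`.
#'
#' @param labels a [ClusterLabels-class] or integer vector.
#' @param truthMask logical per pixel.
#' @param targetCluster the cluster id treated as the positive call.
#' @return list with TP, FP, TN, FN, accuracy, sensitivity, specificity.
#' @export
benchmarkDetection <- function(labels, truthMask, targetCluster) {
  lab <- .labelVector(labels)
  if (length(lab) != length(truthMask))
    stop("labels and truth mask must cover the same pixels")
  call <- lab == targetCluster
  TP <- sum(call & truthMask); FP <- sum(call & !truthMask)
  FN <- sum(!call & truthMask); TN <- sum(!call & !truthMask)
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       accuracy = (TP + TN) / length(lab),
       sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
       specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_)
}
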