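# Reference-spectrum cell typing.

test_that("landmark images use the nearest channel and the full grid", {
  axis <- c(1370.1, 1372.2, 1374.9)
  map <- mkMap(matrix(1:12, 4, 3), gridShape = c(2, 2), axis = axis)
  img <- renderLandmarkImage(map, 1372)
  expect_identical(attr(img, "wavenumber"), 1372.2)
  expect_identical(dim(img), c(2L, 2L))
  expect_equal(img[1, 1], intensities(map)[1, 2])
})

test_that("synthetic erythrocytes light up the hemin band against background", {
  cts <- generateCelltypeScene(gridShape = c(30, 30), cellsPerType = 4,
                               seed = 60)
  img <- renderLandmarkImage(cts$map, 1372)
  lab <- matrix(clusterLabels(cts$labels), 30, 30, byrow = TRUE)
  eryId <- as.integer(names(cts$labels@legend)[cts$labels@legend == "erythrocyte"])
  expect_gte(mean(img[lab == eryId]) / mean(img[lab == 0]), 5)
})

test_that("labelled spectra extraction respects masks and counts", {
  cts <- generateCelltypeScene(gridShape = c(30, 30), cellsPerType = 3,
                               seed = 61)
  coll <- extractLabeledSpectra(cts$map, cts$labels)
  counts <- vapply(coll, nrow, 0L)
  expect_identical(sum(counts), sum(clusterLabels(cts$labels) != 0L))
  # QC-failed labelled pixels are excluded from the counts
  m2 <- cts$map
  labelledPixels <- which(clusterLabels(cts$labels)[
    pixelIndex(m2)[, 1] * gridShape(m2)[2] + pixelIndex(m2)[, 2] + 1] != 0L)
  qcMask(m2)[labelledPixels[1:5]] <- FALSE
  coll2 <- extractLabeledSpectra(m2, cts$labels)
  expect_identical(sum(vapply(coll2, nrow, 0L)), sum(counts) - 5L)
  # a type with no labelled pixels is omitted with a warning
  legend3 <- c(cts$labels@legend, "99" = "ghost")
  lab3 <- CellLabelImage(clusterLabels(cts$labels), gridShape(cts$labels),
                         legend3)
  expect_warning(extractLabeledSpectra(cts$map, lab3), "ghost")
})

test_that("reference spectra are unit-norm means of unit-norm spectra", {
  wn <- seq(400, 420, 2)
  one <- matrix(runif(11), 1)
  refs1 <- buildReferenceSpectra(list(a = one), wn)
  expect_equal(drop(refs1@spectra), drop(one) / sqrt(sum(one^2)))
  # two identical spectra give the same reference as either alone
  refs2 <- buildReferenceSpectra(list(a = rbind(one, one)), wn)
  expect_equal(refs2@spectra, refs1@spectra)
  set.seed(62)
  refsM <- buildReferenceSpectra(list(a = matrix(runif(44), 4),
                                      b = matrix(runif(44), 4)), wn)
  expect_equal(unname(rowSums(refsM@spectra^2)), c(1, 1), tolerance = 1e-12)
})

test_that("matching assigns exact references perfectly and respects thresholds", {
  set.seed(63)
  wn <- seq(400, 598, 2)
  refSpec <- rbind(a = runif(100), b = runif(100))
  refs <- new("ReferenceSpectrumSet",
              spectra = refSpec / sqrt(rowSums(refSpec^2)),
              wavenumbers = wn, nPixels = c(1L, 1L))
  map <- mkMap(rbind(5 * refSpec[1, ], 2 * refSpec[2, ]),
               gridShape = c(2, 1), axis = wn)
  calls <- matchCells(map, refs, metric = "cosine")
  expect_identical(calls$type, c("a", "b"))
  expect_equal(calls$score, c(1, 1), tolerance = 1e-12)
  # impossible threshold leaves every pixel unassigned
  none <- matchCells(map, refs, threshold = 1.01)
  expect_false(any(none$assigned))
  # constant pixel spectrum is undefined under Pearson, stays unassigned
  mapC <- mkMap(rbind(refSpec[1, ], rep(1, 100)), gridShape = c(2, 1),
                axis = wn)
  callsC <- matchCells(mapC, refs, metric = "pearson")
  expect_false(callsC$assigned[2])
})

test_that("matching accuracy is high at low noise and non-increasing in noise", {
  wn <- seq(400, 598, 2)
  set.seed(64)
  specA <- numeric(100); specA[c(10, 30, 50)] <- 1
  specB <- numeric(100); specB[c(20, 60, 80)] <- 1
  truth <- rep(c("a", "b"), each = 40)
  acc <- vapply(c(0.05, 0.2, 0.5), function(ns) {
    X <- rbind(matrix(rep(specA, 40), 40, byrow = TRUE),
               matrix(rep(specB, 40), 40, byrow = TRUE)) +
      matrix(rnorm(80 * 100, sd = ns), 80, 100)
    map <- mkMap(X, gridShape = c(8, 10), axis = wn)
    refs <- buildReferenceSpectra(list(a = rbind(specA), b = rbind(specB)), wn)
    calls <- matchCells(map, refs, threshold = -1)
    mean(calls$type == truth, na.rm = TRUE)
  }, 0)
  expect_gte(acc[1], 0.95)
  expect_true(all(diff(acc) <= 0))
})

test_that("confusion summaries follow standard arithmetic", {
  # TP=2, FN=2, TN=5, FP=1 -> sensitivity 0.5, specificity 5/6
  map <- mkMap(matrix(1, 10, 3), gridShape = c(2, 5))
  truthLab <- c(rep(1L, 4), rep(2L, 6))
  truth <- CellLabelImage(truthLab, c(2, 5), c("1" = "a", "2" = "b"))
  callType <- c("a", "a", "b", "b", "a", "b", "b", "b", "b", "b")
  calls <- data.frame(pixel = 1:10, type = callType, score = 1,
                      assigned = TRUE)
  cs <- evaluateSensSpec(calls, truth, map)
  a <- cs[cs$type == "a", ]
  expect_identical(c(a$TP, a$FN, a$TN, a$FP), c(2L, 2L, 5L, 1L))
  expect_equal(a$sensitivity, 0.5)
  expect_equal(a$specificity, 5 / 6)
  # perfect calls: sensitivity = specificity = 1 everywhere
  callsP <- data.frame(pixel = 1:10, type = c("a", "b")[truthLab],
                       score = 1, assigned = TRUE)
  csP <- evaluateSensSpec(callsP, truth, map)
  expect_true(all(csP$sensitivity == 1) && all(csP$specificity == 1))
  # calling everything one type: its sensitivity 1, the other's 0
  callsA <- data.frame(pixel = 1:10, type = "a", score = 1, assigned = TRUE)
  csA <- evaluateSensSpec(callsA, truth, map)
  expect_equal(csA[csA$type == "a", "sensitivity"], 1)
  expect_equal(csA[csA$type == "b", "sensitivity"], 0)
})

test_that("self-consistency: references built from a scene re-identify its cells", {
  cts <- generateCelltypeScene(gridShape = c(40, 40), cellsPerType = 6,
                               seed = 65)
  coll <- extractLabeledSpectra(cts$map, cts$labels)
  refs <- buildReferenceSpectra(coll, wavenumbers(cts$map))
  calls <- matchCells(cts$map, refs)
  cs <- evaluateSensSpec(calls, cts$labels, cts$map)
  expect_true(all(cs$sensitivity >= 0.9))
})

test_that("spectrally disjoint cell types separate in a tSNE of labelled spectra", {
  cts <- generateCelltypeScene(types = c("erythrocyte", "leukocyte"),
                               gridShape = c(30, 30), cellsPerType = 6,
                               seed = 66)
  coll <- extractLabeledSpectra(cts$map, cts$labels)
  X <- do.call(rbind, coll)
  grp <- rep(seq_along(coll), vapply(coll, nrow, 0L))
  emb <- mkEmbedding(scale(X) %*% svd(scale(X), nv = 5)$v)
  y <- embed2D(emb, "tsne", perplexity = 15, seed = 1)
  d <- as.matrix(dist(y))
  sil <- vapply(seq_len(nrow(y)), function(i) {
    a <- sum(d[i, grp == grp[i]]) / (sum(grp == grp[i]) - 1)
    b <- mean(d[i, grp != grp[i]])
    (b - a) / max(a, b)
  }, 0)
  expect_gt(mean(sil), 0.5)
})
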