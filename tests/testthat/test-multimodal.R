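# Registration, pixel correspondence, imzML I/O, WNN fusion, volcano stats.

test_that("similarity transforms apply, invert and compose to machine precision", {
  tr <- AffineTransform2D(theta = pi / 5, scale = 1.7, translation = c(3, -8))
  set.seed(50)
  P <- matrix(runif(20, -50, 50), 10, 2)
  back <- applyTransform(invertTransform(tr), applyTransform(tr, P))
  expect_lt(max(abs(back - P)), 1e-9)
  comp <- composeTransforms(invertTransform(tr), tr)
  expect_lt(max(abs(applyTransform(comp, P) - P)), 1e-9)
})

test_that("landmark fits recover identity, planted, and noisy transforms", {
  set.seed(51)
  src <- matrix(runif(20, 0, 100), 10, 2)
  # identical landmark sets: identity to 1e-12
  fitI <- estimateSimilarityTransform(src, src)
  expect_lt(abs(fitI$transform@scale - 1), 1e-12)
  expect_lt(abs(fitI$transform@theta), 1e-12)
  expect_lt(max(abs(fitI$transform@translation)), 1e-12)
  # planted s = 2, theta = 30 deg, t = (5, -3): recovered to 1e-9
  tr <- AffineTransform2D(theta = 30 * pi / 180, scale = 2,
                          translation = c(5, -3))
  fit <- estimateSimilarityTransform(src, applyTransform(tr, src))
  expect_lt(abs(fit$transform@scale - 2), 1e-9)
  expect_lt(abs(fit$transform@theta - 30 * pi / 180), 1e-9)
  expect_lt(max(abs(fit$transform@translation - c(5, -3))), 1e-9)
  expect_lt(fit$rmsResidual, 1e-9)
  # noisy landmarks: residual bounded by the noise scale
  noisy <- applyTransform(tr, src) + matrix(rnorm(20, sd = 0.5), 10, 2)
  fitN <- estimateSimilarityTransform(src, noisy)
  expect_lte(fitN$rmsResidual, 3 * 0.5)
  expect_error(estimateSimilarityTransform(src[1, , drop = FALSE],
                                           src[1, , drop = FALSE]), "2")
  expect_error(estimateSimilarityTransform(rbind(c(1, 1), c(1, 1)),
                                           rbind(c(0, 0), c(2, 2))),
               "coincident")
})

test_that("pixel-centre correspondence respects the 5:1 resolution geometry", {
  raman <- mkMap(matrix(0, 100, 2), gridShape = c(10, 10), pixelSize = 10)
  msi <- MSIMap(c(100, 200), matrix(0, 4, 2), c(2, 2), pixelSize = 50)
  corr <- mapPixelCenters(AffineTransform2D(), msi, raman)
  # MSI pixel (0,0) centre (25,25) -> Raman pixel (row 2, col 2)
  first <- corr$pairs[corr$pairs$msi_pixel == 1, "raman_pixel"]
  expect_identical(pixelIndex(raman)[first, ], c(row = 2L, col = 2L))
  # all 4 MSI centres land inside; matched pixels form a 5-spaced sublattice
  expect_identical(nrow(corr$pairs), 4L)
  idx <- pixelIndex(raman)[corr$pairs$raman_pixel, ]
  expect_identical(sort(unique(idx[, "row"])), c(2L, 7L))
  expect_identical(sort(unique(idx[, "col"])), c(2L, 7L))
  # pure translation by one Raman pixel shifts the correspondence uniformly
  corrT <- mapPixelCenters(AffineTransform2D(translation = c(10, 0)),
                           msi, raman)
  idxT <- pixelIndex(raman)[corrT$pairs$raman_pixel, ]
  expect_identical(idxT[, "col"], idx[, "col"] + 1L)
  expect_identical(idxT[, "row"], idx[, "row"])
  # centres transformed outside the extent are unmatched
  corrO <- mapPixelCenters(AffineTransform2D(translation = c(30, 0)),
                           msi, raman)
  expect_identical(corrO$unmatched, c(2L, 4L))
  expect_error(mapPixelCenters(AffineTransform2D(translation = c(1e4, 0)),
                               msi, raman), "transform")
})

test_that("imzML round-trips in continuous and processed mode with RMS normalization", {
  set.seed(52)
  mz <- sort(runif(30, 75, 1000))
  X <- matrix(runif(6 * 30, 0, 10), 6, 30)
  msi <- MSIMap(mz, X, c(2, 3), pixelSize = 50)
  for (mode in c("continuous", "processed")) {
    f <- withr::local_tempfile(fileext = ".imzML")
    writeImzML(msi, f, mode = mode)
    raw <- readMSI(f, normalize = FALSE)
    expect_equal(mzAxis(raw), mz, tolerance = 1e-9)
    expect_equal(intensities(raw), X, tolerance = 1e-6)  # 32-bit floats
    expect_identical(gridShape(raw), c(2L, 3L))
    norm <- readMSI(f, normalize = TRUE)
    expect_equal(sqrt(rowMeans(intensities(norm)^2)), rep(1, 6),
                 tolerance = 1e-9)
  }
})

test_that("processed-mode centroids merge within the ppm tolerance and split beyond it", {
  mz <- c(500, 500 + 500 * 2e-6, 600, 600 + 600 * 20e-6)  # 2 ppm and 20 ppm
  X <- matrix(1, 2, 4)
  msi <- MSIMap(mz, X, c(1, 2), pixelSize = 50)
  f <- withr::local_tempfile(fileext = ".imzML")
  writeImzML(msi, f, mode = "processed")
  out <- readMSI(f, ppm = 5, normalize = FALSE)
  expect_identical(length(mzAxis(out)), 3L)        # 2 ppm pair merged
  expect_equal(intensities(out)[1, 1], 2)          # intensities summed
  # acquisition-range filter
  msi2 <- MSIMap(c(50, 80, 900, 1200), matrix(1, 2, 4), c(1, 2))
  f2 <- withr::local_tempfile(fileext = ".imzML")
  writeImzML(msi2, f2)
  filt <- readMSI(f2, mzRange = c(75, 1000), normalize = FALSE)
  expect_identical(length(mzAxis(filt)), 2L)
})

test_that("WNN weights reflect modality information content", {
  set.seed(53)
  n <- 500
  truth <- rep(0:3, each = n / 4)
  A <- matrix(rnorm(n * 4, sd = 0.3), n, 4)
  A[, 1] <- A[, 1] + ifelse(truth %in% c(2, 3), 4, 0)
  A[, 2] <- A[, 2] + ifelse(truth %in% c(1, 3), 4, 0)
  noise <- matrix(rnorm(n * 4), n, 4)
  # uninformative second modality: nearly all weight on modality A
  wNoise <- wnnIntegrate(A, noise, k = 20, seed = 1)
  expect_gt(mean(wNoise$weights[, 1]), 0.9)
  # exact copy: weights 0.5 by symmetry
  wCopy <- wnnIntegrate(A, A, k = 20, seed = 1)
  expect_lt(max(abs(wCopy$weights[, 1] - 0.5)), 0.05)
  expect_error(wnnIntegrate(A, noise, k = n), "k must be")
})

test_that("complementary modalities fuse into clusters neither resolves alone", {
  set.seed(54)
  n <- 300
  truth <- rep(0:3, each = n / 4)
  A <- matrix(rnorm(n * 4, sd = 0.3), n, 4)
  A[, 1] <- A[, 1] + ifelse(truth %in% c(2, 3), 4, 0)  # separates {0,1}|{2,3}
  B <- matrix(rnorm(n * 4, sd = 0.3), n, 4)
  B[, 1] <- B[, 1] + ifelse(truth %in% c(1, 3), 4, 0)  # separates {0,2}|{1,3}
  joint <- wnnIntegrate(A, B, k = 20, resolution = 0.8, seed = 2)
  ariJ <- adjustedRand(joint$labels, truth)
  ariA <- adjustedRand(snnCluster(A, 20, 0.8, seed = 2), truth)
  ariB <- adjustedRand(snnCluster(B, 20, 0.8, seed = 2), truth)
  expect_gt(ariJ, max(ariA, ariB))
  expect_gt(ariJ, 0.9)
})

test_that("volcano statistics match hand-computed fold changes, t-tests and SMD", {
  # equal groups: zero fold change, p = 1
  A <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3)
  res0 <- volcanoStats(A, A)
  expect_true(all(res0$log2fc == 0))
  expect_true(all(res0$p_paired == 1))
  # SMD toy: A = {1,2,3}, B = {3,4,5} -> pooled SD 1, smd -2
  res <- volcanoStats(matrix(1:3, 1), matrix(3:5, 1))
  expect_equal(res$smd, -2)
  # planted shifts dominate the SMD ranking with matching signs
  set.seed(55)
  nF <- 50
  base <- matrix(rnorm(nF * 3, 10, 0.05), nF, 3)
  delta <- rep(0, nF)
  shifted <- sample(nF, 10)
  delta[shifted] <- sample(c(-2, 2), 10, replace = TRUE)
  resP <- volcanoStats(base + delta, base + rnorm(nF * 3, sd = 0.05))
  top10 <- order(-abs(resP$smd))[1:10]
  expect_setequal(top10, shifted)
  expect_identical(sign(resP$smd[shifted]), sign(delta[shifted]))
  # degenerate zero-variance nonzero difference flagged
  resD <- volcanoStats(matrix(2, 1, 3), matrix(1, 1, 3))
  expect_identical(resD$p_paired, 0)
  expect_true(resD$degenerate)
})
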