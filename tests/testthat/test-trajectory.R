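# Pseudotime trees, line trajectories, loess profiles and dynamics
# statistics.

test_that("a 1-D cloud yields a path tree whose pseudotime tracks the line", {
  set.seed(40)
  t <- runif(200)
  X <- cbind(10 * t, rnorm(200, sd = 0.05))
  pt <- principalTree(mkEmbedding(X), nNodes = 15, seed = 1)
  expect_length(branchPoints(pt), 0)
  expect_gte(abs(cor(pseudotime(pt), t, method = "spearman")), 0.99)
  # pixels assigned to the root node sit at pseudotime 0
  expect_true(all(pseudotime(pt)[pt@nodeAssignment == pt@root] == 0))
  expect_error(principalTree(mkEmbedding(X), nNodes = 300), "nNodes")
})

test_that("a Y-shaped cloud yields exactly one branch point in >= 9/10 seeds", {
  nBranch <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 150
    arm <- sample(1:3, n, replace = TRUE)
    tt <- runif(n)
    dirs <- rbind(c(1, 0), c(-0.5, 0.87), c(-0.5, -0.87))
    X <- dirs[arm, ] * tt * 10 + matrix(rnorm(2 * n, sd = 0.15), n, 2)
    length(branchPoints(principalTree(mkEmbedding(X), nNodes = 15, seed = s)))
  }, 0L)
  expect_gte(sum(nBranch == 1L), 9L)
})

test_that("Bresenham trajectories cover rows, columns and diagonals", {
  map <- mkMap(matrix(0, 25, 3), gridShape = c(5, 5))
  horiz <- sampleLineTrajectory(map, c(0, 0), c(0, 4))
  expect_equal(horiz@pixels, cbind(rep(0L, 5), 0:4), ignore_attr = TRUE)
  diag4 <- sampleLineTrajectory(map, c(0, 0), c(3, 3))
  expect_equal(diag4@pixels, cbind(0:3, 0:3), ignore_attr = TRUE)
  expect_equal(max(diag4@distance), 3 * sqrt(2))
  single <- sampleLineTrajectory(map, c(2, 2), c(2, 2))
  expect_identical(nrow(single@pixels), 1L)
  expect_identical(single@distance, 0)
  expect_error(sampleLineTrajectory(map, c(0, 0), c(5, 0)), "outside")
})

test_that("trajectory profiles are log2-normalized to the trajectory mean", {
  # constant intensity -> identically zero series
  map <- mkMap(matrix(7, 36, 10), gridShape = c(6, 6))
  traj <- sampleLineTrajectory(map, c(0, 0), c(0, 5))
  prof <- trajectoryProfile(map, traj)
  expect_true(all(prof@series == 0))
  # intensity doubling at the midpoint: two-level series around the mean
  X <- matrix(10, 36, 10)
  X[1:18, ] <- 20  # rows 0-2 of the grid doubled
  map2 <- mkMap(X, gridShape = c(6, 6))
  traj2 <- sampleLineTrajectory(map2, c(0, 0), c(5, 0))
  prof2 <- trajectoryProfile(map2, traj2)
  mu <- mean(c(rep(20, 3), rep(10, 3)))
  expect_equal(prof2@series[1, 1], log2(21 / (mu + 1)))
  expect_equal(prof2@series[6, 1], log2(11 / (mu + 1)))
  # normalization identity: mean of 2^series is ~1 (epsilon-corrected)
  expect_lt(abs(mean(2^prof2@series[, 1]) - 1), 0.02)
  # QC-dropped pixels are skipped
  qcMask(map2)[7] <- FALSE  # trajectory pixel (1,0)
  prof3 <- trajectoryProfile(map2, traj2)
  expect_identical(nrow(prof3@series), 5L)
})

test_that("reversing a trajectory reverses the series but not the dynamics metrics", {
  gs <- generateGradientScene(gridShape = c(8, 30), seed = 41)
  labs <- ClusterLabels(gs$truth$regionLabels, seq_len(nPixels(gs$map)))
  fwd <- trajectoryProfile(gs$map,
                           sampleLineTrajectory(gs$map, c(4, 0), c(4, 29)),
                           labs)
  rev <- trajectoryProfile(gs$map,
                           sampleLineTrajectory(gs$map, c(4, 29), c(4, 0)),
                           labs)
  expect_equal(rev@series, fwd@series[nrow(fwd@series):1, ])
  dFwd <- dynamicsMetrics(fwd)
  dRev <- dynamicsMetrics(rev)
  expect_equal(dFwd$max_variability, dRev$max_variability, tolerance = 1e-10)
  expect_equal(dFwd$dynamic_fraction, dRev$dynamic_fraction, tolerance = 1e-10)
})

test_that("loessFit reproduces polynomials exactly and matches the direct oracle", {
  # exact quadratic reproduction
  x <- seq(0, 1, length.out = 15)
  y <- 2 + 3 * x - 5 * x^2
  f <- loessFit(x, y)
  expect_lt(max(abs(f$fitted - y)), 1e-8)
  # 20 random points against the per-point weighted-least-squares oracle
  set.seed(42)
  x2 <- sort(runif(20))
  y2 <- sin(4 * x2) + rnorm(20, sd = 0.1)
  f2 <- loessFit(x2, y2)
  expect_lt(max(abs(f2$fitted - oracleLoess(x2, y2))), 1e-6)
  # constant input: constant fit, non-negative CI width
  fc <- loessFit(x, rep(3, 15))
  expect_equal(fc$fitted, rep(3, 15))
  expect_true(all(fc$ciUpper >= fc$ciLower))
  expect_error(loessFit(x[1:3], y[1:3]), "at least")
})

test_that("dynamics metrics follow the ramp arithmetic and threshold contract", {
  # constant profile: both metrics exactly zero
  mapC <- mkMap(matrix(5, 36, 4), gridShape = c(6, 6))
  trajC <- sampleLineTrajectory(mapC, c(0, 0), c(0, 5))
  labs <- ClusterLabels(rep(0, 36), seq_len(36))
  dC <- dynamicsMetrics(trajectoryProfile(mapC, trajC, labs))
  expect_true(all(dC$max_variability == 0))
  expect_true(all(dC$dynamic_fraction == 0))
  # linear log2 ramp with slope 0.5 per pixel: all defined steps exceed 0.4
  prof <- new("TrajectoryProfile", trajectory = trajC,
              wavenumbers = c(1000),
              series = matrix(seq(0, 4.5, by = 0.5), 10, 1),
              fitted = matrix(seq(0, 4.5, by = 0.5), 10, 1),
              ciLower = matrix(0, 10, 1), ciUpper = matrix(0, 10, 1),
              clusterAt = rep(0L, 10), positions = as.numeric(0:9))
  d <- dynamicsMetrics(prof, threshold = 0.4)
  expect_equal(d$dynamic_fraction, 1.0)
  expect_equal(d$max_variability, 4.5)
  # threshold above the largest derivative: fraction 0
  expect_equal(dynamicsMetrics(prof, threshold = 0.6)$dynamic_fraction, 0)
  # a single-position cluster is skipped with a warning
  prof@clusterAt <- c(rep(0L, 9), 1L)
  expect_warning(dynamicsMetrics(prof), "skipped")
})

test_that("cluster dynamics comparison matches hand-computed t statistics", {
  tab <- data.frame(cluster = rep(c(0, 1), each = 5),
                    wavenumber = rep(1:5, 2),
                    max_variability = 0,
                    dynamic_fraction = c(1, 2, 3, 4, 5, 2, 4, 3, 6, 8))
  res <- compareClustersDynamics(tab, 0, 1)
  d <- c(1, 2, 3, 4, 5) - c(2, 4, 3, 6, 8)
  tHand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$paired$statistic, tHand)
  expect_equal(res$paired$p.value,
               2 * pt(-abs(tHand), df = 4))
  wHand <- t.test(c(1, 2, 3, 4, 5), c(2, 4, 3, 6, 8))
  expect_equal(res$welch$statistic, unname(wHand$statistic))
  # identical metric vectors: p = 1 by convention
  tabSame <- tab
  tabSame$dynamic_fraction <- rep(1:5, 2)
  resSame <- compareClustersDynamics(tabSame, 0, 1)
  expect_identical(resSame$paired$p.value, 1)
  # planted shift of 0.3 over 200 wavenumbers: p far below 1e-6
  set.seed(43)
  a <- rnorm(200, sd = 0.05)
  tabBig <- data.frame(cluster = rep(c(0, 1), each = 200),
                       wavenumber = rep(1:200, 2),
                       max_variability = 0,
                       dynamic_fraction = c(a, a + 0.3 +
                                            rnorm(200, sd = 0.05)))
  expect_lt(compareClustersDynamics(tabBig, 1, 0)$paired$p.value, 1e-6)
})

test_that("planted dynamics are recovered: the ramped cluster dominates at planted bands", {
  gs <- generateGradientScene(seed = 44)
  labs <- ClusterLabels(gs$truth$regionLabels, seq_len(nPixels(gs$map)))
  traj <- sampleLineTrajectory(gs$map, c(10, 0), c(10, 59))
  dyn <- dynamicsMetrics(trajectoryProfile(gs$map, traj, labs))
  wn <- wavenumbers(gs$map)
  planted <- wn[vapply(gs$truth$dynamicWavenumbers,
                       function(p) which.min(abs(wn - p)), 0L)]
  a <- dyn[dyn$cluster == 1 & dyn$wavenumber %in% round(planted, 1), ]
  b <- dyn[dyn$cluster == 0 & dyn$wavenumber %in% round(planted, 1), ]
  expect_gte(mean(a$dynamic_fraction > b$dynamic_fraction), 0.95)
  expect_gte(mean(a$max_variability > b$max_variability), 0.95)
})
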