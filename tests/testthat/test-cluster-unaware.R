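# Spatially-unaware analysis: PCA, PC significance, SNN communities,
# 2-D embeddings, differential peaks, NMF.

test_that("pcaEmbed reproduces a direct eigendecomposition of the correlation", {
  set.seed(10)
  X <- matrix(rnorm(10 * 5), 10, 5)
  map <- mkMap(X, gridShape = c(2, 5))
  emb <- pcaEmbed(map, nDims = 4)
  # oracle: eigendecomposition of the channel correlation matrix
  Xs <- scale(X)
  eig <- eigen(stats::cov(Xs), symmetric = TRUE)
  oracleScores <- Xs %*% eig$vectors[, 1:4]
  for (j in 1:4) {
    s <- sign(sum(emb@scores[, j] * oracleScores[, j]))
    expect_equal(emb@scores[, j], s * oracleScores[, j], tolerance = 1e-8)
  }
  expect_true(all(diff(emb@explainedVariance) <= 1e-12))
  expect_equal(crossprod(emb@loadings), diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(pcaEmbed(map, nDims = 50), "nDims")
})

test_that("rank-1 data puts all variance on the first component", {
  t <- seq(0, 1, length.out = 20)
  X <- cbind(t, 2 * t) + 0  # exactly collinear channels
  map <- mkMap(X, gridShape = c(4, 5))
  emb <- pcaEmbed(map, nDims = 2)
  expect_equal(emb@explainedVariance[1], 1, tolerance = 1e-10)
})

test_that("permutation PC significance is calibrated on noise and detects a planted signal", {
  # null: fraction of p < 0.05 within 3 binomial SEs of 0.05 over dims x reps
  ps <- c()
  for (rep in 1:20) {
    set.seed(rep * 100)
    m <- mkMap(matrix(rnorm(60 * 100), 60, 100), gridShape = c(6, 10))
    ps <- c(ps, pcSignificance(m, nDims = 10, nPerm = 100, frac = 0.1,
                               seed = rep))
  }
  band <- 3 * sqrt(0.05 * 0.95 / length(ps))
  expect_lt(abs(mean(ps < 0.05) - 0.05), band)
  # planted rank-1 signal at 10x noise SD: dim 1 at the permutation floor
  set.seed(11)
  S <- matrix(rnorm(60 * 100), 60, 100) +
    10 * outer(rnorm(60), rnorm(100)) / sqrt(60)
  m2 <- mkMap(S, gridShape = c(6, 10))
  p2 <- pcSignificance(m2, nDims = 5, nPerm = 100, frac = 0.1, seed = 12)
  expect_equal(p2[1], 1 / 101)
  # determinism under the seed
  expect_identical(p2, pcSignificance(m2, nDims = 5, nPerm = 100, frac = 0.1,
                                      seed = 12))
  expect_error(pcSignificance(m2, nPerm = 0), "nPerm")
})

test_that("SNN clustering recovers well-separated blobs across 10 seeds", {
  for (s in 1:10) {
    b <- mkBlobs(s)
    cl <- snnCluster(b$X, kNeighbors = 15, resolution = 0.05, seed = s)
    expect_identical(cl@k, 2L)
    expect_equal(adjustedRand(cl, b$truth), 1.0)
  }
})

test_that("SNN clustering contracts: identical points, size ordering, monotone resolution", {
  # all points identical -> one cluster
  cl1 <- snnCluster(matrix(1, 30, 2), kNeighbors = 5, seed = 1)
  expect_identical(cl1@k, 1L)
  expect_error(snnCluster(matrix(1, 10, 2), kNeighbors = 10), "kNeighbors")
  # labels ordered by descending cluster size
  b <- mkBlobs(1, nPerBlob = 150)
  X <- rbind(b$X, matrix(rnorm(100), 50, 2) + 50)
  cl <- snnCluster(X, kNeighbors = 15, resolution = 0.05, seed = 2)
  sizes <- as.integer(table(clusterLabels(cl)))
  expect_true(all(diff(sizes) <= 0))
  # cluster count non-decreasing in resolution on fixed data
  ks <- vapply(c(0.2, 0.5, 1.0, 2.0), function(r)
    snnCluster(b$X, kNeighbors = 15, resolution = r, seed = 3)@k, 0L)
  expect_true(all(diff(ks) >= 0))
})

test_that("2-D embeddings have one coordinate per pixel and are seed-stable", {
  set.seed(20)
  X <- matrix(rnorm(80 * 5), 80, 5)
  emb <- mkEmbedding(X)
  yt <- embed2D(emb, "tsne", perplexity = 10, seed = 5)
  expect_identical(dim(yt), c(80L, 2L))
  expect_identical(yt, embed2D(emb, "tsne", perplexity = 10, seed = 5))
  yu <- embed2D(emb, "umap", seed = 5)
  expect_identical(dim(yu), c(80L, 2L))
  expect_identical(yu, embed2D(emb, "umap", seed = 5))
  expect_error(embed2D(emb, "tsne", perplexity = 100), "perplexity")
  # duplicated input points land nearer each other than the median distance
  Xd <- rbind(X, X[1:5, ])
  yd <- embed2D(mkEmbedding(Xd), "tsne", perplexity = 10, seed = 6)
  dupDist <- sqrt(rowSums((yd[81:85, ] - yd[1:5, ])^2))
  expect_lt(max(dupDist), median(dist(yd)))
})

test_that("differential peaks rank a planted doubled channel first with the closed-form fold change", {
  set.seed(21)
  mu <- 10
  n <- 40
  X <- matrix(rpois(2 * n * 30, mu), 2 * n, 30) + 0
  X[1:n, 7] <- 2 * X[1:n, 7]  # channel 7 doubled in cluster A
  map <- mkMap(X, gridShape = c(8, 10))
  labels <- ClusterLabels(rep(c(1, 0), each = n), seq_len(2 * n))
  # relabelling is size-ordered; recover which label is the doubled group
  aLab <- clusterLabels(labels)[1]
  tab <- differentialPeaks(map, labels)
  top <- tab[tab$cluster == aLab, ][1, ]
  expect_equal(top$wavenumber, wavenumbers(map)[7])
  expect_lt(abs(top$avg_log2fc - (log2(2 * mu + 1) - log2(mu + 1))), 0.05)
  expect_true(all(tab$p_adjusted >= 0) && all(tab$p_adjusted <= 1))
  # wavenumbers reported rounded to one decimal
  map2 <- mkMap(X, gridShape = c(8, 10), axis = seq(400.123, by = 2.04,
                                                    length.out = 30))
  tab2 <- differentialPeaks(map2, labels)
  expect_identical(tab2$wavenumber, round(tab2$wavenumber, 1))
})

test_that("differential peaks control type I error on identical distributions", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    X <- matrix(rnorm(40 * 25, 10), 40, 25)
    map <- mkMap(X, gridShape = c(8, 5))
    labels <- ClusterLabels(rep(0:1, each = 20), seq_len(40))
    tab <- differentialPeaks(map, labels)
    any(tab$p_adjusted < 0.05)
  }, TRUE)
  expect_gte(mean(!hits), 0.95)
})

test_that("NMF recovers an exact non-negative factorization and respects contracts", {
  set.seed(22)
  W <- matrix(runif(30 * 2), 30, 2)
  H <- rbind(runif(40), runif(40))
  map <- mkMap(W %*% H, gridShape = c(5, 6))
  fit <- nmfComponents(map, k = 2, seed = 1, maxIter = 2000)
  expect_lt(fit$relError, 1e-3)
  expect_true(all(fit$spectra >= 0) && all(fit$abundances >= 0))
  # k = 1 on a constant-spectrum map recovers that spectrum up to scale
  spec1 <- runif(40)
  map1 <- mkMap(outer(runif(20, 0.5, 2), spec1), gridShape = c(4, 5))
  f1 <- nmfComponents(map1, k = 1, seed = 1)
  cosine <- sum(f1$spectra * spec1) /
    sqrt(sum(f1$spectra^2) * sum(spec1^2))
  expect_gte(cosine, 0.999)
  # negative intensities are clipped with a warning
  mapNeg <- mkMap(matrix(c(-1, runif(39 * 4 + 3)), 4, 40), gridShape = c(2, 2))
  expect_warning(nmfComponents(mapNeg, k = 1, seed = 1), "clipped")
})
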