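# Shared fixtures, built in code at test time.

# wrap a bare score matrix as an Embedding
mkEmbedding <- function(X, pixels = seq_len(nrow(X))) {
  new("Embedding", scores = as.matrix(X), loadings = matrix(0, 0, 0),
      explainedVariance = numeric(0), center = numeric(0),
      scaling = numeric(0), pixels = as.integer(pixels), method = "direct")
}

# two Gaussian blobs separated by `sep` standard deviations
mkBlobs <- function(seed, nPerBlob = 200, d = 2, sep = 20) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(nPerBlob * d), nPerBlob, d),
             matrix(stats::rnorm(nPerBlob * d), nPerBlob, d) + sep)
  list(X = X, truth = rep(0:1, each = nPerBlob))
}

# planted two-region lattice embedding: top/bottom halves of a rows x cols
# grid with means `sep` noise-SDs apart in the first dimension
mkTwoRegionGrid <- function(seed, rows = 40, cols = 40, d = 5, sep = 2) {
  set.seed(seed)
  n <- rows * cols
  truth <- as.integer((seq_len(n) - 1L) %/% cols >= rows / 2)
  Y <- matrix(stats::rnorm(n * d), n, d)
  Y[truth == 1L, 1L] <- Y[truth == 1L, 1L] + sep
  list(emb = mkEmbedding(Y), truth = truth,
       grid = gridNeighbors(c(rows, cols), 4L))
}

# three horizontal bands on a lattice, well separated in 2 of d dims
mkThreeRegionGrid <- function(seed, rows = 24, cols = 24, d = 5, sep = 3) {
  set.seed(seed)
  n <- rows * cols
  truth <- as.integer(pmin((seq_len(n) - 1L) %/% (n / 3), 2))
  mu <- rbind(rep(0, d), c(sep, rep(0, d - 1)), c(0, sep, rep(0, d - 2)))
  Y <- matrix(stats::rnorm(n * d), n, d) + mu[truth + 1L, ]
  list(emb = mkEmbedding(Y), truth = truth,
       grid = gridNeighbors(c(rows, cols), 4L))
}

# small flat SpectralMap with given intensity matrix
mkMap <- function(X, gridShape = NULL, axis = NULL, pixelSize = 1) {
  X <- as.matrix(X)
  if (is.null(gridShape)) gridShape <- c(nrow(X), 1L)
  if (is.null(axis)) axis <- seq(400, by = 2, length.out = ncol(X))
  SpectralMap(axis, X, gridShape, pixelSize = pixelSize)
}

# brute-force tricube local weighted least squares (independent oracle via
# stats::loess exact direct fit)
oracleLoess <- function(x, y, span = 0.75, degree = 2) {
  unname(stats::predict(stats::loess(y ~ x, span = span, degree = degree,
                                     surface = "direct")))
}
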