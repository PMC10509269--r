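# Spatially-unaware analysis: standardized PCA, permutation-based component
# significance, SNN-graph communities, 2-D embeddings, differential peaks,
# and NMF component maps (true-component-analysis analog).

#' Channel-standardized PCA of retained pixel spectra
#'
#' Channels are centred and scaled to unit variance (constant channels get
#' scale 1), then decomposed; scores reproduce the eigendecomposition of the
#' channel correlation matrix. More than ~20 components rarely improve
#' downstream clustering of Raman scans, hence the default.
#'
#' @param map a [SpectralMap-class].
#' @param nDims number of components (default 20); must not exceed
#'   `min(nRetainedPixels, nChannels)`.
#' @return An [Embedding-class] with orthonormal loadings and non-increasing
#'   explained-variance fractions.
#' @export
pcaEmbed <- function(map, nDims = 20L) {
  rm <- retainedMatrix(map)
  X <- rm$matrix
  if (nDims > min(nrow(X), ncol(X)))
    stop("nDims exceeds min(nRetainedPixels, nChannels)")
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE, rank. = nDims)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  new("Embedding",
      scores = pc$x[, seq_len(nDims), drop = FALSE],
      loadings = pc$rotation[, seq_len(nDims), drop = FALSE],
      explainedVariance = ev[seq_len(nDims)],
      center = ctr, scaling = scl, pixels = rm$pixels, method = "pca")
}

#' Permutation significance of principal components
#'
#' For each permutation a fraction of channels is independently shuffled
#' across pixels and the PCA recomputed; the per-dimension p-value compares
#' the observed component variance against the permutation null:
#' `p_j = (1 + #\{lambda_j^perm >= lambda_j\}) / (nPerm + 1)`.
#'
#' @param map a [SpectralMap-class].
#' @param nDims dimensions to score (default 20).
#' @param nPerm permutations (default 100, `>= 1`).
#' @param frac fraction of channels shuffled per permutation, in (0, 1)
#'   (default 0.1).
#' @param seed RNG seed.
#' @return numeric per-dimension p-values.
#' @export
pcSignificance <- function(map, nDims = 20L, nPerm = 100L, frac = 0.1,
                           seed = 1L) {
  if (nPerm < 1L) stop("nPerm must be >= 1")
  if (frac <= 0 || frac >= 1) stop("frac must be in (0, 1)")
  rm <- retainedMatrix(map)
  X <- rm$matrix
  nDims <- min(nDims, nrow(X) - 1L, ncol(X))
  scl <- apply(X, 2L, stats::sd); scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2L, colMeans(X)), 2L, scl, "/")
  eig <- function(M) {
    s <- svd(M, nu = 0, nv = 0)$d[seq_len(nDims)]
    s^2
  }
  obs <- eig(Xs)
  nShuffle <- max(1L, round(frac * ncol(Xs)))
  set.seed(seed)
  exceed <- numeric(nDims)
  for (b in seq_len(nPerm)) {
    cols <- sample.int(ncol(Xs), nShuffle)
    Xp <- Xs
    for (j in cols) Xp[, j] <- Xp[sample.int(nrow(Xp)), j]
    exceed <- exceed + (eig(Xp) >= obs)
  }
  (1 + exceed) / (nPerm + 1)
}

# kNN indices by brute-force distances (desk-scale pixel counts)
.knnIndex <- function(X, k) {
  d <- as.matrix(stats::dist(X))
  diag(d) <- Inf
  t(apply(d, 1L, function(r) order(r)[seq_len(k)]))
}

# shared-nearest-neighbor graph: edge weight = Jaccard of kNN sets, over
# the union of directed kNN pairs (so no kNN relation is dropped)
.snnGraph <- function(X, k) {
  nn <- .knnIndex(X, k)
  n <- nrow(X)
  sets <- lapply(seq_len(n), function(i) c(i, nn[i, ]))
  pairs <- unique(cbind(pmin(rep(seq_len(n), each = k), as.vector(t(nn))),
                        pmax(rep(seq_len(n), each = k), as.vector(t(nn)))))
  w <- vapply(seq_len(nrow(pairs)), function(e) {
    i <- pairs[e, 1L]; j <- pairs[e, 2L]
    length(intersect(sets[[i]], sets[[j]])) /
      length(union(sets[[i]], sets[[j]]))
  }, 0)
  keep <- w > 0
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(pairs[keep, , drop = FALSE]))
  igraph::E(g)$weight <- w[keep]
  g
}

# merge singleton communities into the cluster they are most strongly
# connected to (by total SNN edge weight); unconnected singletons stay
.groupSingletons <- function(memb, g) {
  tab <- table(memb)
  singles <- as.integer(names(tab)[tab == 1L])
  for (s in singles) {
    v <- which(memb == s)
    inc <- igraph::incident(g, v)
    if (!length(inc)) next
    ends <- igraph::ends(g, inc)
    other <- ifelse(ends[, 1L] == v, ends[, 2L], ends[, 1L])
    wsum <- tapply(igraph::E(g)$weight[as.integer(inc)], memb[other], sum)
    wsum <- wsum[as.integer(names(wsum)) != s]
    if (length(wsum)) memb[v] <- as.integer(names(wsum)[which.max(wsum)])
  }
  memb
}

#' Shared-nearest-neighbor community clustering
#'
#' Builds a kNN graph in embedding space, weights edges by the Jaccard
#' similarity of neighbour sets, and runs Louvain modularity community
#' detection at the given resolution. Disconnected graph components are
#' clustered independently (Louvain handles them natively); singleton
#' communities are merged into their strongest-connected cluster.
#' Deterministic given the seed; label ids are ordered by descending
#' cluster size.
#'
#' @param emb an [Embedding-class] (or a bare score matrix).
#' @param kNeighbors neighbours per pixel (default 20), `< nPixels`.
#' @param resolution Louvain resolution (default 0.8).
#' @param seed RNG seed (default 7).
#' @return A [ClusterLabels-class].
#' @export
snnCluster <- function(emb, kNeighbors = 20L, resolution = 0.8, seed = 7L) {
  X <- if (is(emb, "Embedding")) emb@scores else as.matrix(emb)
  pixels <- if (is(emb, "Embedding")) emb@pixels else seq_len(nrow(X))
  if (kNeighbors >= nrow(X)) stop("kNeighbors must be < number of pixels")
  if (all(X == rep(X[1, ], each = nrow(X))))  # degenerate: all points equal
    return(ClusterLabels(rep(0L, nrow(X)), pixels, method = "snn",
                         params = list(kNeighbors = kNeighbors,
                                       resolution = resolution),
                         seed = seed))
  g <- .snnGraph(X, kNeighbors)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- .groupSingletons(as.integer(igraph::membership(comm)), g)
  ClusterLabels(memb, pixels, method = "snn",
                params = list(kNeighbors = kNeighbors, resolution = resolution),
                seed = seed)
}

#' 2-D embedding for visualization (tSNE or UMAP)
#'
#' @param emb an [Embedding-class].
#' @param method `"tsne"` (default, perplexity 30) or `"umap"`.
#' @param perplexity tSNE perplexity; must satisfy
#'   `3 * perplexity < nPixels - 1`.
#' @param seed RNG seed (default 7). Fixed seed gives identical coordinates
#'   across runs.
#' @return numeric matrix `nRetainedPixels x 2`.
#' @export
embed2D <- function(emb, method = c("tsne", "umap"), perplexity = 30,
                    seed = 7L) {
  method <- match.arg(method)
  X <- emb@scores
  set.seed(seed)
  if (method == "tsne") {
    if (perplexity >= nrow(X)) stop("perplexity must be < number of pixels")
    if (3 * perplexity >= nrow(X) - 1)
      perplexity <- floor((nrow(X) - 2) / 3)
    out <- Rtsne::Rtsne(X, dims = 2, perplexity = perplexity,
                        pca = FALSE, check_duplicates = FALSE)$Y
  } else {
    out <- uwot::umap(X, n_neighbors = min(15L, nrow(X) - 1L),
                      n_threads = 1L, n_sgd_threads = 1L, batch = TRUE)
  }
  unname(out)
}

#' Differential Raman peaks per cluster
#'
#' One-vs-rest Wilcoxon rank-sum per channel;
#' `avg_log2fc = log2(mean_in + 1) - log2(mean_out + 1)`; Bonferroni
#' adjustment (across the whole cluster x channel table) by default,
#' Benjamini-Hochberg optional. Reported wavenumbers
#' are rounded to one decimal place. Clusters of size 1 are skipped with a
#' warning. Rows are sorted within cluster by `avg_log2fc` descending.
#'
#' @param map a [SpectralMap-class].
#' @param labels a [ClusterLabels-class] with `k >= 2`.
#' @param adjust `"bonferroni"` (default) or `"BH"`.
#' @return data.frame with columns cluster, wavenumber, avg_log2fc, p_raw,
#'   p_adjusted, fraction_in, fraction_out.
#' @export
differentialPeaks <- function(map, labels, adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  if (labels@k < 2L) stop("need at least 2 clusters")
  X <- intensities(map)[labels@pixels, , drop = FALSE]
  wn <- wavenumbers(map)
  out <- list()
  for (cl in seq(0L, labels@k - 1L)) {
    inCl <- labels@labels == cl
    if (sum(inCl) < 2L) {
      warning("cluster ", cl, " has fewer than 2 pixels; skipped")
      next
    }
    A <- X[inCl, , drop = FALSE]; B <- X[!inCl, , drop = FALSE]
    p <- vapply(seq_len(ncol(X)), function(j)
      stats::wilcox.test(A[, j], B[, j], exact = FALSE)$p.value, 0)
    mIn <- colMeans(A); mOut <- colMeans(B)
    df <- data.frame(
      cluster = cl,
      wavenumber = round(wn, 1L),
      avg_log2fc = log2(mIn + 1) - log2(mOut + 1),
      p_raw = p,
      fraction_in = colMeans(A > 0),
      fraction_out = colMeans(B > 0))
    out[[length(out) + 1L]] <- df[order(-df$avg_log2fc), ]
  }
  res <- do.call(rbind, out)
  res$p_adjusted <- pmin(1, stats::p.adjust(res$p_raw, method = adjust))
  res <- res[, c("cluster", "wavenumber", "avg_log2fc", "p_raw",
                 "p_adjusted", "fraction_in", "fraction_out")]
  rownames(res) <- NULL
  res
}

#' Non-negative matrix factorization component maps
#'
#' True-component-analysis analog: factors the non-negative pixel x channel
#' matrix into `k` component spectra and per-pixel abundances by
#' multiplicative updates (Frobenius loss). Negative intensities (possible
#' after baseline correction) are clipped at 0 with a warning.
#'
#' @param map a [SpectralMap-class].
#' @param k number of components, `>= 1`.
#' @param seed RNG seed for the initialization (default 7).
#' @param maxIter update iterations (default 500).
#' @param tol relative loss-change convergence tolerance (default 1e-8).
#' @return list with `spectra` (`k x nChannels`), `abundances`
#'   (`nRetainedPixels x k`), `pixels`, and `relError` (relative Frobenius
#'   reconstruction error).
#' @export
nmfComponents <- function(map, k, seed = 7L, maxIter = 500L, tol = 1e-8) {
  if (k < 1L) stop("k must be >= 1")
  rm <- retainedMatrix(map)
  X <- rm$matrix
  if (any(X < 0)) {
    warning("negative intensities clipped at 0 for NMF")
    X[X < 0] <- 0
  }
  set.seed(seed)
  n <- nrow(X); m <- ncol(X)
  W <- matrix(stats::runif(n * k, 0.1, 1), n, k) * sqrt(mean(X) / k)
  H <- matrix(stats::runif(k * m, 0.1, 1), k, m) * sqrt(mean(X) / k)
  eps <- .Machine$double.eps
  lossOld <- Inf
  for (it in seq_len(maxIter)) {
    H <- H * (crossprod(W, X) / (crossprod(W) %*% H + eps))
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
    if (it %% 10L == 0L) {
      loss <- sum((X - W %*% H)^2)
      if (is.finite(lossOld) && abs(lossOld - loss) <= tol * lossOld) break
      lossOld <- loss
    }
  }
  relErr <- sqrt(sum((X - W %*% H)^2) / max(sum(X^2), eps))
  list(spectra = H, abundances = W, pixels = rm$pixels, relError = relErr)
}
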