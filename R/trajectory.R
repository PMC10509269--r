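# Pseudotime principal trees, straight-line spatial trajectories, loess
# profiles, and the dynamics statistics along them.

#' Principal tree pseudotime ordering
#'
#' Simplified reversed-graph-embedding: alternating soft assignment of
#' pixels to latent nodes (Gaussian responsibilities), node position updates
#' (responsibility-weighted means), and a minimum spanning tree over the
#' nodes, iterated until node movement falls below `tol`. Pseudotime is the
#' geodesic (tree) distance of each pixel's assigned node from the root;
#' branch points are tree nodes of degree >= 3.
#'
#' @param emb an [Embedding-class].
#' @param nNodes latent nodes, `2 <= nNodes < nPixels` (default 20).
#' @param root `"auto"` (the tree leaf with the largest total geodesic
#'   distance to all nodes) or a pixel index (1-based into the embedding
#'   rows); the root node is that pixel's assigned node.
#' @param seed RNG seed (default 7).
#' @param maxIter alternating iterations (default 50).
#' @param tol node-movement convergence threshold (default 1e-4).
#' @return A [PrincipalTree-class].
#' @export
principalTree <- function(emb, nNodes = 20L, root = "auto", seed = 7L,
                          maxIter = 50L, tol = 1e-4) {
  X <- emb@scores
  if (nNodes < 2L) stop("nNodes must be >= 2")
  if (nNodes >= nrow(X)) stop("nNodes must be < number of pixels")
  set.seed(seed)
  km <- stats::kmeans(X, centers = nNodes, nstart = 5L, iter.max = 50L)
  M <- km$centers
  sigma2 <- mean(km$withinss / pmax(km$size, 1L)) + 1e-12
  for (it in seq_len(maxIter)) {
    D2 <- outer(rowSums(X^2), rowSums(M^2), "+") - 2 * X %*% t(M)
    R <- exp(-(D2 - .rowMinMatrix(D2)) / (2 * sigma2))
    R <- R / rowSums(R)
    Mnew <- (t(R) %*% X) / pmax(colSums(R), 1e-12)
    move <- max(abs(Mnew - M))
    M <- Mnew
    if (move < tol) break
  }
  # hard assignment + MST over node distances
  D2 <- outer(rowSums(X^2), rowSums(M^2), "+") - 2 * X %*% t(M)
  assign <- max.col(-D2)
  nodeD <- as.matrix(stats::dist(M))
  g <- igraph::graph_from_adjacency_matrix(nodeD, mode = "undirected",
                                           weighted = TRUE)
  mst <- igraph::mst(g)
  geo <- igraph::distances(mst)
  deg <- igraph::degree(mst)
  if (identical(root, "auto")) {
    leaves <- which(deg == 1L)
    rootNode <- leaves[which.max(rowSums(geo)[leaves])]
  } else {
    rootNode <- assign[root]
  }
  edges <- igraph::as_edgelist(mst, names = FALSE)
  storage.mode(edges) <- "integer"
  new("PrincipalTree",
      nodePositions = unname(M), edges = edges,
      nodeAssignment = as.integer(assign), root = as.integer(rootNode),
      pseudotime = as.numeric(geo[rootNode, assign]),
      branchPoints = as.integer(which(deg >= 3L)), pixels = emb@pixels)
}

# rowwise minimum broadcast to a matrix (keeps exp() overflow-safe)
.rowMinMatrix <- function(M) {
  matrix(apply(M, 1L, min), nrow(M), ncol(M))
}

#' Straight-line trajectory across the pixel grid
#'
#' Bresenham (8-connected) rasterization from `start` to `end`, both
#' inclusive; the cumulative distance is the Euclidean distance between
#' successive pixel centres times the pixel size.
#'
#' @param map a [SpectralMap-class].
#' @param start,end 0-based `(row, col)` inside the grid.
#' @return A [Trajectory-class].
#' @export
sampleLineTrajectory <- function(map, start, end) {
  shape <- gridShape(map)
  start <- as.integer(start); end <- as.integer(end)
  for (p in list(start, end))
    if (any(p < 0L) || p[1L] >= shape[1L] || p[2L] >= shape[2L])
      stop("trajectory endpoint outside the grid")
  r0 <- start[1L]; c0 <- start[2L]; r1 <- end[1L]; c1 <- end[2L]
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  err <- dc - dr
  pts <- matrix(NA_integer_, dr + dc + 1L, 2L)
  i <- 0L
  repeat {
    i <- i + 1L
    pts[i, ] <- c(r0, c0)
    if (r0 == r1 && c0 == c1) break
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c0 <- c0 + sc }
    if (e2 < dc) { err <- err + dc; r0 <- r0 + sr }
  }
  pts <- pts[seq_len(i), , drop = FALSE]
  step <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                        pts[-i, , drop = FALSE])^2)) * pixelSize(map)
  new("Trajectory", start = start, end = end, pixels = pts,
      distance = c(0, cumsum(step)))
}

#' Log2-normalized intensity profile along a trajectory
#'
#' Per wavenumber, the series is `log2((I + 1) / (mean I + 1))` with the
#' mean over the trajectory's retained positions; a loess fit with a 0.95
#' confidence band is attached per wavenumber. QC-dropped pixels are
#' skipped (their position gap is preserved in the distances).
#'
#' @param map a [SpectralMap-class].
#' @param traj a [Trajectory-class].
#' @param labels optional [ClusterLabels-class]; records the cluster at
#'   each position.
#' The default smoothing window covers ~12 trajectory positions (capped at
#' a 0.75 span for short trajectories): at micrometre pixel pitch this
#' preserves tissue-boundary transitions that a fixed 0.75 span would
#' flatten on long trajectories.
#'
#' @param span loess span; `NULL` (default) uses `min(0.75, 12/n)`.
#' @param degree loess polynomial degree (default 2).
#' @return A [TrajectoryProfile-class].
#' @export
trajectoryProfile <- function(map, traj, labels = NULL, span = NULL,
                              degree = 2L) {
  shape <- gridShape(map)
  idx <- pixelIndex(map)
  rowMajorOf <- idx[, 1L] * shape[2L] + idx[, 2L] + 1L
  mapRow <- match(traj@pixels[, 1L] * shape[2L] + traj@pixels[, 2L] + 1L,
                  rowMajorOf)
  keep <- qcMask(map)[mapRow]
  mapRow <- mapRow[keep]
  positions <- traj@distance[keep]
  X <- intensities(map)[mapRow, , drop = FALSE]
  mu <- colMeans(X)
  S <- log2(sweep(X + 1, 2L, mu + 1, "/"))
  nP <- nrow(S); nC <- ncol(S)
  if (is.null(span))
    span <- min(0.75, max(12 / nP, (degree + 2) / nP))
  fitted <- ciL <- ciU <- matrix(NA_real_, nP, nC)
  for (j in seq_len(nC)) {
    f <- loessFit(positions, S[, j], span = span, degree = degree)
    fitted[, j] <- f$fitted
    ciL[, j] <- f$ciLower
    ciU[, j] <- f$ciUpper
  }
  clusterAt <- rep(NA_integer_, nP)
  if (!is.null(labels)) {
    m <- match(mapRow, labels@pixels)
    clusterAt <- labels@labels[m]
  }
  new("TrajectoryProfile", trajectory = traj, wavenumbers = wavenumbers(map),
      series = S, fitted = fitted, ciLower = ciL, ciUpper = ciU,
      clusterAt = clusterAt, positions = positions)
}

#' Tricube-weighted local polynomial regression (loess) with 0.95 CI
#'
#' Exact per-point fit: at each `x_i` a degree-`degree` polynomial is fitted
#' by weighted least squares with tricube weights over the
#' `q = max(floor(span * n), degree + 1)` nearest neighbours; the pointwise
#' 0.95 confidence band uses the local linear-smoother norm with a global
#' residual variance estimate.
#'
#' @param x positions (need not be sorted).
#' @param y values, same length.
#' @param span neighbourhood fraction (default 0.75).
#' @param degree polynomial degree (default 2); needs
#'   `length(x) >= degree + 2`.
#' @return list with `fitted`, `ciLower`, `ciUpper`, `sigma`.
#' @export
loessFit <- function(x, y, span = 0.75, degree = 2L) {
  n <- length(x)
  if (n < degree + 2L) stop("need at least degree + 2 points")
  q <- max(floor(span * n), degree + 1L)
  q <- min(q, n)
  fitted <- numeric(n)
  l2 <- numeric(n)  # squared norm of the equivalent-kernel row
  trL <- 0
  for (i in seq_len(n)) {
    d <- abs(x - x[i])
    qi <- q
    repeat {
      dq <- sort(d, partial = qi)[qi]
      if (dq == 0) dq <- .Machine$double.eps
      w <- pmax(1 - (d / dq)^3, 0)^3
      use <- w > 0
      # tricube is 0 at the qi-th distance itself; widen the local window
      # when gaps leave too few interior points for the polynomial
      if (sum(use) >= degree + 1L || qi >= n) break
      qi <- qi + 1L
    }
    if (sum(use) < degree + 1L) {
      dq <- max(d) * 1.05
      w <- pmax(1 - (d / dq)^3, 0)^3
      use <- w > 0
    }
    if (sum(use) < degree + 1L)
      stop("span too small: local window underpopulated")
    B <- outer(x[use] - x[i], 0:degree, `^`)
    Wb <- w[use] * B
    A <- crossprod(B, Wb)
    # equivalent kernel row: fitted_i = e1' (B'WB)^-1 B'W y
    li <- rep(0, n)
    li[use] <- drop(solve(A, t(Wb))[1L, ])
    fitted[i] <- sum(li * y)
    l2[i] <- sum(li^2)
    trL <- trL + li[i]
  }
  res <- y - fitted
  dfRes <- max(n - trL, 1)
  sigma2 <- sum(res^2) / dfRes
  half <- 1.96 * sqrt(sigma2 * l2)
  list(fitted = fitted, ciLower = fitted - half, ciUpper = fitted + half,
       sigma = sqrt(sigma2))
}

#' Dynamics statistics along a trajectory
#'
#' For each (cluster, wavenumber), restricted to that cluster's positions:
#' `max_variability` is the range of the loess curve (max - min);
#' the derivative is the successive difference of loess values per pixel
#' step, and `dynamic_fraction` is the share of defined steps with
#' `|derivative| > threshold` (default 0.4). Clusters with fewer than 2
#' positions on the trajectory are skipped with a warning.
#'
#' @param profile a [TrajectoryProfile-class].
#' @param threshold absolute derivative threshold (default 0.4).
#' @return data.frame with columns cluster, wavenumber, max_variability,
#'   dynamic_fraction.
#' @export
dynamicsMetrics <- function(profile, threshold = 0.4) {
  cl <- profile@clusterAt
  clusters <- sort(unique(cl[!is.na(cl)]))
  if (!length(clusters)) clusters <- NA_integer_
  out <- list()
  for (k in clusters) {
    pos <- if (is.na(k)) seq_along(cl) else which(!is.na(cl) & cl == k)
    if (length(pos) < 2L) {
      warning("cluster ", k, " has < 2 trajectory positions; skipped")
      next
    }
    Fk <- profile@fitted[pos, , drop = FALSE]
    mv <- apply(Fk, 2L, function(v) max(v) - min(v))
    dfrac <- apply(Fk, 2L, function(v) {
      dv <- diff(v)
      mean(abs(dv) > threshold)
    })
    out[[length(out) + 1L]] <- data.frame(
      cluster = k, wavenumber = profile@wavenumbers,
      max_variability = mv, dynamic_fraction = dfrac)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare dynamics metrics between two clusters
#'
#' Pairs the per-wavenumber metric values of two clusters and reports both
#' the paired t-test on the differences (primary) and the Welch unpaired
#' two-sample t-test; two-sided p-values. All-zero differences give
#' statistic 0 and p = 1 by convention.
#'
#' @param table a [dynamicsMetrics()] data.frame.
#' @param clusterA,clusterB cluster ids to compare.
#' @param metric `"dynamic_fraction"` (default) or `"max_variability"`.
#' @return list with `paired` and `welch`, each `(statistic, p.value)`, and
#'   `meanDifference` (A - B).
#' @export
compareClustersDynamics <- function(table, clusterA, clusterB,
                                    metric = c("dynamic_fraction",
                                               "max_variability")) {
  metric <- match.arg(metric)
  a <- table[table$cluster == clusterA, c("wavenumber", metric)]
  b <- table[table$cluster == clusterB, c("wavenumber", metric)]
  m <- merge(a, b, by = "wavenumber", suffixes = c(".a", ".b"))
  if (!nrow(m)) stop("no shared wavenumbers between the clusters")
  va <- m[[paste0(metric, ".a")]]; vb <- m[[paste0(metric, ".b")]]
  d <- va - vb
  if (all(d == 0)) {
    paired <- list(statistic = 0, p.value = 1)
  } else {
    tt <- stats::t.test(va, vb, paired = TRUE)
    paired <- list(statistic = unname(tt$statistic), p.value = tt$p.value)
  }
  if (stats::sd(va) == 0 && stats::sd(vb) == 0) {
    welch <- list(statistic = if (mean(d) == 0) 0 else Inf,
                  p.value = if (mean(d) == 0) 1 else 0)
  } else {
    wt <- stats::t.test(va, vb, paired = FALSE, var.equal = FALSE)
    welch <- list(statistic = unname(wt$statistic), p.value = wt$p.value)
  }
  list(paired = paired, welch = welch, meanDifference = mean(d))
}
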