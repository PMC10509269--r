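# Spatially-aware clustering: Potts-prior Bayesian mixture with
# t-distributed errors on the pixel lattice, and elbow-based model size
# selection on the negative pseudo-log-likelihood.

#' Neighbourhood graph of a pixel lattice
#'
#' @param shape `(rows, cols)`, both `>= 1`.
#' @param connectivity 4 (orthogonal neighbours) or 8 (plus diagonals);
#'   boundary pixels have truncated neighbourhoods.
#' @return A [GridGraph-class] with 1-based row-major neighbour lists.
#' @export
gridNeighbors <- function(shape, connectivity = 4L) {
  shape <- as.integer(shape)
  if (any(shape < 1L)) stop("rows and cols must be >= 1")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  nr <- shape[1L]; nc <- shape[2L]
  off <- if (connectivity == 4L)
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  else
    cbind(c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
          c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L))
  nbrs <- vector("list", nr * nc)
  for (r in seq_len(nr) - 1L) {
    for (cc in seq_len(nc) - 1L) {
      rr <- r + off[, 1L]; c2 <- cc + off[, 2L]
      ok <- rr >= 0L & rr < nr & c2 >= 0L & c2 < nc
      nbrs[[r * nc + cc + 1L]] <- rr[ok] * nc + c2[ok] + 1L
    }
  }
  new("GridGraph", shape = shape, connectivity = as.integer(connectivity),
      neighbors = nbrs)
}

#' MRF clustering configuration
#'
#' Defaults follow the conventions of t-error Potts-prior spatial clustering
#' on square lattices: `nu = 4` degrees of freedom, smoothing `gamma = 2`,
#' 2000 sweeps with the first 1000 discarded, and vague conjugate priors
#' (mean prior variance `tau2Factor` times the mean data variance; Wishart
#' prior degrees of freedom `nDims + 2` centred on the sample precision).
#'
#' @param q number of clusters, `>= 1`.
#' @param gamma Potts smoothing strength, `>= 0` (0 = non-spatial mixture).
#' @param nu t degrees of freedom; `Inf` gives Gaussian errors.
#' @param nDims embedding dimensions used (default 20).
#' @param nIter total Gibbs sweeps (default 2000), `> burnIn`.
#' @param burnIn discarded sweeps (default 1000).
#' @param seed RNG seed (default 7).
#' @param tau2Factor mean-prior variance as a multiple of the mean data
#'   variance (default 100).
#' @return A validated list of class `MRFConfig`.
#' @export
mrfConfig <- function(q, gamma = 2, nu = 4, nDims = 20L, nIter = 2000L,
                      burnIn = 1000L, seed = 7L, tau2Factor = 100) {
  if (q < 1L) stop("q must be >= 1")
  if (gamma < 0) stop("gamma must be >= 0")
  if (nIter <= burnIn) stop("nIter must exceed burnIn")
  cfg <- list(q = as.integer(q), gamma = gamma, nu = nu,
              nDims = as.integer(nDims), nIter = as.integer(nIter),
              burnIn = as.integer(burnIn), seed = as.integer(seed),
              tau2Factor = tau2Factor)
  class(cfg) <- "MRFConfig"
  cfg
}

#' Potts single-site conditional probabilities
#'
#' The exact full conditional the Gibbs sampler draws from:
#' `p(z_i = k) \propto lik[k] * exp(gamma * #\{j in N(i): z_j = k\})`.
#' Exposed so it can be validated against exhaustive enumeration.
#'
#' @param lik likelihood values per label (length q, not necessarily
#'   normalized).
#' @param neighborLabels 0-based labels of the site's neighbours.
#' @param gamma Potts smoothing strength.
#' @return Normalized probability vector of length q.
#' @export
pottsSiteConditional <- function(lik, neighborLabels, gamma) {
  as.numeric(.pottsSiteProbs(log(lik), as.integer(neighborLabels), gamma))
}

#' Fit the spatially-aware cluster model
#'
#' Bayesian mixture in embedding space with multivariate-t errors
#' (per-pixel Gamma(nu/2, nu/2) scale weights, shared covariance) and a
#' Potts prior over lattice neighbours:
#' `p(z_i = k | z_N(i)) \propto exp(gamma * #\{j in N(i): z_j = k\})`.
#' Conjugate Gibbs updates for the means and shared precision, Gamma updates
#' for the weights, and single-site updates for the labels from the exact
#' full conditional. Final labels are the per-pixel posterior mode over
#' post-burn-in sweeps. Labels are initialized by seeded k-means. An empty
#' cluster during sampling is re-seeded from the worst-fitting pixel.
#'
#' @param emb an [Embedding-class]; score rows must align with the grid's
#'   retained pixels.
#' @param grid a [GridGraph-class] over the same pixels (use
#'   [retainedGridGraph()] when QC dropped pixels).
#' @param cfg an [mrfConfig()] list.
#' @return list with `labels` (a [ClusterLabels-class]) and `diagnostics`
#'   (negative pseudo-log-likelihood trace, per-sweep label-flip rate,
#'   total label switches, empty-cluster re-seeds).
#' @export
fitMRFClusters <- function(emb, grid, cfg) {
  if (!inherits(cfg, "MRFConfig")) stop("cfg must come from mrfConfig()")
  Y <- emb@scores[, seq_len(min(cfg$nDims, ncol(emb@scores))), drop = FALSE]
  if (nrow(Y) != length(grid@neighbors))
    stop("embedding rows must align with grid pixels")
  set.seed(cfg$seed)
  if (cfg$q == 1L) {
    zInit <- rep(0L, nrow(Y))
  } else {
    km <- stats::kmeans(Y, centers = cfg$q, nstart = 5L, iter.max = 50L)
    zInit <- km$cluster - 1L
  }
  tau2 <- cfg$tau2Factor * mean(apply(Y, 2L, stats::var))
  fit <- .mrfGibbs(Y, grid@neighbors, cfg$q, cfg$gamma, cfg$nu,
                   cfg$nIter, cfg$burnIn, tau2, zInit)
  if (fit$emptyReseeds > 0L)
    message(fit$emptyReseeds, " empty-cluster re-seed(s) during sampling")
  labels <- ClusterLabels(fit$labels, emb@pixels, method = "mrf",
                          params = unclass(cfg), seed = cfg$seed)
  diagnostics <- list(negPseudoLogLik = fit$negPseudoLogLik,
                      flipRate = fit$flipRate,
                      labelSwitches = fit$labelSwitches,
                      emptyReseeds = fit$emptyReseeds)
  list(labels = labels, diagnostics = diagnostics)
}

#' Lattice graph restricted to retained pixels
#'
#' Builds the grid graph for a map and drops QC-flagged pixels; surviving
#' neighbour lists are re-indexed to the retained subset so they align with
#' embedding score rows.
#'
#' @param map a [SpectralMap-class].
#' @param connectivity 4 or 8.
#' @return A [GridGraph-class] over retained pixels.
#' @export
retainedGridGraph <- function(map, connectivity = 4L) {
  g <- gridNeighbors(gridShape(map), connectivity)
  keep <- which(qcMask(map))
  # map row-major pixel index -> retained-order index via the pixelIndex
  idx <- pixelIndex(map)
  rowMajor <- idx[, 1L] * gridShape(map)[2L] + idx[, 2L] + 1L
  toRetained <- rep(NA_integer_, prod(gridShape(map)))
  toRetained[rowMajor[keep]] <- seq_along(keep)
  nbrs <- lapply(rowMajor[keep], function(p) {
    v <- toRetained[g@neighbors[[p]]]
    v[!is.na(v)]
  })
  new("GridGraph", shape = gridShape(map),
      connectivity = as.integer(connectivity), neighbors = nbrs)
}

# perpendicular distance of curve points to the first-to-last chord
.chordDistance <- function(x, y) {
  p1 <- c(x[1L], y[1L]); p2 <- c(x[length(x)], y[length(y)])
  v <- p2 - p1
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(rep(0, length(x)))
  # signed distance; positive on the concave (below-chord) side for a
  # decreasing convex curve
  ((x - p1[1L]) * v[2L] - (y - p1[2L]) * v[1L]) / nv
}

#' Choose the cluster count from the negative pseudo-log-likelihood elbow
#'
#' Fits the MRF model for each candidate `q`, records the converged
#' (post-burn-in mean) negative pseudo-log-likelihood, and returns the `q`
#' maximizing the perpendicular distance to the chord from the first to the
#' last curve point. A flat or convex curve (no point strictly below the
#' chord) raises a "no clear elbow" flag and returns the smallest `q`.
#'
#' @param emb an [Embedding-class].
#' @param grid a [GridGraph-class].
#' @param qRange integer candidates, at least 3 values.
#' @param cfg an [mrfConfig()] list; its `q` is overridden per candidate.
#' @return list with `q` (chosen), `curve` (data.frame q, negPLL),
#'   `noClearElbow` flag.
#' @export
selectQ <- function(emb, grid, qRange, cfg) {
  qRange <- sort(as.integer(qRange))
  if (length(qRange) < 3L) stop("qRange needs at least 3 values")
  npll <- vapply(qRange, function(qq) {
    cfg$q <- qq
    fit <- fitMRFClusters(emb, grid, cfg)
    tr <- fit$diagnostics$negPseudoLogLik
    mean(tr[(cfg$burnIn + 1L):cfg$nIter])
  }, 0)
  d <- .chordDistance(qRange, npll)
  interior <- d[-c(1L, length(d))]
  if (all(interior <= 1e-9 * max(abs(npll), 1))) {
    return(list(q = qRange[1L], curve = data.frame(q = qRange, negPLL = npll),
                noClearElbow = TRUE))
  }
  list(q = qRange[which.max(d)],
       curve = data.frame(q = qRange, negPLL = npll), noClearElbow = FALSE)
}
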