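#' @include AllClasses.R utils.R algebra.R
NULL

#' Z-score the edge distribution of an embedded network
#'
#' Networks from different modalities live on different weight scales;
#' before subtracting them their embedded edge-weight distributions are
#' standardized to mean 0 and standard deviation 1. The mean and sd are
#' estimated from exactly the off-diagonal upper triangle (each
#' unordered edge once); the diagonal is left at 0 and excluded.
#'
#' @param d a closed [DistanceNetwork-class] with finite off-diagonal
#'   entries.
#' @return list with `z` (symmetric z-scored matrix, diagonal 0),
#'   `center` and `scale` (the estimated mean and sd).
#' @export
zscoreEmbedded <- function(d) {
  stopifnot(is(d, "DistanceNetwork"))
  if (!d@isClosed)
    stop("z-scoring is defined on embedded (metrically closed) networks")
  m <- d@weights
  v <- upperValues(m)
  if (any(!is.finite(v)))
    stop("embedded network has non-finite off-diagonal entries")
  mu <- mean(v)
  sdv <- stats::sd(v)
  if (sdv == 0) stop("degenerate network: embedded edge distribution has sd 0")
  z <- (m - mu) / sdv
  diag(z) <- 0
  list(z = symmetrizeUpper(z), center = mu, scale = sdv)
}

.rowNorm <- function(M, normType) {
  n <- ncol(M)
  ss <- rowSums(M^2)  # diagonal is 0, contributes nothing
  if (normType == "rms") sqrt(ss / (n - 1)) else sqrt(ss)
}

#' Difference grid between two embedded networks
#'
#' Z-scores both embedded networks and forms the entrywise absolute
#' difference `M = |z(a) - z(b)|`. Each node's row of `M` is its
#' coordinate vector in the difference space; the node's displacement
#' from the origin is, by default, the root-mean-square of that row over
#' its `n - 1` off-diagonal entries, so displacement is expressed in the
#' same SD units as the z-scored edges and a threshold of 1 reads as
#' "one standard deviation". A plain Euclidean row norm is available via
#' `normType = "euclidean"`.
#'
#' @param a,b closed [DistanceNetwork-class] objects on identical node
#'   labels.
#' @param normType "rms" (default) or "euclidean".
#' @return a [DifferenceGrid-class].
#' @export
differenceGrid <- function(a, b, normType = c("rms", "euclidean")) {
  stopifnot(is(a, "DistanceNetwork"), is(b, "DistanceNetwork"))
  normType <- match.arg(normType)
  matchLabels(a, b)
  za <- zscoreEmbedded(a)
  zb <- zscoreEmbedded(b)
  M <- abs(za$z - zb$z)
  diag(M) <- 0
  M <- symmetrizeUpper(M)
  disp <- .rowNorm(M, normType)
  names(disp) <- a@nodeLabels
  new("DifferenceGrid", M = M, nodeLabels = a@nodeLabels,
      displacement = disp,
      zparams = list(a = c(center = za$center, scale = za$scale),
                     b = c(center = zb$center, scale = zb$scale)),
      normType = normType)
}

#' Count nodes inside a hypersphere of radius s
#'
#' Samples the non-decreasing step function s -> #{nodes with
#' displacement <= s}.
#'
#' @param g a [DifferenceGrid-class] (or bare displacement vector).
#' @param radii numeric vector of radii.
#' @return data.frame with columns `s` and `countInside`.
#' @export
countWithinRadius <- function(g, radii) {
  disp <- if (is(g, "DifferenceGrid")) g@displacement else g
  data.frame(s = radii,
             countInside = vapply(radii, function(s) sum(disp <= s), 0L))
}

#' Detect nodes outside the hypersphere of radius s
#'
#' Nodes whose displacement from the origin of the difference space
#' exceeds `s` standard deviations are flagged as topologically
#' different between the two modalities. Detection operates on the full
#' (n-1)-dimensional difference space; the MDS projection is exploratory
#' visualization only and never feeds detection.
#'
#' @param g a [DifferenceGrid-class].
#' @param s hypersphere radius in SD units; must be positive.
#' @param radii optional grid of radii at which to sample the
#'   count-inside curve (default: 50 points from 0 to just above the
#'   maximum displacement).
#' @return a [DetectionReport-class].
#' @export
detectNodes <- function(g, s = 1, radii = NULL) {
  stopifnot(is(g, "DifferenceGrid"))
  if (!is.numeric(s) || length(s) != 1 || s <= 0)
    stop("radius s must be a single positive number")
  disp <- g@displacement
  if (is.null(radii))
    radii <- seq(0, max(disp) * 1.05 + 1e-12, length.out = 50)
  outside <- disp > s
  new("DetectionReport", radius = s,
      insideLabels = g@nodeLabels[!outside],
      outsideLabels = g@nodeLabels[outside],
      displacement = disp,
      curve = countWithinRadius(g, radii))
}

#' Tidy per-node detection table
#'
#' @param g a [DifferenceGrid-class].
#' @param radii radii at which to report inside/outside status.
#' @return data.frame with `node`, `displacement`, and one logical
#'   `inside_s<r>` column per radius.
#' @export
detectionTable <- function(g, radii = c(0.8, 1, 1.2)) {
  stopifnot(is(g, "DifferenceGrid"))
  out <- data.frame(node = g@nodeLabels, displacement = g@displacement,
                    row.names = NULL)
  for (r in radii)
    out[[paste0("inside_s", r)]] <- g@displacement <= r
  out
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Torgerson MDS: double-center the squared distances, eigendecompose,
#' keep the top-k nonnegative eigenpairs (via [stats::cmdscale()]).
#' Deterministic. The stress reported is the normalized residual
#' `sqrt(sum((d - dhat)^2) / sum(d^2))` over the off-diagonal upper
#' triangle, where `dhat` are the Euclidean distances of the
#' configuration. For exactly Euclidean inputs and sufficient `k` the
#' stress is numerically zero. Non-Euclidean inputs (metric closures
#' often are) may offer fewer than `k` positive eigenvalues, in which
#' case the configuration is padded with zero coordinates.
#'
#' @param d a [DistanceNetwork-class] or bare symmetric nonnegative
#'   matrix with zero diagonal.
#' @param k target dimension (default 3); must be `< n`.
#' @return an [MdsProjection-class].
#' @export
mdsProject <- function(d, k = 3) {
  m <- if (is(d, "DistanceNetwork")) d@weights else d
  stopIfNotSquareNumeric(m, "distance matrix")
  n <- nrow(m)
  if (k >= n) stop("k must be smaller than the number of nodes")
  if (any(m < 0)) stop("distances must be nonnegative")
  fit <- suppressWarnings(stats::cmdscale(m, k = k, eig = TRUE))
  pts <- fit$points
  if (is.null(dim(pts)) || ncol(pts) < k) {
    pad <- matrix(0, n, k - NCOL(pts))
    pts <- cbind(pts, pad)
  }
  rownames(pts) <- rownames(m)
  dhat <- as.matrix(stats::dist(pts))
  num <- sum((upperValues(m) - upperValues(dhat))^2)
  den <- sum(upperValues(m)^2)
  stress <- if (den == 0) 0 else sqrt(num / den)
  new("MdsProjection", coordinates = pts, stress = stress,
      methodTag = "classical", eig = fit$eig)
}

#' End-to-end comparison of two modality networks
#'
#' Takes two proximity networks (e.g. an aggregated functional network
#' and a structural network) on the same node set, maps both to distance
#' space, metrically closes them, forms the difference grid, detects
#' nodes outside the hypersphere at each requested radius, and computes
#' the exploratory MDS projection.
#'
#' @param a,b [ProximityNetwork-class] objects (or already-closed
#'   [DistanceNetwork-class] objects) on identical node labels.
#' @param dialect isomorphism dialect for [proxToDist()].
#' @param radii detection radii (default `c(0.8, 1, 1.2)`).
#' @param mdsDims MDS target dimension (default 3).
#' @param normType displacement norm, see [differenceGrid()].
#' @return list with `grid` ([DifferenceGrid-class]), `reports` (one
#'   [DetectionReport-class] per radius), and `mds` (an
#'   [MdsProjection-class] of the difference grid).
#' @export
compareModalities <- function(a, b, dialect = "reciprocal",
                              radii = c(0.8, 1, 1.2), mdsDims = 3,
                              normType = "rms") {
  toClosed <- function(x) {
    if (is(x, "ProximityNetwork"))
      return(metricClosure(proxToDist(x, dialect = dialect)))
    if (!x@isClosed) stop("distance-network input must be metrically closed")
    x
  }
  ca <- toClosed(a); cb <- toClosed(b)
  g <- differenceGrid(ca, cb, normType = normType)
  reports <- lapply(radii, function(s) detectNodes(g, s))
  names(reports) <- paste0("s", radii)
  list(grid = g, reports = reports, mds = mdsProject(g@M, k = mdsDims))
}
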