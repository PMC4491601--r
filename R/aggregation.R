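#' @include AllClasses.R utils.R algebra.R
NULL

.layerSpace <- function(m) class(m@layers[[1]])[1]

.layerStack <- function(m) {
  vapply(m@layers, function(l) l@weights,
         matrix(0, nNodes(m), nNodes(m)))
}

#' Average aggregation of a multiplex network
#'
#' Entrywise arithmetic mean of homologous edges across layers — the
#' "simple averaging" group representative. Works in either space;
#' averaging tends to blur edge weights toward the group mean, diluting
#' structure that is strong in only part of the group.
#'
#' @param m a [MultiplexNetwork-class], or a plain list of equal-size
#'   square matrices (e.g. raw Fisher Z layers), in which case the bare
#'   mean matrix is returned.
#' @return a network of the same class as the layers (or a matrix for
#'   matrix-list input).
#' @export
aggregateAverage <- function(m) {
  if (is.list(m) && !is(m, "MultiplexNetwork")) {
    if (length(m) == 0) stop("empty multiplex: nothing to average")
    for (x in m) stopIfNotSquareNumeric(x, "layer")
    return(Reduce(`+`, m) / length(m))
  }
  stopifnot(is(m, "MultiplexNetwork"))
  st <- .layerStack(m)
  avg <- apply(st, c(1, 2), mean)
  avg <- symmetrizeUpper(avg)
  l1 <- m@layers[[1]]
  if (.layerSpace(m) == "ProximityNetwork")
    ProximityNetwork(avg, nodeLabels = l1@nodeLabels, epsilon = l1@epsilon)
  else
    DistanceNetwork(avg, nodeLabels = l1@nodeLabels, dialect = l1@dialect,
                    isClosed = FALSE)
}

#' Algebraic (tropical) aggregation of a multiplex network
#'
#' Entrywise `oplus = min` over homologous edges of distance-space
#' layers. When interlayer couplings have proximity 1 (distance 0) — the
#' multiplex case — collapsing the supra-adjacency walk onto homologous
#' edges is exact, so the full tensor is never materialized. The result
#' is the unclosed group representative; apply [metricClosure()] (or use
#' [embedAggregate()]) to embed it.
#'
#' @param m a [MultiplexNetwork-class] whose layers are
#'   [DistanceNetwork-class] objects.
#' @return an unclosed [DistanceNetwork-class].
#' @export
aggregateAlgebraic <- function(m) {
  stopifnot(is(m, "MultiplexNetwork"))
  if (.layerSpace(m) != "DistanceNetwork")
    stop("algebraic aggregation is defined in distance space; ",
         "map layers with proxToDist() first")
  agg <- Reduce(pmin, lapply(m@layers, function(l) l@weights))
  l1 <- m@layers[[1]]
  DistanceNetwork(agg, nodeLabels = l1@nodeLabels, dialect = l1@dialect,
                  isClosed = FALSE)
}

#' Aggregate and metrically embed a distance-space multiplex
#'
#' `metricClosure(aggregateAlgebraic(m))`: the group representative
#' embedded in the common metric space. For a single layer this reduces
#' to the metric closure of that layer.
#'
#' @param m a distance-space [MultiplexNetwork-class].
#' @param maxPower passed to [metricClosure()].
#' @return a closed [DistanceNetwork-class].
#' @export
embedAggregate <- function(m, maxPower = "auto") {
  metricClosure(aggregateAlgebraic(m), maxPower = maxPower)
}

#' Per-layer contribution to the algebraic aggregate
#'
#' For each finite off-diagonal aggregate edge, every layer whose
#' homologous edge attains the minimum (within `tol`) is credited; ties
#' are shared. Layers with zero credited edges are flagged as outliers —
#' subjects contributing nothing to the group representative. Credit is
#' assigned at the aggregation step (entrywise argmin), not via
#' membership in realized shortest paths of the closure, whose tie-broken
#' enumeration is underdetermined.
#'
#' @param m a distance-space [MultiplexNetwork-class].
#' @param aggregate the unclosed algebraic aggregate of `m` (defaults to
#'   computing it); supplying a closed network is an error.
#' @param tol tie tolerance; default 1e-12.
#' @return a [LayerContribution-class].
#' @export
layerContribution <- function(m, aggregate = aggregateAlgebraic(m),
                              tol = 1e-12) {
  stopifnot(is(m, "MultiplexNetwork"), is(aggregate, "DistanceNetwork"))
  if (!identical(nodeLabels(m), aggregate@nodeLabels))
    stop("node labels of multiplex and aggregate do not match")
  if (aggregate@isClosed)
    stop("contribution is credited on the unclosed aggregate")
  agg <- aggregate@weights
  ut <- upper.tri(agg)
  finiteEdges <- which(ut & is.finite(agg), arr.ind = TRUE)
  counts <- integer(nLayers(m))
  edges <- vector("list", nLayers(m))
  for (k in seq_len(nLayers(m))) {
    lw <- m@layers[[k]]@weights
    hit <- is.finite(lw) & ut & is.finite(agg) & (lw - agg <= tol)
    idx <- which(hit, arr.ind = TRUE)
    counts[k] <- nrow(idx)
    colnames(idx) <- c("i", "j")
    edges[[k]] <- idx
  }
  names(counts) <- m@layerIds
  names(edges) <- m@layerIds
  new("LayerContribution", counts = counts, edges = edges,
      outliers = m@layerIds[counts == 0L],
      nEdges = nrow(finiteEdges))
}

#' Group pipeline: normalize, aggregate and embed proximity layers
#'
#' High-level driver over a proximity-space multiplex (or a list of raw
#' symmetric weight matrices, which are normalized first). The algebraic
#' route maps each layer to distance space, takes the entrywise tropical
#' `min`, and closes; the average route averages in proximity space,
#' maps once to distance space, and closes.
#'
#' @param layers a proximity-space [MultiplexNetwork-class], a list of
#'   [ProximityNetwork-class] objects, or a list of raw symmetric weight
#'   matrices.
#' @param method "algebraic" (default) or "average".
#' @param epsilon normalization margin used when `layers` are raw matrices.
#' @param dialect isomorphism dialect for [proxToDist()].
#' @param scope normalization scope for raw matrices ("per_network" or
#'   "pooled").
#' @param averageZ for the average route with raw-matrix input: average
#'   the raw (Z-space) layers first and normalize the mean matrix once,
#'   instead of normalizing each layer and averaging proximities.
#' @param maxPower passed to [metricClosure()].
#' @return list with elements `embedded` (closed [DistanceNetwork-class]),
#'   `aggregate` (the pre-closure group network), and for the algebraic
#'   route `contribution` (a [LayerContribution-class]).
#' @export
embedGroup <- function(layers, method = c("algebraic", "average"),
                       epsilon = 0.01, dialect = "reciprocal",
                       scope = "per_network", averageZ = FALSE,
                       maxPower = "auto") {
  method <- match.arg(method)
  if (averageZ && method != "average")
    stop("averageZ applies to the average route only")
  ids <- NULL
  if (is(layers, "MultiplexNetwork")) {
    ids <- layers@layerIds
    layers <- layers@layers
  } else if (!is.null(names(layers))) ids <- names(layers)
  if (is.matrix(layers[[1]])) {
    if (averageZ) {
      layers <- list(normalizeWeights(aggregateAverage(layers),
                                      epsilon = epsilon))
      ids <- NULL
    }
    else layers <- normalizeLayers(layers, epsilon = epsilon, scope = scope)
  } else if (averageZ)
    stop("averageZ requires raw (unnormalized) matrix layers")
  stopifnot(all(vapply(layers, is, logical(1), "ProximityNetwork")))
  if (method == "algebraic") {
    dm <- MultiplexNetwork(lapply(layers, proxToDist, dialect = dialect),
                           layerIds = ids)
    agg <- aggregateAlgebraic(dm)
    list(embedded = metricClosure(agg, maxPower = maxPower),
         aggregate = agg,
         contribution = layerContribution(dm, agg))
  } else {
    pm <- MultiplexNetwork(layers, layerIds = ids)
    avg <- aggregateAverage(pm)
    list(embedded = metricClosure(proxToDist(avg, dialect = dialect),
                                  maxPower = maxPower),
         aggregate = avg)
  }
}
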