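#' @import methods
#' @importFrom stats cor sd pnorm rnorm runif cmdscale acf setNames quantile
#' @importFrom utils read.csv write.csv packageVersion
NULL

.symCheck <- function(m, tol = 1e-9) {
  if (!is.matrix(m) || !is.numeric(m)) return("weights must be a numeric matrix")
  if (nrow(m) != ncol(m)) return("weights must be square")
  fin <- is.finite(m) & is.finite(t(m))
  if (any(abs(m[fin] - t(m)[fin]) > tol)) return("weights must be symmetric")
  if (any(is.infinite(m) != is.infinite(t(m)))) return("weights must be symmetric (infinite entries)")
  TRUE
}

.labelCheck <- function(labels, n) {
  if (length(labels) != n) return("node labels must match matrix dimension")
  if (anyDuplicated(labels)) return("node labels must be unique")
  TRUE
}

#' Regional time series for one subject
#'
#' Container for per-node signals (one row per node, one column per time
#' point), e.g. band-limited BOLD time series averaged over the voxels of
#' each atlas region. The container is agnostic to the recording modality;
#' `samplingNote` is free text describing acquisition/filtering.
#'
#' @slot signals numeric matrix, nodes x time points.
#' @slot nodeLabels character vector of unique region labels, one per row.
#' @slot samplingNote free-text acquisition note.
#' @exportClass TimeSeriesSet
setClass("TimeSeriesSet",
  representation(signals = "matrix", nodeLabels = "character",
                 samplingNote = "character"),
  validity = function(object) {
    m <- object@signals
    if (!is.numeric(m)) return("signals must be numeric")
    if (nrow(m) < 2) return("need at least 2 nodes")
    if (ncol(m) < 8) return("need at least 8 time points")
    if (anyNA(m)) return("signals contain missing values")
    .labelCheck(object@nodeLabels, nrow(m))
  })

#' Construct a TimeSeriesSet
#'
#' @param signals nodes x time numeric matrix (or time x nodes data frame as
#'   read from a wide CSV, see `transpose`).
#' @param nodeLabels node labels; defaults to rownames of `signals`.
#' @param samplingNote free-text acquisition note.
#' @param transpose if `TRUE`, `signals` is given as time x nodes and is
#'   transposed (the on-disk layout of wide time-series CSV files).
#' @return a [TimeSeriesSet-class] object.
#' @export
TimeSeriesSet <- function(signals, nodeLabels = NULL, samplingNote = "",
                          transpose = FALSE) {
  signals <- as.matrix(signals)
  if (transpose) signals <- t(signals)
  if (is.null(nodeLabels)) nodeLabels <- rownames(signals)
  if (is.null(nodeLabels)) nodeLabels <- paste0("node", seq_len(nrow(signals)))
  nodeLabels <- as.character(nodeLabels)
  rownames(signals) <- nodeLabels
  new("TimeSeriesSet", signals = signals, nodeLabels = nodeLabels,
      samplingNote = samplingNote)
}

#' Zero-lag correlation analysis of a TimeSeriesSet
#'
#' Holds the Pearson correlation matrix `r`, its Fisher Z transform `z`,
#' the autocorrelation-corrected effective degrees of freedom `dfEff`, and
#' the two-sided p-value of each Z under the null N(0, 1/(df-3)).
#'
#' @slot r node x node zero-lag Pearson correlation, diagonal 1.
#' @slot z Fisher Z of `r` off-diagonal; diagonal set to 0 (unused downstream).
#' @slot dfEff effective degrees of freedom per pair.
#' @slot pvalue two-sided significance of `z`.
#' @slot nodeLabels node labels.
#' @slot nObs number of time points the matrices were estimated from.
#' @exportClass CorrelationResult
setClass("CorrelationResult",
  representation(r = "matrix", z = "matrix", dfEff = "matrix",
                 pvalue = "matrix", nodeLabels = "character", nObs = "integer"),
  validity = function(object) {
    ok <- .symCheck(object@r, 1e-9)
    if (!isTRUE(ok)) return(paste("r:", ok))
    if (any(abs(diag(object@r) - 1) > 1e-9)) return("diagonal of r must be 1")
    for (nm in c("z", "dfEff", "pvalue")) {
      s <- slot(object, nm)
      if (!all(dim(s) == dim(object@r))) return(paste(nm, "has wrong dimensions"))
    }
    .labelCheck(object@nodeLabels, nrow(object@r))
  })

#' Proximity-space weighted network
#'
#' Symmetric network with weights in `[0, 1]`, larger = more strongly
#' connected; the space of normalized correlations. Self-proximity is
#' maximal (diagonal 1).
#'
#' @slot weights symmetric numeric matrix in `[0, 1]`, diagonal 1.
#' @slot nodeLabels unique node labels.
#' @slot epsilon the boundary margin used at normalization time
#'   (`NA` when unknown / not applicable).
#' @exportClass ProximityNetwork
setClass("ProximityNetwork",
  representation(weights = "matrix", nodeLabels = "character",
                 epsilon = "numeric"),
  prototype(epsilon = NA_real_),
  validity = function(object) {
    ok <- .symCheck(object@weights)
    if (!isTRUE(ok)) return(ok)
    w <- object@weights
    if (any(w < -1e-12 | w > 1 + 1e-12)) return("proximity weights must lie in [0, 1]")
    if (any(abs(diag(w) - 1) > 1e-12)) return("proximity diagonal must be 1")
    .labelCheck(object@nodeLabels, nrow(w))
  })

#' Construct a ProximityNetwork
#'
#' @param weights symmetric matrix in `[0,1]`, diagonal 1.
#' @param nodeLabels node labels (default: dimnames or `node<i>`).
#' @param epsilon normalization margin recorded for provenance.
#' @return a [ProximityNetwork-class] object.
#' @export
ProximityNetwork <- function(weights, nodeLabels = NULL, epsilon = NA_real_) {
  weights <- as.matrix(weights)
  nodeLabels <- .resolveLabels(weights, nodeLabels)
  dimnames(weights) <- list(nodeLabels, nodeLabels)
  new("ProximityNetwork", weights = weights, nodeLabels = nodeLabels,
      epsilon = epsilon)
}

#' Distance-space weighted network
#'
#' Symmetric network with weights in the extended nonnegative reals
#' (smaller = closer, `Inf` = unreachable), the carrier of the (min, +)
#' semiring. `isClosed` records whether the metric closure has been
#' applied, after which the triangle inequality holds.
#'
#' @slot weights symmetric nonnegative matrix (Inf allowed), diagonal 0.
#' @slot nodeLabels unique node labels.
#' @slot dialect the proximity-to-distance isomorphism used
#'   ("reciprocal" = 1/w - 1, or "log" = -log w); `NA` if constructed directly.
#' @slot isClosed `TRUE` once metric closure has been applied.
#' @exportClass DistanceNetwork
setClass("DistanceNetwork",
  representation(weights = "matrix", nodeLabels = "character",
                 dialect = "character", isClosed = "logical"),
  prototype(dialect = NA_character_, isClosed = FALSE),
  validity = function(object) {
    ok <- .symCheck(object@weights)
    if (!isTRUE(ok)) return(ok)
    w <- object@weights
    if (any(w < -1e-12, na.rm = TRUE)) return("distance weights must be nonnegative")
    if (anyNA(w)) return("distance weights must not contain NA")
    if (any(diag(w) != 0)) return("distance diagonal must be 0")
    if (length(object@isClosed) != 1) return("isClosed must be a single flag")
    .labelCheck(object@nodeLabels, nrow(w))
  })

#' Construct a DistanceNetwork
#'
#' @param weights symmetric nonnegative matrix, diagonal 0, `Inf` allowed.
#' @param nodeLabels node labels (default: dimnames or `node<i>`).
#' @param dialect isomorphism dialect recorded for provenance.
#' @param isClosed whether the matrix is already metrically closed.
#' @return a [DistanceNetwork-class] object.
#' @export
DistanceNetwork <- function(weights, nodeLabels = NULL,
                            dialect = NA_character_, isClosed = FALSE) {
  weights <- as.matrix(weights)
  nodeLabels <- .resolveLabels(weights, nodeLabels)
  dimnames(weights) <- list(nodeLabels, nodeLabels)
  new("DistanceNetwork", weights = weights, nodeLabels = nodeLabels,
      dialect = dialect, isClosed = isClosed)
}

.resolveLabels <- function(m, labels) {
  if (is.null(labels)) labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("node", seq_len(nrow(m)))
  as.character(labels)
}

#' Semiring specification
#'
#' Names the pair of binary operators a generalized matrix product runs
#' under. The tropical (min, +) instance used throughout the package is
#' built by [tropicalSemiring()]. Validity samples associativity,
#' commutativity and identity behavior of the named operators.
#'
#' @slot oplus name of the additive operator (e.g. "min").
#' @slot otimes name of the multiplicative operator (e.g. "+").
#' @slot carrier free-text description of the carrier set.
#' @slot oplusIdentity identity element of `oplus`.
#' @slot otimesIdentity identity element of `otimes`.
#' @exportClass SemiringSpec
setClass("SemiringSpec",
  representation(oplus = "character", otimes = "character",
                 carrier = "character", oplusIdentity = "numeric",
                 otimesIdentity = "numeric"),
  validity = function(object) {
    op <- match.fun(object@oplus); ot <- match.fun(object@otimes)
    pts <- c(0, 0.5, 1, 2, 7, 100, Inf)
    for (f in list(op, ot)) {
      for (a in pts) for (b in pts) for (cc in c(0, 1, 3)) {
        lhs <- f(f(a, b), cc); rhs <- f(a, f(b, cc))
        if (!isTRUE(all.equal(lhs, rhs)) && !(is.infinite(lhs) && is.infinite(rhs)))
          return("operator not associative on sampled triples")
        if (!identical(f(a, b), f(b, a)))
          return("operator not commutative on sampled pairs")
      }
    }
    for (a in pts[is.finite(pts)]) {
      if (!identical(op(a, object@oplusIdentity), a))
        return("oplus identity does not behave as identity")
      if (!identical(ot(a, object@otimesIdentity), a))
        return("otimes identity does not behave as identity")
    }
    TRUE
  })

#' The (min, +) tropical semiring
#'
#' @return a [SemiringSpec-class] with `oplus = min`, `otimes = +`,
#'   carrier the extended nonnegative reals.
#' @export
tropicalSemiring <- function() {
  new("SemiringSpec", oplus = "min", otimes = "+",
      carrier = "[0, Inf]: nonnegative extended reals",
      oplusIdentity = Inf, otimesIdentity = 0)
}

#' Multiplex network (ordered same-node layers)
#'
#' One layer per subject; all layers share the same ordered node set and
#' live in the same space (all proximity or all distance).
#'
#' @slot layers list of [ProximityNetwork-class] or [DistanceNetwork-class],
#'   homogeneous.
#' @slot layerIds layer identifiers (e.g. subject IDs), same length.
#' @exportClass MultiplexNetwork
setClass("MultiplexNetwork",
  representation(layers = "list", layerIds = "character"),
  validity = function(object) {
    if (length(object@layers) < 1) return("need at least one layer")
    if (length(object@layerIds) != length(object@layers))
      return("layerIds must match number of layers")
    if (anyDuplicated(object@layerIds)) return("layerIds must be unique")
    cls <- vapply(object@layers, function(x) class(x)[1], character(1))
    if (!all(cls %in% c("ProximityNetwork", "DistanceNetwork")))
      return("layers must be ProximityNetwork or DistanceNetwork")
    if (length(unique(cls)) != 1) return("layers must share a single space")
    labs <- lapply(object@layers, function(x) x@nodeLabels)
    if (!all(vapply(labs, identical, logical(1), labs[[1]])))
      return("all layers must share the same ordered node labels")
    TRUE
  })

#' Construct a MultiplexNetwork
#'
#' @param layers list of same-space, same-node networks.
#' @param layerIds layer identifiers; default `layer<i>` or list names.
#' @return a [MultiplexNetwork-class] object.
#' @export
MultiplexNetwork <- function(layers, layerIds = NULL) {
  if (is.null(layerIds)) layerIds <- names(layers)
  if (is.null(layerIds)) layerIds <- paste0("layer", seq_along(layers))
  new("MultiplexNetwork", layers = unname(layers),
      layerIds = as.character(layerIds))
}

#' Per-layer contribution to an algebraic aggregate
#'
#' Credits each finite aggregate edge to every layer attaining the
#' entrywise minimum (ties shared); layers that never attain the minimum
#' are flagged as outliers.
#'
#' @slot counts named integer vector, credited edges per layer.
#' @slot edges named list, per layer a two-column matrix of credited
#'   (i, j) upper-triangle index pairs.
#' @slot outliers layer ids with zero credited edges.
#' @slot nEdges number of finite aggregate edges considered.
#' @exportClass LayerContribution
setClass("LayerContribution",
  representation(counts = "integer", edges = "list", outliers = "character",
                 nEdges = "integer"))

#' Difference grid between two embedded modalities
#'
#' Entrywise absolute difference of the two z-scored embedded distance
#' matrices, plus the per-node displacement from the origin of the
#' difference space (in SD units of the z-scored edge distributions).
#'
#' @slot M symmetric nonnegative difference matrix, zero diagonal.
#' @slot nodeLabels node labels.
#' @slot displacement named per-node displacement (SD units).
#' @slot zparams list with the (mean, sd) used to z-score each input.
#' @slot normType "rms" (default, row RMS over n-1 coordinates) or
#'   "euclidean" (plain row norm).
#' @exportClass DifferenceGrid
setClass("DifferenceGrid",
  representation(M = "matrix", nodeLabels = "character",
                 displacement = "numeric", zparams = "list",
                 normType = "character"),
  validity = function(object) {
    ok <- .symCheck(object@M)
    if (!isTRUE(ok)) return(ok)
    if (any(object@M < -1e-12)) return("difference grid must be nonnegative")
    if (any(diag(object@M) != 0)) return("difference grid diagonal must be 0")
    if (length(object@displacement) != nrow(object@M))
      return("displacement must have one entry per node")
    if (any(object@displacement < 0)) return("displacement must be nonnegative")
    .labelCheck(object@nodeLabels, nrow(object@M))
  })

#' Hypersphere detection report
#'
#' Nodes whose displacement from the origin of the difference space
#' exceeds the radius `s` are flagged as topologically different between
#' the two modalities.
#'
#' @slot radius the hypersphere radius `s` (SD units).
#' @slot insideLabels,outsideLabels disjoint node-label partitions.
#' @slot displacement named per-node displacement the report was built from.
#' @slot curve data.frame (`s`, `countInside`) sampling the count-vs-radius
#'   step function.
#' @exportClass DetectionReport
setClass("DetectionReport",
  representation(radius = "numeric", insideLabels = "character",
                 outsideLabels = "character", displacement = "numeric",
                 curve = "data.frame"),
  validity = function(object) {
    if (object@radius <= 0) return("radius must be positive")
    if (length(intersect(object@insideLabels, object@outsideLabels)) > 0)
      return("inside and outside label sets must be disjoint")
    if (length(object@insideLabels) + length(object@outsideLabels) !=
        length(object@displacement))
      return("inside + outside must cover all nodes")
    TRUE
  })

#' Classical MDS projection of a distance matrix
#'
#' @slot coordinates node x k configuration.
#' @slot stress normalized residual between the input distances and the
#'   configuration distances, sqrt(sum((d - dhat)^2) / sum(d^2)).
#' @slot methodTag "classical" (Torgerson double-centering).
#' @slot eig eigenvalues of the doubly-centered matrix.
#' @exportClass MdsProjection
setClass("MdsProjection",
  representation(coordinates = "matrix", stress = "numeric",
                 methodTag = "character", eig = "numeric"))

#' Synthetic-data generation parameters
#'
#' Fixes the study conditions the generators emulate: a group of subjects
#' sharing a weighted backbone (with per-subject expression variability
#' and jitter), spurious per-layer noise edges, autocorrelated regional
#' time series with a planted correlation structure, and paired-modality
#' networks with a known set of perturbed nodes.
#'
#' @slot nNodes number of nodes (atlas regions).
#' @slot nLayers number of layers (subjects).
#' @slot backboneDensity probability a node pair is a backbone edge.
#' @slot backboneStrength central backbone proximity (proximity units).
#' @slot backbonePrevalence probability a backbone edge is expressed in a
#'   given layer (inter-subject variability).
#' @slot noiseDensity per-layer probability of a spurious edge on a
#'   non-backbone pair.
#' @slot noiseStrengthSd sd of the multiplicative lognormal jitter (log scale).
#' @slot nPerturbedNodes number of planted discordant nodes for modality pairs.
#' @slot perturbationMagnitude planted perturbation, in SD units of the
#'   embedded edge distribution.
#' @slot arCoefficient AR(1) coefficient of generated time series.
#' @slot nTimepoints number of generated time points.
#' @slot seed mandatory RNG seed.
#' @exportClass SynthSpec
setClass("SynthSpec",
  representation(nNodes = "integer", nLayers = "integer",
                 backboneDensity = "numeric", backboneStrength = "numeric",
                 backbonePrevalence = "numeric", noiseDensity = "numeric",
                 noiseStrengthSd = "numeric", nPerturbedNodes = "integer",
                 perturbationMagnitude = "numeric", arCoefficient = "numeric",
                 nTimepoints = "integer", seed = "integer"),
  validity = function(object) {
    if (object@nNodes < 2) return("need at least 2 nodes")
    if (object@nLayers < 1) return("need at least 1 layer")
    if (object@backboneDensity <= 0 || object@backboneDensity > 1)
      return("backboneDensity must be in (0, 1]")
    if (object@noiseDensity < 0 || object@noiseDensity > 1)
      return("noiseDensity must be in [0, 1]")
    if (object@backbonePrevalence <= 0 || object@backbonePrevalence > 1)
      return("backbonePrevalence must be in (0, 1]")
    if (object@backboneStrength <= 0 || object@backboneStrength >= 1)
      return("backboneStrength must be in (0, 1)")
    if (object@nPerturbedNodes >= object@nNodes)
      return("nPerturbedNodes must be smaller than nNodes")
    if (abs(object@arCoefficient) >= 1) return("arCoefficient must be in (-1, 1)")
    if (object@nTimepoints < 8) return("need at least 8 time points")
    if (length(object@seed) != 1 || is.na(object@seed)) return("seed is mandatory")
    TRUE
  })

#' Construct a SynthSpec
#'
#' Defaults emulate the study conditions of a 90-region atlas and a
#' 20-subject group; see the methods vignette for the rationale behind
#' each value.
#'
#' @param nNodes,nLayers,backboneDensity,backboneStrength,backbonePrevalence
#'   see [SynthSpec-class].
#' @param noiseDensity,noiseStrengthSd,nPerturbedNodes,perturbationMagnitude
#'   see [SynthSpec-class].
#' @param arCoefficient,nTimepoints see [SynthSpec-class].
#' @param seed mandatory integer RNG seed.
#' @return a [SynthSpec-class] object.
#' @export
synthSpec <- function(seed, nNodes = 90L, nLayers = 20L,
                      backboneDensity = 0.15, backboneStrength = 0.6,
                      backbonePrevalence = 0.7, noiseDensity = 0.1,
                      noiseStrengthSd = 0.15,
                      nPerturbedNodes = max(1L, min(5L, nNodes - 1L)),
                      perturbationMagnitude = 2.0, arCoefficient = 0.4,
                      nTimepoints = 150L) {
  if (missing(seed)) stop("'seed' is mandatory in a SynthSpec")
  new("SynthSpec", nNodes = as.integer(nNodes), nLayers = as.integer(nLayers),
      backboneDensity = backboneDensity, backboneStrength = backboneStrength,
      backbonePrevalence = backbonePrevalence, noiseDensity = noiseDensity,
      noiseStrengthSd = noiseStrengthSd,
      nPerturbedNodes = as.integer(nPerturbedNodes),
      perturbationMagnitude = perturbationMagnitude,
      arCoefficient = arCoefficient, nTimepoints = as.integer(nTimepoints),
      seed = as.integer(seed))
}
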