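#' @include AllClasses.R
NULL

#' Extract the weight matrix of a network object
#'
#' @param object a network-like object.
#' @param ... unused.
#' @return the underlying numeric matrix (with node-label dimnames).
#' @export
setGeneric("netWeights", function(object, ...) standardGeneric("netWeights"))

#' Node labels of an object
#' @param object an object carrying node labels.
#' @return character vector of labels.
#' @export
setGeneric("nodeLabels", function(object) standardGeneric("nodeLabels"))

#' Number of nodes
#' @param object an object with a node set.
#' @return integer.
#' @export
setGeneric("nNodes", function(object) standardGeneric("nNodes"))

#' Whether a distance network is metrically closed
#' @param object a [DistanceNetwork-class].
#' @return logical flag.
#' @export
setGeneric("isClosed", function(object) standardGeneric("isClosed"))

#' Per-node displacement of a difference grid
#' @param object a [DifferenceGrid-class].
#' @return named nonnegative numeric vector (SD units).
#' @export
setGeneric("displacement", function(object) standardGeneric("displacement"))

#' @describeIn netWeights weights of a proximity network
#' @export
setMethod("netWeights", "ProximityNetwork", function(object, ...) object@weights)

#' @describeIn netWeights weights of a distance network
#' @export
setMethod("netWeights", "DistanceNetwork", function(object, ...) object@weights)

#' @describeIn netWeights difference matrix of a difference grid
#' @export
setMethod("netWeights", "DifferenceGrid", function(object, ...) object@M)

setMethod("nodeLabels", "TimeSeriesSet", function(object) object@nodeLabels)
setMethod("nodeLabels", "CorrelationResult", function(object) object@nodeLabels)
setMethod("nodeLabels", "ProximityNetwork", function(object) object@nodeLabels)
setMethod("nodeLabels", "DistanceNetwork", function(object) object@nodeLabels)
setMethod("nodeLabels", "DifferenceGrid", function(object) object@nodeLabels)
setMethod("nodeLabels", "MultiplexNetwork",
          function(object) object@layers[[1]]@nodeLabels)

setMethod("nNodes", "TimeSeriesSet", function(object) nrow(object@signals))
setMethod("nNodes", "ProximityNetwork", function(object) nrow(object@weights))
setMethod("nNodes", "DistanceNetwork", function(object) nrow(object@weights))
setMethod("nNodes", "DifferenceGrid", function(object) nrow(object@M))
setMethod("nNodes", "MultiplexNetwork",
          function(object) nrow(object@layers[[1]]@weights))

setMethod("isClosed", "DistanceNetwork", function(object) object@isClosed)
setMethod("displacement", "DifferenceGrid", function(object) object@displacement)

#' Number of layers of a multiplex network
#' @param object a [MultiplexNetwork-class].
#' @return integer.
#' @export
setGeneric("nLayers", function(object) standardGeneric("nLayers"))
setMethod("nLayers", "MultiplexNetwork", function(object) length(object@layers))

#' Layer identifiers of a multiplex network
#' @param object a [MultiplexNetwork-class].
#' @return character vector.
#' @export
setGeneric("layerIds", function(object) standardGeneric("layerIds"))
setMethod("layerIds", "MultiplexNetwork", function(object) object@layerIds)

#' Extract one layer of a multiplex network
#' @param x a [MultiplexNetwork-class].
#' @param i layer index or id.
#' @return the layer network.
#' @export
setMethod("[[", "MultiplexNetwork", function(x, i) {
  if (is.character(i)) i <- match(i, x@layerIds)
  x@layers[[i]]
})

.fmtRange <- function(m) {
  v <- m[row(m) != col(m)]
  sprintf("off-diagonal range [%.4g, %.4g]", min(v), max(v))
}

setMethod("show", "TimeSeriesSet", function(object) {
  cat(sprintf("TimeSeriesSet: %d nodes x %d time points\n",
              nrow(object@signals), ncol(object@signals)))
  if (nzchar(object@samplingNote))
    cat(" sampling:", object@samplingNote, "\n")
})

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("CorrelationResult: %d nodes, N = %d time points\n",
              nrow(object@r), object@nObs))
  cat(" ", .fmtRange(object@r), "(r);",
      sprintf("median df_eff %.1f\n", stats::median(object@dfEff[row(object@dfEff) != col(object@dfEff)])))
})

setMethod("show", "ProximityNetwork", function(object) {
  cat(sprintf("ProximityNetwork: %d nodes, %s", nNodes(object),
              .fmtRange(object@weights)))
  if (!is.na(object@epsilon)) cat(sprintf(", epsilon = %g", object@epsilon))
  cat("\n")
})

setMethod("show", "DistanceNetwork", function(object) {
  cat(sprintf("DistanceNetwork: %d nodes, %s, %s%s\n", nNodes(object),
              .fmtRange(object@weights),
              if (object@isClosed) "metrically closed" else "not closed",
              if (is.na(object@dialect)) "" else paste0(" (", object@dialect, ")")))
})

setMethod("show", "MultiplexNetwork", function(object) {
  cat(sprintf("MultiplexNetwork: %d layers of %s on %d nodes\n",
              nLayers(object), class(object@layers[[1]]), nNodes(object)))
})

setMethod("show", "LayerContribution", function(object) {
  cat(sprintf("LayerContribution: %d aggregate edges over %d layers\n",
              object@nEdges, length(object@counts)))
  if (length(object@outliers))
    cat(" outliers (no contribution):", paste(object@outliers, collapse = ", "), "\n")
})

setMethod("show", "DifferenceGrid", function(object) {
  cat(sprintf("DifferenceGrid: %d nodes, displacement range [%.3g, %.3g] SD (%s norm)\n",
              nNodes(object), min(object@displacement), max(object@displacement),
              object@normType))
})

setMethod("show", "DetectionReport", function(object) {
  cat(sprintf("DetectionReport: radius s = %g SD; %d inside, %d outside\n",
              object@radius, length(object@insideLabels),
              length(object@outsideLabels)))
  if (length(object@outsideLabels))
    cat(" outside:", paste(object@outsideLabels, collapse = ", "), "\n")
})

setMethod("show", "MdsProjection", function(object) {
  cat(sprintf("MdsProjection (%s): %d points in %d dimensions, stress %.3g\n",
              object@methodTag, nrow(object@coordinates),
              ncol(object@coordinates), object@stress))
})

setMethod("show", "SynthSpec", function(object) {
  cat(sprintf(paste0("SynthSpec: %d nodes, %d layers, backbone density %.2f ",
                     "(strength %.2f, prevalence %.2f), seed %d\n"),
              object@nNodes, object@nLayers, object@backboneDensity,
              object@backboneStrength, object@backbonePrevalence, object@seed))
})
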