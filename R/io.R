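#' @include AllClasses.R utils.R algebra.R
NULL

# Matrix CSV dialect: comma-separated, header row and index column of
# node labels, "inf" for +Inf. Chosen for diffability at connectome scale.

.sidecarPath <- function(path) paste0(path, ".json")

#' Write a network (or matrix) as labeled CSV with a JSON sidecar
#'
#' The sidecar records the space (`proximity`/`distance`), epsilon,
#' isomorphism dialect, closure state and arbitrary extra provenance, so
#' pipelines cannot silently mix spaces.
#'
#' @param x a [ProximityNetwork-class], [DistanceNetwork-class] or bare
#'   matrix.
#' @param path output CSV path.
#' @param sidecar write the JSON sidecar (default `TRUE`).
#' @param provenance named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
writeNetworkCSV <- function(x, path, sidecar = TRUE, provenance = list()) {
  m <- if (is.matrix(x)) x else netWeights(x)
  df <- as.data.frame(m)
  # %.17g keeps doubles bit-exact across a write/read round trip
  df[] <- lapply(df, function(col)
    ifelse(is.infinite(col), "inf", sprintf("%.17g", col)))
  utils::write.csv(df, path, row.names = TRUE)
  meta <- list(package = "tropnet",
               version = as.character(utils::packageVersion("tropnet")))
  if (is(x, "ProximityNetwork")) {
    meta$space_tag <- "proximity"
    if (!is.na(x@epsilon)) meta$epsilon <- x@epsilon
  } else if (is(x, "DistanceNetwork")) {
    meta$space_tag <- "distance"
    meta$is_closed <- x@isClosed
    if (!is.na(x@dialect)) meta$dialect <- x@dialect
  } else meta$space_tag <- "matrix"
  meta <- utils::modifyList(meta, provenance)
  if (sidecar)
    jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  invisible(path)
}

.readLabeledMatrix <- function(path) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  df <- tryCatch(utils::read.csv(path, row.names = 1, check.names = FALSE),
                 error = function(e)
                   stop("malformed matrix CSV '", path, "': ",
                        conditionMessage(e)))
  m <- as.matrix(df)
  suppressWarnings(storage <- apply(m, c(1, 2), function(v) {
    if (v %in% c("inf", "Inf", "+inf")) Inf else as.numeric(v)
  }))
  if (anyNA(storage))
    stop("malformed matrix CSV '", path, "': non-numeric entries")
  if (nrow(storage) != ncol(storage) ||
      !identical(rownames(storage), colnames(storage)))
    stop("matrix CSV '", path, "' must be square with matching row/column labels")
  storage
}

#' Read a network CSV (with its sidecar, if present)
#'
#' Reconstructs a [ProximityNetwork-class] or [DistanceNetwork-class]
#' according to the sidecar's `space_tag`; without a sidecar the bare
#' labeled matrix is returned.
#'
#' @param path CSV path written by [writeNetworkCSV()].
#' @return network object or matrix.
#' @export
readNetworkCSV <- function(path) {
  m <- .readLabeledMatrix(path)
  sc <- .sidecarPath(path)
  if (!file.exists(sc)) return(m)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (identical(meta$space_tag, "proximity"))
    ProximityNetwork(m, epsilon = if (is.null(meta$epsilon)) NA_real_
                     else meta$epsilon)
  else if (identical(meta$space_tag, "distance"))
    DistanceNetwork(m, dialect = if (is.null(meta$dialect)) NA_character_
                    else meta$dialect,
                    isClosed = isTRUE(meta$is_closed))
  else m
}

#' Read wide time-series CSV
#'
#' Expected layout: rows are time points, columns are node labels
#' (header row mandatory).
#'
#' @param path CSV path.
#' @param samplingNote free-text note stored on the result.
#' @return a [TimeSeriesSet-class].
#' @export
readTimeSeriesCSV <- function(path, samplingNote = "") {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e)
                   stop("malformed time-series CSV '", path, "': ",
                        conditionMessage(e)))
  if (!all(vapply(df, is.numeric, logical(1))))
    stop("malformed time-series CSV '", path, "': non-numeric columns")
  TimeSeriesSet(as.matrix(df), nodeLabels = colnames(df),
                samplingNote = samplingNote, transpose = TRUE)
}

#' Write a TimeSeriesSet as wide CSV
#' @param ts a [TimeSeriesSet-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTimeSeriesCSV <- function(ts, path) {
  df <- as.data.frame(t(ts@signals))
  colnames(df) <- ts@nodeLabels
  df[] <- lapply(df, function(col) sprintf("%.17g", col))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a multiplex manifest
#'
#' The manifest is a two-column CSV (`layer_id`, `filename`) whose order
#' defines the layer order; filenames are resolved relative to the
#' manifest's directory. All referenced networks must share one space
#' and one node set.
#'
#' @param path manifest CSV path.
#' @return a [MultiplexNetwork-class].
#' @export
readMultiplexManifest <- function(path) {
  if (!file.exists(path)) stop("manifest does not exist: ", path)
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("layer_id", "filename") %in% colnames(mf)))
    stop("manifest '", path, "' needs columns layer_id, filename")
  dir <- dirname(path)
  layers <- lapply(mf$filename, function(f) {
    net <- readNetworkCSV(file.path(dir, f))
    if (is.matrix(net))
      stop("layer '", f, "' has no sidecar declaring its space; ",
           "write layers with writeNetworkCSV()")
    net
  })
  MultiplexNetwork(layers, layerIds = mf$layer_id)
}

#' Write a multiplex network as per-layer CSVs plus manifest
#'
#' @param m a [MultiplexNetwork-class].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix for the per-layer CSVs.
#' @return the manifest path, invisibly.
#' @export
writeMultiplexCSV <- function(m, dir, prefix = "layer") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s_%03d.csv", prefix, seq_len(nLayers(m)))
  for (k in seq_len(nLayers(m)))
    writeNetworkCSV(m@layers[[k]], file.path(dir, files[k]))
  mf <- data.frame(layer_id = m@layerIds, filename = files)
  mfPath <- file.path(dir, "manifest.csv")
  utils::write.csv(mf, mfPath, row.names = FALSE)
  invisible(mfPath)
}

#' Pipeline configuration
#'
#' Reads a YAML configuration (all fields optional) and applies flag
#' overrides; every value is validated. Fields: `epsilon`,
#' `isomorphism_dialect` ("reciprocal"|"log"), `aggregation_method`
#' ("algebraic"|"average"), `closure_r` ("auto" or integer),
#' `detection_radii` (numeric vector), `mds_dims`, `seed`,
#' `normalization_scope` ("per_network"|"pooled").
#'
#' @param path optional YAML file.
#' @param overrides named list overriding file values.
#' @return validated named list of configuration values.
#' @export
readPipelineConfig <- function(path = NULL, overrides = list()) {
  cfg <- list(epsilon = 0.01, isomorphism_dialect = "reciprocal",
              aggregation_method = "algebraic", closure_r = "auto",
              detection_radii = c(0.8, 1, 1.2), mds_dims = 3L,
              seed = 1L, normalization_scope = "per_network")
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file does not exist: ", path)
    fileCfg <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, fileCfg)
  }
  cfg <- utils::modifyList(cfg, overrides)
  if (cfg$epsilon <= 0 || cfg$epsilon >= 0.5)
    stop("config: epsilon must be in (0, 0.5)")
  cfg$isomorphism_dialect <- match.arg(cfg$isomorphism_dialect, .dialects)
  cfg$aggregation_method <- match.arg(cfg$aggregation_method,
                                      c("algebraic", "average"))
  if (!identical(cfg$closure_r, "auto")) {
    cfg$closure_r <- suppressWarnings(as.integer(cfg$closure_r))
    if (is.na(cfg$closure_r) || cfg$closure_r < 1)
      stop("config: closure_r must be \"auto\" or a positive integer")
  }
  if (any(cfg$detection_radii <= 0)) stop("config: detection radii must be positive")
  cfg$mds_dims <- as.integer(cfg$mds_dims)
  cfg$seed <- as.integer(cfg$seed)
  cfg$normalization_scope <- match.arg(cfg$normalization_scope,
                                       c("per_network", "pooled"))
  cfg
}

.provenance <- function(cfg, inputs) {
  list(config = cfg,
       input_md5 = as.list(tools::md5sum(inputs)))
}
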