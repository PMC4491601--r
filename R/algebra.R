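#' @include AllClasses.R utils.R
NULL

#' Affine normalization of raw weights into the unit interval
#'
#' Maps a raw symmetric weight matrix (e.g. Fisher Z values) into
#' `[epsilon, 1 - epsilon]` by the unique affine function sending the
#' minimum raw weight to `epsilon` and the maximum to `1 - epsilon`:
#' `w = ((1 - 2*epsilon) * (x - MIN) / (MAX - MIN)) + epsilon`.
#' The margin `epsilon` keeps boundary vertices from merging (weight 1)
#' or becoming isolated (weight 0). Being a single affine map, the
#' normalization preserves the order of all entries and hence the
#' network's topology.
#'
#' MIN and MAX are taken over off-diagonal entries only: the diagonal is
#' a self-loop, not an edge, and is forced to proximity 1 afterwards.
#'
#' @param raw square symmetric numeric matrix of raw weights.
#' @param epsilon margin in (0, 0.5); default 0.01.
#' @param nodeLabels optional node labels.
#' @param range optional c(min, max) to normalize against instead of the
#'   matrix's own off-diagonal range (used for pooled multi-subject
#'   normalization); entries outside are an error.
#' @return a [ProximityNetwork-class].
#' @export
normalizeWeights <- function(raw, epsilon = 0.01, nodeLabels = NULL,
                             range = NULL) {
  stopIfNotSquareNumeric(raw, "raw weight matrix")
  ok <- .symCheck(raw)
  if (!isTRUE(ok)) stop("raw weight matrix: ", ok)
  if (epsilon <= 0 || epsilon >= 0.5)
    stop("epsilon must lie strictly inside (0, 0.5)")
  off <- raw[row(raw) != col(raw)]
  if (is.null(range)) range <- c(min(off), max(off))
  lo <- range[1]; hi <- range[2]
  if (!(hi > lo))
    stop("constant weight matrix: MAX(raw) must exceed MIN(raw)")
  if (min(off) < lo || max(off) > hi)
    stop("entries fall outside the supplied normalization range")
  w <- ((1 - 2 * epsilon) * (raw - lo)) / (hi - lo) + epsilon
  diag(w) <- 1
  w <- symmetrizeUpper(w)
  ProximityNetwork(w, nodeLabels = .resolveLabels(raw, nodeLabels),
                   epsilon = epsilon)
}

#' Normalize a list of raw weight matrices, per network or pooled
#'
#' Per-network scope applies [normalizeWeights()] to each matrix against
#' its own off-diagonal range (the default: normalization is introduced
#' per network). Pooled scope uses the min/max over all matrices jointly,
#' so that weights remain comparable across subjects.
#'
#' @param rawList list of square symmetric matrices (same dimensions).
#' @param epsilon margin in (0, 0.5).
#' @param scope "per_network" (default) or "pooled".
#' @param nodeLabels optional node labels applied to every network.
#' @return list of [ProximityNetwork-class] objects.
#' @export
normalizeLayers <- function(rawList, epsilon = 0.01,
                            scope = c("per_network", "pooled"),
                            nodeLabels = NULL) {
  scope <- match.arg(scope)
  rng <- NULL
  if (scope == "pooled") {
    offs <- unlist(lapply(rawList, function(m) m[row(m) != col(m)]))
    rng <- c(min(offs), max(offs))
  }
  lapply(rawList, normalizeWeights, epsilon = epsilon,
         nodeLabels = nodeLabels, range = rng)
}

.dialects <- c("reciprocal", "log")

#' Map a proximity network to the isomorphic distance network
#'
#' The default "reciprocal" dialect applies `d = 1/w - 1` entrywise
#' (proximity 1 maps to distance 0, strictly decreasing). The "log"
#' dialect applies `d = -log(w)`. Both are order-reversing isomorphisms
#' between the proximity space `[0, 1]` and the extended nonnegative
#' reals, and both round-trip exactly with [distToProx()].
#'
#' Exact zero proximities are refused by default (normalization
#' guarantees `w >= epsilon`, so a zero indicates upstream data errors);
#' set `zeroPolicy = "infinite"` to map them to `Inf` (e.g. after
#' unioning node sets).
#'
#' @param p a [ProximityNetwork-class].
#' @param dialect "reciprocal" (default) or "log".
#' @param zeroPolicy "error" (default) or "infinite".
#' @return a [DistanceNetwork-class] with `isClosed = FALSE`.
#' @export
proxToDist <- function(p, dialect = c("reciprocal", "log"),
                       zeroPolicy = c("error", "infinite")) {
  stopifnot(is(p, "ProximityNetwork"))
  dialect <- match.arg(dialect)
  zeroPolicy <- match.arg(zeroPolicy)
  w <- p@weights
  if (any(w == 0) && zeroPolicy == "error")
    stop("proximity weight exactly 0 encountered; normalized networks ",
         "have weights >= epsilon (use zeroPolicy = \"infinite\" to allow)")
  d <- if (dialect == "reciprocal") 1 / w - 1 else -log(w)
  diag(d) <- 0
  d <- symmetrizeUpper(d)
  DistanceNetwork(d, nodeLabels = p@nodeLabels, dialect = dialect,
                  isClosed = FALSE)
}

#' Map a distance network back to the isomorphic proximity network
#'
#' Inverse of [proxToDist()]: `w = 1/(1 + d)` for the "reciprocal"
#' dialect, `w = exp(-d)` for "log"; `Inf` maps to 0 in both.
#'
#' @param d a [DistanceNetwork-class].
#' @param dialect "reciprocal" (default) or "log"; defaults to the
#'   dialect recorded on `d` when available.
#' @return a [ProximityNetwork-class].
#' @export
distToProx <- function(d, dialect = NULL) {
  stopifnot(is(d, "DistanceNetwork"))
  if (is.null(dialect))
    dialect <- if (is.na(d@dialect)) "reciprocal" else d@dialect
  dialect <- match.arg(dialect, .dialects)
  m <- d@weights
  if (any(m < 0)) stop("distance weights must be nonnegative")
  w <- if (dialect == "reciprocal") 1 / (1 + m) else exp(-m)
  diag(w) <- 1
  w <- symmetrizeUpper(w)
  ProximityNetwork(w, nodeLabels = d@nodeLabels)
}

#' Tropical identity matrix
#'
#' Identity of the (min, +) matrix product: 0 on the diagonal
#' (the `otimes` identity), `Inf` elsewhere (the `oplus` identity).
#'
#' @param n dimension.
#' @return n x n matrix.
#' @export
tropicalIdentity <- function(n) {
  m <- matrix(Inf, n, n)
  diag(m) <- 0
  m
}

#' Generalized (semiring) matrix product
#'
#' `c_ij = oplus_k (a_ik otimes b_kj)`. For the tropical semiring this is
#' the min-plus product, which composes path lengths: the (i, j) entry of
#' the k-th tropical power of a distance matrix is the shortest length of
#' an i-j walk with at most k edges.
#'
#' The (min, +) instance is computed by a vectorized fast path; any other
#' [SemiringSpec-class] falls back to a generic fold over the named
#' operators.
#'
#' @param a,b conformable square numeric matrices over the semiring carrier.
#' @param spec a [SemiringSpec-class]; default [tropicalSemiring()].
#' @return the product matrix.
#' @export
semiringMatmul <- function(a, b, spec = tropicalSemiring()) {
  stopifnot(is(spec, "SemiringSpec"))
  if (anyNA(a) || anyNA(b)) stop("NaN/NA entries are outside the semiring carrier")
  if (ncol(a) != nrow(b)) stop("matrices are not conformable")
  if (spec@oplus == "min" && spec@otimes == "+") return(.tropMatmul(a, b))
  op <- match.fun(spec@oplus); ot <- match.fun(spec@otimes)
  out <- matrix(spec@oplusIdentity, nrow(a), ncol(b))
  for (i in seq_len(nrow(a)))
    for (j in seq_len(ncol(b)))
      out[i, j] <- Reduce(op, ot(a[i, ], b[, j]))
  out
}

# Min-plus product, column-blocked: column j of the result is the row-wise
# min of a + b[, j] broadcast down the rows.
.tropMatmul <- function(a, b) {
  n <- nrow(a)
  out <- matrix(Inf, n, ncol(b))
  for (j in seq_len(ncol(b))) {
    s <- a + rep(b[, j], each = n)   # s[i, k] = a[i, k] + b[k, j]
    out[, j] <- do.call(pmin, lapply(seq_len(ncol(a)), function(k) s[, k]))
  }
  out
}

#' Metric closure of a distance network
#'
#' Embeds a distance network into a metric space by accumulating its
#' tropical powers, `closure = N oplus N^2 oplus ... oplus N^r`, until a
#' fixpoint (`r = "auto"`, guaranteed at power <= n - 1). Under (min, +)
#' this equals the all-pairs shortest-path distances and enforces the
#' triangle inequality ("transitivity" of the graph topology). The result
#' never exceeds the input entrywise and the operation is idempotent.
#'
#' With `maxPower = "auto"` the closure is computed by repeated tropical
#' squaring with accumulation (at most `ceil(log2(n - 1)) + 1` products);
#' an integer `maxPower` accumulates powers `1 ... r` exactly, which stops
#' short of the full closure when `r` is small.
#'
#' @param d a [DistanceNetwork-class] (or bare matrix) with nonnegative
#'   entries and zero diagonal.
#' @param maxPower "auto" (default) or a positive integer `r`.
#' @return a [DistanceNetwork-class] with `isClosed = TRUE` (a bare
#'   matrix in, a bare matrix out).
#' @export
metricClosure <- function(d, maxPower = "auto") {
  bare <- !is(d, "DistanceNetwork")
  m <- if (bare) d else d@weights
  stopIfNotSquareNumeric(m, "distance matrix")
  if (anyNA(m)) stop("distance matrix must not contain NA")
  if (any(m < 0)) stop("negative distances are outside this framework")
  if (any(diag(m) != 0)) stop("distance diagonal must be 0")
  n <- nrow(m)
  if (identical(maxPower, "auto")) {
    # diag 0 makes squaring monotone non-increasing and self-accumulating
    repeat {
      m2 <- pmin(m, .tropMatmul(m, m))
      if (identical(m2, m)) break
      m <- m2
    }
  } else {
    r <- as.integer(maxPower)
    if (is.na(r) || r < 1) stop("maxPower must be \"auto\" or a positive integer")
    p <- m; acc <- m
    for (k in seq_len(r - 1)) {
      p <- .tropMatmul(p, if (bare) d else d@weights)
      acc <- pmin(acc, p)
    }
    m <- acc
  }
  m <- symmetrizeUpper(m)
  if (bare) return(m)
  DistanceNetwork(m, nodeLabels = d@nodeLabels, dialect = d@dialect,
                  isClosed = TRUE)
}
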