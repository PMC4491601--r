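#' @include AllClasses.R
NULL

# Evaluate expr under a fixed RNG state, restoring the caller's state after.
# Generators are pure functions of (spec, seed) because of this.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Off-diagonal upper-triangle values of a square matrix.
upperValues <- function(m) m[upper.tri(m)]

# Symmetrize exactly from the upper triangle (weights pipelines keep
# matrices symmetric; this guards against last-bit drift).
symmetrizeUpper <- function(m) {
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

stopIfNotSquareNumeric <- function(m, what = "matrix") {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != ncol(m))
    stop(what, " must be a square numeric matrix")
  invisible(m)
}

matchLabels <- function(a, b) {
  if (!identical(nodeLabels(a), nodeLabels(b)))
    stop("node labels of the two networks do not match")
  invisible(TRUE)
}
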