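# Independent oracles, written separately from the production code paths
# they check.

# Floyd-Warshall all-pairs shortest paths (k-outer formulation).
fwClosure <- function(m) {
  n <- nrow(m)
  for (k in seq_len(n))
    m <- pmin(m, outer(m[, k], m[k, ], "+"))
  m
}

# Brute-force triple-loop min-plus product.
tropMatmulLoop <- function(a, b) {
  n <- nrow(a); p <- ncol(b)
  out <- matrix(Inf, n, p)
  for (i in seq_len(n))
    for (j in seq_len(p)) {
      best <- Inf
      for (k in seq_len(ncol(a))) best <- min(best, a[i, k] + b[k, j])
      out[i, j] <- best
    }
  out
}

# Random connected weighted distance matrix: a random spanning chain
# guarantees connectivity, extra Bernoulli edges add shortcuts; weights
# uniform, optionally integer-valued. Non-edges are Inf unless dense.
randomDistanceMatrix <- function(n, density = 0.3, integer = FALSE,
                                 dense = FALSE) {
  m <- matrix(if (dense) 0 else Inf, n, n)
  rw <- function(k) if (integer) sample(1:20, k, replace = TRUE)
        else runif(k, 0.1, 10)
  if (dense) {
    v <- rw(n * (n - 1) / 2)
    m[upper.tri(m)] <- v
  } else {
    ord <- sample(n)
    for (i in seq_len(n - 1)) {
      a <- min(ord[i], ord[i + 1]); b <- max(ord[i], ord[i + 1])
      m[a, b] <- rw(1)
    }
    extra <- which(upper.tri(m) & is.infinite(m), arr.ind = TRUE)
    pick <- runif(nrow(extra)) < density
    if (any(pick)) m[extra[pick, , drop = FALSE]] <- rw(sum(pick))
  }
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 0
  m
}

# Random proximity network with weights bounded away from 0 and 1.
randomProximity <- function(n, lo = 0.05, hi = 0.95) {
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- runif(n * (n - 1) / 2, lo, hi)
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  diag(w) <- 1
  ProximityNetwork(w)
}

# Direct-summation effective-df oracle: autocorrelations computed by the
# definition (biased, demeaned), the lag sum accumulated term by term.
dfOracle <- function(signals, maxLag) {
  N <- ncol(signals)
  acfOne <- function(x, tau) {
    xc <- x - mean(x)
    sum(xc[1:(N - tau)] * xc[(1 + tau):N]) / sum(xc^2)
  }
  nn <- nrow(signals)
  A <- sapply(seq_len(maxLag), function(tau)
    vapply(seq_len(nn), function(i) acfOne(signals[i, ], tau), 0))
  df <- matrix(0, nn, nn)
  for (i in seq_len(nn))
    for (j in seq_len(nn)) {
      s <- 0
      for (tau in seq_len(maxLag))
        s <- s + ((N - tau) / N) * A[i, tau] * A[j, tau]
      df[i, j] <- 1 / (1 / N + (2 / N) * s)
    }
  df
}
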