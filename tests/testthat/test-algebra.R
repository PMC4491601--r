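test_that("weight normalization maps endpoints, midpoint and preserves order", {
  set.seed(31)
  for (eps in c(0.01, 0.05)) {
    raw <- matrix(0, 6, 6)
    raw[upper.tri(raw)] <- rnorm(15)
    raw[lower.tri(raw)] <- t(raw)[lower.tri(raw)]
    off <- raw[row(raw) != col(raw)]
    w <- netWeights(normalizeWeights(raw, epsilon = eps))
    woff <- w[row(w) != col(w)]
    tol <- 4 * .Machine$double.eps
    expect_lt(abs(woff[which.min(off)] - eps), tol)
    expect_lt(abs(woff[which.max(off)] - (1 - eps)), tol)
    expect_identical(order(off), order(woff))  # order-preserving affine map
  }
  # midpoint maps to 1/2 for any epsilon
  raw <- matrix(c(0, 1, 3, 1, 0, 2, 3, 2, 0), 3, 3)  # off-diag {1,2,3}
  for (eps in c(0.01, 0.2))
    expect_equal(netWeights(normalizeWeights(raw, eps))[2, 3], 0.5)
})

test_that("normalization refuses constant matrices and bad epsilon", {
  const <- matrix(1, 4, 4); diag(const) <- 0
  expect_error(normalizeWeights(const), "constant")
  raw <- matrix(rnorm(16), 4, 4); raw <- raw + t(raw)
  expect_error(normalizeWeights(raw, epsilon = 0), "epsilon")
  expect_error(normalizeWeights(raw, epsilon = 0.5), "epsilon")
})

test_that("pooled normalization shares one range across layers", {
  set.seed(32)
  mk <- function(scale) {
    m <- matrix(0, 5, 5)
    m[upper.tri(m)] <- rnorm(10, sd = scale)
    m + t(m)
  }
  raws <- list(mk(1), mk(3))
  pooled <- normalizeLayers(raws, scope = "pooled")
  per <- normalizeLayers(raws, scope = "per_network")
  allPooled <- unlist(lapply(pooled, function(p) upperValues(netWeights(p))))
  # pooled: global extrema hit eps / 1-eps exactly once across the group
  expect_equal(min(allPooled), 0.01)
  expect_equal(max(allPooled), 0.99)
  # per-network: every layer hits its own extrema
  for (p in per) {
    v <- upperValues(netWeights(p))
    expect_equal(min(v), 0.01)
    expect_equal(max(v), 0.99)
  }
})

test_that("proximity/distance isomorphisms evaluate and round-trip in both dialects", {
  w <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  d <- proxToDist(ProximityNetwork(w))
  expect_equal(netWeights(d)[1, 2], 1)   # w = 0.5 -> d = 1
  expect_identical(diag(netWeights(d)), c(node1 = 0, node2 = 0))
  back <- distToProx(DistanceNetwork(matrix(c(0, 3, 3, 0), 2, 2)))
  expect_equal(netWeights(back)[1, 2], 0.25)  # d = 3 -> w = 1/4
  expect_equal(netWeights(distToProx(DistanceNetwork(
    matrix(c(0, Inf, Inf, 0), 2, 2))))[1, 2], 0)  # unreachable -> 0

  set.seed(33)
  for (dialect in c("reciprocal", "log")) {
    for (i in 1:5) {
      p <- randomProximity(8)
      rt <- distToProx(proxToDist(p, dialect = dialect), dialect = dialect)
      expect_equal(netWeights(rt), netWeights(p), tolerance = 1e-12)
    }
  }
})

test_that("zero proximities are refused unless the infinite policy is chosen", {
  w <- matrix(c(1, 0, 0, 1), 2, 2)
  p <- new("ProximityNetwork", weights = w, nodeLabels = c("a", "b"),
           epsilon = NA_real_)
  expect_error(proxToDist(p), "epsilon")
  d <- proxToDist(p, zeroPolicy = "infinite")
  expect_identical(netWeights(d)[1, 2], Inf)
})

test_that("tropical product obeys semiring identities and the triple-loop oracle", {
  spec <- tropicalSemiring()
  expect_true(validObject(spec))
  set.seed(34)
  a <- matrix(sample(0:20, 25, replace = TRUE), 5, 5)
  expect_identical(semiringMatmul(a, tropicalIdentity(5)), a * 1)
  expect_identical(semiringMatmul(tropicalIdentity(5), a), a * 1)
  z <- matrix(0, 2, 2)
  expect_identical(semiringMatmul(z, z), z)
  for (i in 1:5) {
    x <- matrix(sample(0:30, 25, replace = TRUE), 5, 5)
    y <- matrix(sample(0:30, 25, replace = TRUE), 5, 5)
    expect_identical(semiringMatmul(x, y), tropMatmulLoop(x, y))
  }
  expect_error(semiringMatmul(matrix(NaN, 2, 2), z), "carrier")
  # generic fold path (operators looked up by name) agrees with the
  # vectorized min-plus fast path
  generic <- new("SemiringSpec", oplus = "pmin", otimes = "+",
                 carrier = "[0, Inf]", oplusIdentity = Inf,
                 otimesIdentity = 0)
  expect_equal(semiringMatmul(a, a, generic), semiringMatmul(a, a))
})

test_that("metric closure solves the 3-node shortcut and matches Floyd-Warshall", {
  d <- matrix(c(0, 1, 5, 1, 0, 1, 5, 1, 0), 3, 3)
  cl <- metricClosure(DistanceNetwork(d))
  expect_equal(netWeights(cl)[1, 3], 2)  # brute force over simple paths: min(5, 1+1)
  expect_true(isClosed(cl))

  set.seed(35)
  for (i in 1:10) {
    m <- randomDistanceMatrix(15, density = 0.3)
    expect_equal(metricClosure(m), fwClosure(m), tolerance = 1e-9)
  }
})

test_that("closure is idempotent, dominated by the input, and metric", {
  set.seed(36)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    m <- randomDistanceMatrix(n, density = 0.25)
    cl <- metricClosure(m)
    expect_identical(metricClosure(cl), cl)          # exact fixpoint
    expect_true(all(cl <= m))
    expect_identical(unname(diag(cl)), rep(0, n))
    expect_lt(max(abs(cl - t(cl))), 1e-9)
    # triangle inequality on every triple
    for (k in seq_len(n)) {
      slack <- outer(cl[, k], cl[k, ], "+") - cl
      expect_gte(min(slack), -1e-9)
    }
  }
})

test_that("accumulated tropical powers never increase and reach the closure", {
  set.seed(37)
  m <- randomDistanceMatrix(12, density = 0.3)
  acc <- m
  prev <- m
  for (k in 2:11) {
    acc2 <- pmin(acc, semiringMatmul(prev, m))
    expect_true(all(acc2 <= acc))
    prev <- semiringMatmul(prev, m)
    acc <- acc2
  }
  expect_equal(acc, metricClosure(m), tolerance = 1e-12)
  # truncated closure: maxPower caps the walk length
  r2 <- metricClosure(DistanceNetwork(m), maxPower = 2)
  full <- metricClosure(DistanceNetwork(m))
  expect_true(all(netWeights(full) <= netWeights(r2)))
})

test_that("closure rejects negative entries and handles infinities", {
  neg <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(metricClosure(neg), "negative")
  # two disconnected components stay at infinite distance
  m <- matrix(Inf, 4, 4); diag(m) <- 0
  m[1, 2] <- m[2, 1] <- 1; m[3, 4] <- m[4, 3] <- 2
  cl <- metricClosure(m)
  expect_identical(cl[1, 3], Inf)
  expect_identical(cl[1, 2], 1)
})
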