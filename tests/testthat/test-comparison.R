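closedNet <- function(n, seed) {
  set.seed(seed)
  metricClosure(proxToDist(randomProximity(n)))
}

test_that("z-scoring standardizes the upper-triangle edge distribution", {
  d <- closedNet(12, seed = 51)
  zs <- zscoreEmbedded(d)
  v <- zs$z[upper.tri(zs$z)]
  expect_lt(abs(mean(v)), 1e-9)
  expect_lt(abs(sd(v) - 1), 1e-9)
  expect_identical(unname(diag(zs$z)), rep(0, 12))

  # affine rescales of the input leave the z-scores untouched
  m2 <- 3.7 * netWeights(d) + 2; diag(m2) <- 0
  d2 <- DistanceNetwork(m2, isClosed = TRUE)
  expect_equal(zscoreEmbedded(d2)$z, zs$z, tolerance = 1e-9,
               ignore_attr = TRUE)

  # 4-node worked example against explicit arithmetic
  w <- matrix(0, 4, 4)
  w[upper.tri(w)] <- c(1, 2, 3, 4, 5, 7)
  w <- w + t(w)
  dn <- DistanceNetwork(w, isClosed = TRUE)
  v4 <- c(1, 2, 3, 4, 5, 7)
  mu <- sum(v4) / 6
  sdv <- sqrt(sum((v4 - mu)^2) / 5)
  zs4 <- zscoreEmbedded(dn)
  expect_equal(zs4$center, mu)
  expect_equal(zs4$scale, sdv)
  expect_equal(zs4$z[1, 2], (1 - mu) / sdv)

  expect_error(zscoreEmbedded(proxToDist(randomProximity(5))), "closed")
  const <- DistanceNetwork(matrix(1, 3, 3) - diag(3), isClosed = TRUE)
  expect_error(zscoreEmbedded(const), "degenerate")
})

test_that("difference grid vanishes for identical or affinely related inputs", {
  d <- closedNet(10, seed = 52)
  g <- differenceGrid(d, d)
  expect_true(all(netWeights(g) == 0))
  expect_true(all(displacement(g) == 0))

  m2 <- 2.5 * netWeights(d) + 1; diag(m2) <- 0
  d2 <- DistanceNetwork(m2, isClosed = TRUE)
  g2 <- differenceGrid(d, d2)
  expect_lt(max(netWeights(g2)), 1e-9)
})

test_that("difference grid is symmetric in its arguments and equivariant", {
  a <- closedNet(9, seed = 53)
  b <- closedNet(9, seed = 54)
  expect_identical(netWeights(differenceGrid(a, b)),
                   netWeights(differenceGrid(b, a)))

  # relabeling/permutation of nodes permutes displacements identically
  p <- sample(9)
  perm <- function(d) {
    m <- netWeights(d)[p, p]
    DistanceNetwork(m, nodeLabels = nodeLabels(d)[p], dialect = d@dialect,
                    isClosed = TRUE)
  }
  g <- differenceGrid(a, b)
  gp <- differenceGrid(perm(a), perm(b))
  expect_equal(unname(displacement(gp)), unname(displacement(g)[p]))
})

test_that("displacement norms relate as rms = euclidean / sqrt(n-1)", {
  a <- closedNet(8, seed = 55)
  b <- closedNet(8, seed = 56)
  rms <- displacement(differenceGrid(a, b, normType = "rms"))
  euc <- displacement(differenceGrid(a, b, normType = "euclidean"))
  expect_equal(euc, rms * sqrt(7), tolerance = 1e-12)
})

test_that("hypersphere detection partitions nodes and its curve is monotone", {
  a <- closedNet(15, seed = 57)
  b <- closedNet(15, seed = 58)
  g <- differenceGrid(a, b)
  rep1 <- detectNodes(g, s = 1)
  expect_setequal(c(rep1@insideLabels, rep1@outsideLabels), nodeLabels(g))
  expect_identical(sort(rep1@outsideLabels),
                   sort(names(which(displacement(g) > 1))))

  # zero grid: everything inside at any radius
  g0 <- differenceGrid(a, a)
  expect_length(detectNodes(g0, s = 0.001)@outsideLabels, 0)

  # s -> 0+: every node with nonzero displacement is outside
  tiny <- detectNodes(g, s = 1e-12)
  expect_setequal(tiny@outsideLabels, names(which(displacement(g) > 1e-12)))

  radii <- seq(0, max(displacement(g)) + 0.5, length.out = 40)
  curve <- countWithinRadius(g, radii)
  expect_true(all(diff(curve$countInside) >= 0))
  expect_identical(curve$countInside[40], 15L)
  expect_error(detectNodes(g, s = -1), "positive")

  tab <- detectionTable(g, radii = c(0.5, 1))
  expect_identical(tab$inside_s1, unname(displacement(g) <= 1))
})

test_that("fraction outside the sphere shrinks as the radius grows", {
  set.seed(59)
  fracs <- sapply(1:10, function(i) {
    a <- closedNet(20, seed = 600 + i)
    b <- closedNet(20, seed = 700 + i)
    g <- differenceGrid(a, b)
    c(mean(displacement(g) > 1), mean(displacement(g) > 1.5))
  })
  expect_gt(mean(fracs[1, ]), 0)
  expect_true(all(fracs[2, ] <= fracs[1, ]))
})

test_that("classical MDS reproduces Euclidean configurations exactly", {
  set.seed(61)
  X <- matrix(rnorm(20 * 3), 20, 3)
  D <- as.matrix(dist(X))
  proj <- mdsProject(D, k = 3)
  expect_lt(proj@stress, 1e-6)
  pro <- vegan::procrustes(X, proj@coordinates, symmetric = TRUE)
  expect_lt(pro$ss, 1e-6)

  # k = n - 1 on a Euclidean matrix reconstructs it exactly
  X8 <- matrix(rnorm(8 * 3), 8, 3)
  proj8 <- mdsProject(as.matrix(dist(X8)), k = 7)
  expect_lt(proj8@stress, 1e-6)

  # colinear 1D configuration: spacing recovered up to reflection/shift
  pts <- c(0, 1, 2, 3, 4)
  D1 <- abs(outer(pts, pts, "-"))
  proj1 <- mdsProject(D1, k = 1)
  rec <- proj1@coordinates[, 1]
  gaps <- diff(sort(rec))
  expect_equal(gaps, rep(1, 4), tolerance = 1e-9)

  expect_error(mdsProject(D1, k = 5), "smaller")
})

test_that("MDS stress is non-increasing in the projection dimension", {
  # monotonicity is guaranteed for Euclidean inputs, where every added
  # eigen-dimension moves the configuration distances toward the input
  set.seed(62)
  X <- matrix(rnorm(15 * 10), 15, 10)
  D <- as.matrix(dist(X))
  stresses <- vapply(1:8, function(k) mdsProject(D, k)@stress, 0)
  expect_true(all(diff(stresses) <= 1e-12))
})

test_that("modality comparison pipeline recovers planted discordant nodes", {
  pair <- genModalityPair(synthSpec(seed = 63, nNodes = 40,
                                    nPerturbedNodes = 3))
  res <- compareModalities(pair$a, pair$b)
  disp <- displacement(res$grid)
  top3 <- names(sort(disp, decreasing = TRUE))[1:3]
  expect_setequal(top3, pair$perturbed)
  expect_setequal(res$reports[["s1"]]@outsideLabels, pair$perturbed)
  expect_s4_class(res$mds, "MdsProjection")
  # unclosed distance input is refused
  expect_error(compareModalities(proxToDist(pair$a), pair$b), "closed")
})
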