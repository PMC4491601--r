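test_that("generators are pure functions of the spec seed", {
  sp <- synthSpec(seed = 71, nNodes = 20, nLayers = 4, nTimepoints = 60)
  expect_identical(genCorrelatedTimeseries(sp)$ts@signals,
                   genCorrelatedTimeseries(sp)$ts@signals)
  m1 <- genMultiplex(sp); m2 <- genMultiplex(sp)
  expect_identical(lapply(m1$multiplex@layers, netWeights),
                   lapply(m2$multiplex@layers, netWeights))
  p1 <- genModalityPair(sp); p2 <- genModalityPair(sp)
  expect_identical(netWeights(p1$b), netWeights(p2$b))
  expect_identical(p1$perturbed, p2$perturbed)
  # and they do not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(genMultiplex(sp)); after <- runif(1)
  expect_identical(before, after)
})

test_that("seed is mandatory and spec fields are validated", {
  expect_error(synthSpec(), "mandatory")
  expect_error(synthSpec(seed = 1, backboneDensity = 0), "backboneDensity")
  expect_error(synthSpec(seed = 1, nPerturbedNodes = 10, nNodes = 10),
               "nPerturbedNodes")
  expect_error(synthSpec(seed = 1, arCoefficient = 1), "arCoefficient")
})

test_that("time series recover the planted correlation structure", {
  # identity target, no autocorrelation: off-diagonal r stays small
  spId <- synthSpec(seed = 72, nNodes = 4, nTimepoints = 1e4,
                    arCoefficient = 0)
  resId <- genCorrelatedTimeseries(spId, target = diag(4))
  r <- zeroLagCorrelation(resId$ts)
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)

  # planted r12 = 0.6 recovered within Monte-Carlo tolerance
  tgt <- diag(3); tgt[1, 2] <- tgt[2, 1] <- 0.6
  for (seed in 73:75) {
    sp <- synthSpec(seed = seed, nNodes = 3, nTimepoints = 1e4)
    res <- genCorrelatedTimeseries(sp, target = tgt)
    r12 <- zeroLagCorrelation(res$ts)[1, 2]
    expect_gt(r12, 0.55); expect_lt(r12, 0.65)
  }

  # AR(1) filtering preserves the planted zero-lag correlation
  spAr <- synthSpec(seed = 76, nNodes = 3, nTimepoints = 1e4,
                    arCoefficient = 0.6)
  rAr <- zeroLagCorrelation(genCorrelatedTimeseries(spAr, target = tgt)$ts)
  expect_gt(rAr[1, 2], 0.55); expect_lt(rAr[1, 2], 0.65)
})

test_that("non-positive-definite targets are repaired with a warning", {
  bad <- matrix(0.9, 3, 3); bad[1, 2] <- bad[2, 1] <- -0.9; diag(bad) <- 1
  sp <- synthSpec(seed = 77, nNodes = 3, nTimepoints = 100)
  expect_warning(res <- genCorrelatedTimeseries(sp, target = bad),
                 "positive definite")
  ev <- eigen(res$target, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-9)
})

test_that("multiplex layers satisfy proximity invariants without repair", {
  mx <- genMultiplex(synthSpec(seed = 78, nNodes = 30, nLayers = 5))
  for (l in mx$multiplex@layers) expect_true(validObject(l))
  expect_true(validObject(mx$truth))
  expect_true(isClosed(mx$truth))
})

test_that("realized densities track the spec within binomial tolerance", {
  dens <- c(); noise <- c()
  for (seed in 80:89) {
    sp <- synthSpec(seed = seed, nNodes = 40, nLayers = 3,
                    backboneDensity = 0.2, noiseDensity = 0.1)
    mx <- genMultiplex(sp)
    nPairs <- 40 * 39 / 2
    dens <- c(dens, sum(mx$mask[upper.tri(mx$mask)]) / nPairs)
    # noise edges: off-backbone pairs above the floor in layer 1
    w <- netWeights(mx$multiplex[[1]])
    offBack <- upper.tri(w) & !mx$mask
    noise <- c(noise, mean(w[offBack] > 0.01))
  }
  # 10 replicates of Bin(780, p): the mean sits within ~4 joint SEs
  expect_lt(abs(mean(dens) - 0.2), 4 * sqrt(0.2 * 0.8 / 780 / 10))
  expect_lt(abs(mean(noise) - 0.1), 4 * sqrt(0.1 * 0.9 / 780 / 10))
})

test_that("without noise and dropout, layers are identical up to attenuation", {
  sp <- synthSpec(seed = 90, nNodes = 25, nLayers = 3, noiseDensity = 0,
                  backbonePrevalence = 1)
  mx <- genMultiplex(sp)
  truthW <- netWeights(mx$strengths)
  for (l in mx$multiplex@layers) {
    w <- netWeights(l)
    # support identical to the backbone, weights at or below the ceiling
    expect_identical(w > 0.01, truthW > 0.01)
    expect_true(all(w[mx$mask] <= truthW[mx$mask] + 1e-12))
  }
})

test_that("layers with a negligible backbone are mutually independent", {
  sp <- synthSpec(seed = 91, nNodes = 20, nLayers = 2,
                  backboneDensity = 1e-6, noiseDensity = 0.3)
  mx <- genMultiplex(sp)
  w1 <- netWeights(mx$multiplex[[1]]); w2 <- netWeights(mx$multiplex[[2]])
  offFloor1 <- w1[upper.tri(w1)] > 0.01
  offFloor2 <- w2[upper.tri(w2)] > 0.01
  # noise supports drawn independently per layer: overlap near product
  expect_lt(mean(offFloor1 & offFloor2), 0.3 * 0.3 + 0.15)
})

test_that("backbone edges embed closer than noise-only edges", {
  mx <- genMultiplex(synthSpec(seed = 92))
  emb <- embedGroup(mx$multiplex, method = "algebraic")$embedded
  w <- netWeights(emb); ut <- upper.tri(w)
  expect_lt(mean(w[ut & mx$mask]), mean(w[ut & !mx$mask]))
})

test_that("modality pairs plant the advertised perturbation", {
  spNull <- synthSpec(seed = 93, nNodes = 30, perturbationMagnitude = 0)
  pairNull <- genModalityPair(spNull)
  expect_equal(netWeights(pairNull$a), netWeights(pairNull$b),
               tolerance = 1e-12)

  for (seed in 94:96) {
    pair <- genModalityPair(synthSpec(seed = seed, nNodes = 30))
    dA <- netWeights(proxToDist(pair$a))
    dB <- netWeights(proxToDist(pair$b))
    delta <- abs(dB - dA)
    idx <- nodeLabels(pair$a) %in% pair$perturbed
    incident <- outer(idx, idx, "|") & upper.tri(delta)
    expect_gt(mean(delta[incident]), mean(delta[!incident & upper.tri(delta)]))
  }
})
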