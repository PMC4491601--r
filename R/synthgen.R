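#' @include AllClasses.R utils.R algebra.R
NULL

# Default planted correlation target: compound-symmetry blocks of ~5
# nodes with within-block correlation backboneStrength. Block structure
# keeps the target positive definite by construction.
.defaultTarget <- function(spec) {
  n <- spec@nNodes
  blocks <- rep(seq_len(ceiling(n / 5)), each = 5, length.out = n)
  tgt <- outer(blocks, blocks, "==") * spec@backboneStrength
  diag(tgt) <- 1
  tgt
}

#' Generate autocorrelated time series with a planted correlation structure
#'
#' Draws AR(1)-filtered Gaussian signals whose innovations are correlated
#' according to `target` (Cholesky factorization). With a common AR
#' coefficient across nodes, the stationary zero-lag correlation of the
#' filtered signals equals the innovation correlation, so `target` is the
#' ground truth the connectivity module should recover. A burn-in of 200
#' samples is discarded for stationarity.
#'
#' @param spec a [SynthSpec-class] (`nNodes`, `nTimepoints`,
#'   `arCoefficient`, `seed` are used; the default `target` also uses
#'   `backboneStrength`).
#' @param target optional planted correlation matrix; must be positive
#'   definite (non-PD inputs are repaired to the nearest correlation
#'   matrix with a warning). Default: compound-symmetry blocks of 5
#'   nodes at correlation `backboneStrength`.
#' @return list with `ts` (a [TimeSeriesSet-class]) and `target` (the
#'   planted correlation matrix actually used).
#' @export
genCorrelatedTimeseries <- function(spec, target = NULL) {
  stopifnot(is(spec, "SynthSpec"))
  if (is.null(target)) target <- .defaultTarget(spec)
  stopIfNotSquareNumeric(target, "target correlation matrix")
  ev <- eigen(target, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    warning("target correlation matrix is not positive definite; ",
            "repairing to the nearest correlation matrix")
    target <- as.matrix(Matrix::nearPD(target, corr = TRUE)$mat)
  }
  n <- spec@nNodes
  Tn <- spec@nTimepoints
  burn <- 200L
  withSeed(spec@seed, {
    L <- chol(target)
    eps <- matrix(stats::rnorm((Tn + burn) * n), Tn + burn, n) %*% L
    x <- matrix(0, Tn + burn, n)
    x[1, ] <- eps[1, ] / sqrt(1 - spec@arCoefficient^2)
    for (t in 2:(Tn + burn))
      x[t, ] <- spec@arCoefficient * x[t - 1, ] + eps[t, ]
    signals <- t(x[(burn + 1):(burn + Tn), , drop = FALSE])
  })
  labels <- paste0("node", seq_len(n))
  ts <- TimeSeriesSet(signals, nodeLabels = labels,
                      samplingNote = sprintf("synthetic AR(1) phi=%.2f",
                                             spec@arCoefficient))
  dimnames(target) <- list(labels, labels)
  list(ts = ts, target = target)
}

# One proximity layer: floor everywhere, expressed backbone edges at
# strengths * per-layer attenuation, spurious noise edges uniform in
# (eps, 0.4]. All sampling on the upper triangle, mirrored down.
.synthLayer <- function(n, mask, strengths, expressed, noiseMask, noiseW, eps) {
  w <- matrix(eps, n, n)
  w[mask & expressed] <- strengths[mask & expressed]
  w[noiseMask] <- noiseW[noiseMask]
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  w <- pmin(pmax(w, eps), 1 - eps)
  diag(w) <- 1
  w
}

#' Generate a multiplex ensemble with a planted common backbone
#'
#' Emulates a group of subjects sharing a weighted backbone: a Bernoulli
#' (`backboneDensity`) edge mask with per-edge true proximity strengths
#' (lognormal jitter around `backboneStrength`, shared by all layers).
#' Each layer expresses each backbone edge independently with
#' probability `backbonePrevalence` (inter-subject variability) and
#' attenuates it by a downward half-lognormal factor
#' `exp(-|N(0, noiseStrengthSd)|)` — a subject realizes a connection at
#' or below its ceiling strength, never above — and adds independent
#' spurious noise edges (per-layer Bernoulli `noiseDensity` on
#' non-backbone pairs, weak-to-moderate proximity uniform in
#' `(eps, 0.4]`). Overlaps are resolved backbone-first. Unexpressed and
#' non-edges sit at the proximity floor `eps`.
#'
#' The ground truth is the backbone network itself (true strengths on
#' the mask, floor elsewhere), returned both as a proximity network and
#' as its closed distance embedding.
#'
#' @param spec a [SynthSpec-class].
#' @param epsilon proximity floor/ceiling margin; default 0.01.
#' @return list with `multiplex` (proximity-space
#'   [MultiplexNetwork-class]), `mask` (logical backbone mask),
#'   `strengths` (true backbone proximity matrix), `truth` (closed
#'   ground-truth [DistanceNetwork-class]).
#' @export
genMultiplex <- function(spec, epsilon = 0.01) {
  stopifnot(is(spec, "SynthSpec"))
  n <- spec@nNodes
  labels <- paste0("node", seq_len(n))
  withSeed(spec@seed, {
    ut <- upper.tri(matrix(0, n, n))
    mask <- matrix(FALSE, n, n)
    mask[ut] <- stats::runif(sum(ut)) < spec@backboneDensity
    sTrue <- matrix(epsilon, n, n)
    jit <- exp(stats::rnorm(sum(mask), 0, spec@noiseStrengthSd))
    sTrue[mask] <- pmin(pmax(spec@backboneStrength * jit, epsilon), 1 - epsilon)
    layers <- vector("list", spec@nLayers)
    for (k in seq_len(spec@nLayers)) {
      expressed <- matrix(FALSE, n, n)
      expressed[ut] <- stats::runif(sum(ut)) < spec@backbonePrevalence
      layerJit <- matrix(1, n, n)
      layerJit[ut] <- exp(-abs(stats::rnorm(sum(ut), 0, spec@noiseStrengthSd)))
      noiseMask <- matrix(FALSE, n, n)
      noiseMask[ut & !mask] <- stats::runif(sum(ut & !mask)) < spec@noiseDensity
      noiseW <- matrix(epsilon, n, n)
      noiseW[noiseMask] <- stats::runif(sum(noiseMask), epsilon, 0.4)
      layers[[k]] <- ProximityNetwork(
        .synthLayer(n, mask, sTrue * layerJit, expressed, noiseMask,
                    noiseW, epsilon),
        nodeLabels = labels, epsilon = epsilon)
    }
  })
  truthProx <- sTrue
  truthProx[lower.tri(truthProx)] <- t(truthProx)[lower.tri(truthProx)]
  diag(truthProx) <- 1
  truthProxNet <- ProximityNetwork(truthProx, nodeLabels = labels,
                                   epsilon = epsilon)
  mask[lower.tri(mask)] <- t(mask)[lower.tri(mask)]
  list(multiplex = MultiplexNetwork(layers,
                                    layerIds = paste0("subject", seq_len(spec@nLayers))),
       mask = mask,
       strengths = truthProxNet,
       truth = metricClosure(proxToDist(truthProxNet)))
}

#' Generate a paired-modality network with planted discordant nodes
#'
#' Emulates comparing an aggregated functional network with a structural
#' one: network A is a single backbone realization (graded backbone
#' strengths plus weak noise edges); network B equals A except that
#' every edge incident to `nPerturbedNodes` randomly chosen nodes is
#' weakened. The perturbation is applied in distance space as an
#' additive shift of `perturbationMagnitude` times the standard
#' deviation of A's closed embedded edge distribution, so the planted
#' effect size is expressed in the SD units the difference grid
#' measures.
#'
#' @param spec a [SynthSpec-class].
#' @param epsilon proximity floor/ceiling margin; default 0.01.
#' @return list with `a`, `b` ([ProximityNetwork-class] pair),
#'   `perturbed` (character labels of the planted nodes), and
#'   `embeddedSd` (the SD of A's embedded edge distribution used to
#'   scale the perturbation).
#' @export
genModalityPair <- function(spec, epsilon = 0.01) {
  stopifnot(is(spec, "SynthSpec"))
  n <- spec@nNodes
  labels <- paste0("node", seq_len(n))
  withSeed(spec@seed, {
    ut <- upper.tri(matrix(0, n, n))
    mask <- matrix(FALSE, n, n)
    mask[ut] <- stats::runif(sum(ut)) < spec@backboneDensity
    w <- matrix(epsilon, n, n)
    jit <- exp(stats::rnorm(sum(mask), 0, spec@noiseStrengthSd))
    w[mask] <- pmin(pmax(spec@backboneStrength * jit, epsilon), 1 - epsilon)
    noiseMask <- matrix(FALSE, n, n)
    noiseMask[ut & !mask] <- stats::runif(sum(ut & !mask)) < spec@noiseDensity
    w[noiseMask] <- stats::runif(sum(noiseMask), epsilon, 0.4)
    w[lower.tri(w)] <- t(w)[lower.tri(w)]
    diag(w) <- 1
    perturbed <- sort(sample.int(n, spec@nPerturbedNodes))
  })
  a <- ProximityNetwork(w, nodeLabels = labels, epsilon = epsilon)
  da <- proxToDist(a)
  sdA <- stats::sd(upperValues(metricClosure(da)@weights))
  shift <- spec@perturbationMagnitude * sdA
  dw <- da@weights
  if (shift > 0) {
    S <- matrix(0, n, n)
    S[perturbed, ] <- shift   # each incident edge shifted exactly once,
    S[, perturbed] <- shift   # including edges between two planted nodes
    dw <- dw + S
    diag(dw) <- 0
    dw <- symmetrizeUpper(dw)
  }
  b <- distToProx(DistanceNetwork(dw, nodeLabels = labels,
                                  dialect = "reciprocal"))
  list(a = a, b = b, perturbed = labels[perturbed], embeddedSd = sdA)
}
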