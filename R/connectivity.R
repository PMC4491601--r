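#' @include AllClasses.R utils.R
NULL

#' Zero-lag Pearson correlation between all node pairs
#'
#' A functional link between two regional signals is the temporal average
#' of their product after each signal is normalized to zero mean and unit
#' variance, i.e. the zero-lag Pearson correlation. Lagged and spectral
#' couplings are deliberately out of scope.
#'
#' @param ts a [TimeSeriesSet-class].
#' @return symmetric node x node correlation matrix, diagonal exactly 1.
#' @export
zeroLagCorrelation <- function(ts) {
  stopifnot(is(ts, "TimeSeriesSet"))
  x <- ts@signals
  v <- apply(x, 1, stats::var)
  if (any(v == 0)) {
    bad <- ts@nodeLabels[which(v == 0)]
    stop("constant signal (zero variance) for node(s): ",
         paste(bad, collapse = ", "))
  }
  r <- stats::cor(t(x))
  diag(r) <- 1
  r <- symmetrizeUpper(r)
  dimnames(r) <- list(ts@nodeLabels, ts@nodeLabels)
  r
}

#' Fisher Z variance-stabilizing transform
#'
#' `Z = 0.5 * log((1 + r) / (1 - r))`, an odd function of `r`, mapping
#' correlations in (-1, 1) to the whole real line. Values with
#' `|r| >= 1` are refused: whether (and how) to clip is the caller's
#' decision, since silent clipping hides duplicated signals.
#'
#' @param r correlation value(s) in (-1, 1); vector or matrix.
#' @return transformed value(s), same shape.
#' @seealso [fisherZInv()] for the inverse (tanh).
#' @export
fisherZ <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE))
    stop("|r| >= 1 is outside the domain of the Fisher Z transform; ",
         "clip explicitly if this is intended")
  atanh(r)
}

#' Inverse Fisher Z transform
#' @param z real value(s).
#' @return correlation value(s) in (-1, 1).
#' @export
fisherZInv <- function(z) tanh(z)

# Effective-df from per-node autocorrelation rows A (nodes x lags) with
# taper weights w = (N - tau)/N: 1/df_ij = 1/N + (2/N) sum_tau w_tau A_i A_j.
dfFromAutocorr <- function(A, N) {
  nlag <- ncol(A)
  if (nlag == 0) {
    inv <- matrix(1 / N, nrow(A), nrow(A))
  } else {
    w <- (N - seq_len(nlag)) / N
    S <- (A * rep(w, each = nrow(A))) %*% t(A)
    inv <- 1 / N + (2 / N) * S
  }
  bad <- inv <= 0
  if (any(bad)) {
    warning("pathological autocorrelation sums for ", sum(bad),
            " pair(s); clamping df_eff to just above 3")
    inv[bad] <- 1 / (3 + 1e-8)
  }
  df <- 1 / inv
  symmetrizeUpper(df)
}

#' Effective degrees of freedom under autocorrelation
#'
#' Autocorrelated signals violate the independence assumption behind the
#' standard significance test of a correlation, inflating Type I error.
#' The sample size is corrected per pair by
#' `1/df_ij = 1/N + (2/N) * sum_tau ((N - tau)/N) * r_ii(tau) * r_jj(tau)`,
#' where `r_xx(tau)` is the biased sample autocorrelation of signal `x`.
#' For mutually independent white noise `df_eff` is close to `N`; it
#' shrinks as autocorrelation grows.
#'
#' The lag sum runs over `tau = 1 ... maxLag`. The default `maxLag`
#' (`floor(N/5)`) retains any realistic autocorrelation while keeping the
#' variance of the correction low; pass `maxLag = N - 1` for the full
#' taper range. Pairs whose computed `1/df` is nonpositive (pathological
#' autocorrelation sums) are clamped to just above `df = 3` with a
#' warning, so the null variance `1/(df - 3)` stays positive.
#'
#' @param ts a [TimeSeriesSet-class].
#' @param maxLag largest lag entering the sum; default `floor(N/5)`.
#' @return symmetric node x node matrix of effective degrees of freedom.
#' @export
effectiveDF <- function(ts, maxLag = NULL) {
  stopifnot(is(ts, "TimeSeriesSet"))
  x <- ts@signals
  N <- ncol(x)
  if (is.null(maxLag)) maxLag <- floor(N / 5)
  maxLag <- min(as.integer(maxLag), N - 1)
  A <- t(apply(x, 1, function(s)
    stats::acf(s, lag.max = maxLag, plot = FALSE, demean = TRUE)$acf[-1]))
  if (maxLag == 1) A <- matrix(A, ncol = 1)  # apply() drops to a vector
  df <- dfFromAutocorr(A, N)
  dimnames(df) <- list(ts@nodeLabels, ts@nodeLabels)
  df
}

#' Two-sided significance of a Fisher Z value
#'
#' Under independence, `Z` is normal with mean 0 and variance
#' `1/(df - 3)`; the p-value is the two-sided tail probability of the
#' observed `Z` under that null.
#'
#' @param z Fisher Z value(s).
#' @param dfEff effective degrees of freedom, same shape; must exceed 3.
#' @return two-sided p-value(s).
#' @export
zSignificance <- function(z, dfEff) {
  if (any(dfEff <= 3))
    stop("df_eff must exceed 3 for the null variance 1/(df - 3) to exist")
  2 * stats::pnorm(-abs(z) * sqrt(dfEff - 3))
}

#' Full zero-lag correlation analysis
#'
#' Computes the correlation matrix, its Fisher Z transform, the
#' autocorrelation-corrected effective degrees of freedom and the
#' two-sided significance of each edge in one pass.
#'
#' Off-diagonal correlations numerically equal to +/-1 indicate
#' duplicated (or sign-flipped) signals and raise an error rather than
#' being clipped silently.
#'
#' @param ts a [TimeSeriesSet-class].
#' @param maxLag passed to [effectiveDF()].
#' @return a [CorrelationResult-class].
#' @export
correlationAnalysis <- function(ts, maxLag = NULL) {
  r <- zeroLagCorrelation(ts)
  off <- abs(r[row(r) != col(r)])
  if (any(off >= 1 - 1e-12)) {
    idx <- which(abs(r) >= 1 - 1e-12 & row(r) != col(r), arr.ind = TRUE)
    stop("off-diagonal |r| = 1 between nodes ",
         paste(unique(apply(idx, 1, function(k)
           paste(ts@nodeLabels[k], collapse = "/"))), collapse = ", "),
         "; signals appear duplicated")
  }
  z <- r
  z[row(z) != col(z)] <- fisherZ(r[row(r) != col(r)])
  diag(z) <- 0  # self-coupling carries no information; excluded downstream
  df <- effectiveDF(ts, maxLag = maxLag)
  p <- matrix(1, nrow(r), ncol(r), dimnames = dimnames(r))
  offIdx <- row(r) != col(r)
  p[offIdx] <- zSignificance(z[offIdx], df[offIdx])
  p <- symmetrizeUpper(p)
  new("CorrelationResult", r = r, z = z, dfEff = df, pvalue = p,
      nodeLabels = ts@nodeLabels, nObs = ncol(ts@signals))
}

#' Build a functional proximity network from time series
#'
#' Runs the full connectivity pipeline: zero-lag correlation, Fisher Z,
#' then affine normalization of the Z weights into `[epsilon, 1 - epsilon]`
#' (see [normalizeWeights()]). By default all Z values are kept, mirroring
#' the pipeline in which normalization consumes the raw Z matrix; setting
#' `alpha` zeroes non-significant Z values (two-sided test at that level,
#' using the autocorrelation-corrected df) before normalization.
#'
#' @param ts a [TimeSeriesSet-class].
#' @param epsilon normalization margin in (0, 0.5); default 0.01.
#' @param alpha optional significance level for zeroing non-significant
#'   edges before normalization; default `NULL` (keep all).
#' @param maxLag passed to [effectiveDF()].
#' @return a [ProximityNetwork-class].
#' @export
buildFunctionalNetwork <- function(ts, epsilon = 0.01, alpha = NULL,
                                   maxLag = NULL) {
  res <- correlationAnalysis(ts, maxLag = maxLag)
  z <- res@z
  if (!is.null(alpha)) z[res@pvalue > alpha] <- 0
  normalizeWeights(z, epsilon = epsilon, nodeLabels = res@nodeLabels)
}
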