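#' Pointwise ensemble mean and variance
#'
#' Across an ensemble of repeated constant-voltage traces, computes the
#' pointwise mean and the unbiased (M - 1 denominator) variance.
#'
#' @param traces M x T matrix, one trace per row
#' @return list with numeric vectors `mean` and `var` of length T
#' @export
ensembleVariance <- function(traces) {
  traces <- as.matrix(traces)
  if (nrow(traces) < 2) stop("need at least 2 traces")
  m <- colMeans(traces)
  v <- colSums(sweep(traces, 2, m)^2) / (nrow(traces) - 1)
  list(mean = m, var = v)
}

#' Steady-state variance/mean point of an ensemble
#'
#' Trailing-window average of the pointwise mean and variance series —
#' the steady-state summary used as one point of the variance-mean
#' relation.
#'
#' @param varSeries,meanSeries pointwise series from [ensembleVariance()]
#' @param windowFraction trailing fraction to average over
#' @return named numeric `c(mean, var)`
#' @export
steadyStatePoint <- function(varSeries, meanSeries, windowFraction = 0.25) {
  stopifnot(length(varSeries) == length(meanSeries),
            windowFraction > 0, windowFraction <= 1)
  n <- length(varSeries)
  k <- max(1, ceiling(windowFraction * n))
  idx <- seq(n - k + 1, n)
  c(mean = mean(meanSeries[idx]), var = mean(varSeries[idx]))
}

#' Fit the variance-mean parabola
#'
#' Least-squares fit of `var = mean * i - mean^2 / N` across activity
#' levels, yielding the single-channel current `i` and channel count
#' `N`. The fit is linear in the `(i, 1/N)` parameterization, which is
#' well conditioned in the low-Po, near-linear regime.
#'
#' @param meanI,varI steady-state mean currents (pA) and variances
#'   (pA^2), at least 3 points with distinct means
#' @return list with `iSinglePA`, `nChannels` and the `lm` fit
#' @export
fitVarianceMean <- function(meanI, varI) {
  ok <- is.finite(meanI) & is.finite(varI)
  meanI <- meanI[ok]; varI <- varI[ok]
  if (length(unique(meanI)) < 3)
    stop("need at least 3 points with distinct mean currents")
  fit <- stats::lm(varI ~ 0 + meanI + I(meanI^2))
  cf <- stats::coef(fit)
  if (!is.finite(cf[[2]]) || abs(cf[[2]]) < .Machine$double.eps)
    stop("degenerate variance-mean design (collinear points)")
  list(iSinglePA = cf[[1]], nChannels = -1 / cf[[2]], fit = fit)
}

#' Open probability from mean current
#'
#' `Po = mean_I / (N * i)`; values outside \[0, 1\] are reported
#' unclipped with a flag.
#'
#' @param meanI mean current (pA)
#' @param N channel count
#' @param iSingle single-channel current (pA)
#' @return numeric Po (attribute `"flag"` marks values outside
#'   \[-0.05, 1.05\])
#' @export
openProbability <- function(meanI, N, iSingle) {
  if (N * iSingle == 0) stop("N * i must be nonzero")
  po <- meanI / (N * iSingle)
  attr(po, "flag") <- po > 1.05 | po < -0.05
  po
}

#' Stationary noise analysis of an agonist concentration series
#'
#' Full pipeline: per-concentration ensemble mean/variance, steady-state
#' points, variance-mean parabola fit for `(i, N)`, and per-concentration
#' open probability. Baseline (no-agonist) variance subtraction is off
#' by default and available via `baselineVar`.
#'
#' @param ensembles named list of M x T trace matrices, one per agonist
#'   concentration
#' @param conc_M agonist concentrations (mol/L), same length/order
#' @param windowFraction trailing steady-state window
#' @param baselineVar optional variance (pA^2) to subtract from every
#'   steady-state variance before fitting
#' @return a [NoiseResult]
#' @export
noiseAnalysis <- function(ensembles, conc_M, windowFraction = 0.25,
                          baselineVar = 0) {
  stopifnot(length(ensembles) == length(conc_M))
  pts <- t(vapply(ensembles, function(m) {
    ev <- ensembleVariance(m)
    steadyStatePoint(ev$var, ev$mean, windowFraction)
  }, c(mean = 0, var = 0)))
  v <- pts[, "var"] - baselineVar
  vm <- fitVarianceMean(pts[, "mean"], v)
  po <- openProbability(pts[, "mean"], vm$nChannels, vm$iSinglePA)
  new("NoiseResult", iSinglePA = vm$iSinglePA, nChannels = vm$nChannels,
      table = data.frame(conc_M = conc_M, mean_I_pA = pts[, "mean"],
                         var_pA2 = v, Po = as.numeric(po),
                         Po_flag = attr(po, "flag")),
      converged = TRUE)
}
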