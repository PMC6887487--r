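#' Fraction of current blocked
#'
#' `F = 1 - (I_Ag - I_ctrl) / (I_0 - I_ctrl)`, where `I_Ag` is the
#' current in blocker, `I_ctrl` the control current without agonist and
#' `I_0` the agonist current without blocker. Not clipped: noise can
#' push F slightly outside \[0, 1\].
#'
#' @param I_Ag,I_ctrl,I_0 currents (pA)
#' @return fraction blocked
#' @export
fractionBlocked <- function(I_Ag, I_ctrl, I_0) {
  if (any(abs(I_0 - I_ctrl) < .Machine$double.eps * 4 * pmax(1, abs(I_0))))
    stop("degenerate input: I_0 equals I_ctrl")
  1 - (I_Ag - I_ctrl) / (I_0 - I_ctrl)
}

.hillCurve <- function(conc, base, maxF, K, s)
  base + (maxF - base) / (1 + (K / conc)^s)

## parameter standard errors from a converged nls.lm fit
.lmSE <- function(fit, n) {
  p <- length(fit$par)
  se <- rep(NA_real_, p)
  if (n > p) {
    s2 <- fit$deviance / (n - p)
    cv <- try(solve(fit$hessian) * s2, silent = TRUE)
    if (!inherits(cv, "try-error")) {
      dg <- diag(cv)
      se <- ifelse(dg >= 0, sqrt(dg), NA_real_)
    }
  }
  stats::setNames(se, names(fit$par))
}

#' Fit the Hill equation to a dose-response relation
#'
#' Fits `F = base + (max - base) / (1 + (K/x)^s)` by least squares, with
#' the Hill coefficient fixed at 1 by default (base and max free, since
#' neither leak nor the unblocked maximum is perfectly constrained
#' experimentally). The midpoint is fitted as `log K` to enforce
#' positivity across the nM-pM range.
#'
#' @param conc_M concentrations (mol/L), at least 3 distinct
#' @param F response (fraction blocked, or any saturating response)
#' @param sFixed Hill coefficient to fix, or `NA` to fit it freely
#' @param weights optional inverse-variance weights
#' @param start optional named list overriding self-starting values
#' @return a [HillFit]
#' @export
fitHill <- function(conc_M, F, sFixed = 1.0, weights = NULL,
                    start = NULL) {
  ok <- is.finite(conc_M) & is.finite(F) & conc_M > 0
  conc_M <- conc_M[ok]; F <- F[ok]
  if (length(unique(conc_M)) < 3)
    stop("need at least 3 distinct concentrations")
  free_s <- is.na(sFixed)
  if (is.null(weights)) weights <- rep(1, length(F))
  w <- sqrt(weights)
  ## self-start: midpoint from the concentration nearest the half response
  yr <- range(F)
  half <- (yr[1] + yr[2]) / 2
  k0 <- conc_M[which.min(abs(F - half))]
  st <- list(base = min(F), maxF = max(F), logK = log(k0))
  if (free_s) st$s <- 1
  if (!is.null(start)) st[names(start)] <- start
  resid <- function(p) {
    s <- if (free_s) p$s else sFixed
    w * (F - .hillCurve(conc_M, p$base, p$maxF, exp(p$logK), s))
  }
  fit <- try(minpack.lm::nls.lm(
    par = st, fn = resid,
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error") || fit$info == 0 || fit$info == 5)
    stop("Hill fit did not converge",
         if (!inherits(fit, "try-error")) paste0(": ", fit$message))
  cf <- fit$par
  se <- .lmSE(fit, length(F))
  new("HillFit", K_M = exp(cf[["logK"]]), base = cf[["base"]],
      maxF = cf[["maxF"]], s = if (free_s) cf[["s"]] else sFixed,
      se = se, sFixed = !free_s, converged = TRUE)
}

#' Fit the Hill equation with all four parameters free
#'
#' Convenience wrapper around [fitHill()] with the Hill coefficient
#' unconstrained, as used for open-probability dose-response relations.
#'
#' @inheritParams fitHill
#' @return a [HillFit]
#' @export
fitHillUnconstrained <- function(conc_M, F, weights = NULL) {
  if (length(unique(conc_M[conc_M > 0])) < 4)
    stop("need at least 4 distinct concentrations for a 4-parameter fit")
  fitHill(conc_M, F, sFixed = NA, weights = weights)
}

#' Fit the Woodhull model of voltage-dependent block
#'
#' Fits `K_D(V) = K_D(0 mV) * exp(-Zdelta * V * F / (R * T))` by least
#' squares on `log K_D` (multiplicative errors on dissociation constants
#' spanning orders of magnitude), V in volts internally.
#'
#' @param V_mV voltages (mV), at least 2 distinct
#' @param K_D_M apparent dissociation constants (mol/L)
#' @param temperatureK temperature; default 295.15 K (22 C),
#'   RT/F ~ 25.44 mV
#' @return a [WoodhullFit]
#' @export
fitWoodhull <- function(V_mV, K_D_M, temperatureK = 295.15) {
  ok <- is.finite(V_mV) & is.finite(K_D_M) & K_D_M > 0
  V_mV <- V_mV[ok]; K_D_M <- K_D_M[ok]
  if (length(unique(V_mV)) < 2)
    stop("need at least 2 distinct voltages (singular design)")
  fOverRT <- .FARADAY / (.RGAS * temperatureK)   # 1/V
  x <- (V_mV / 1000) * fOverRT
  fit <- stats::lm(log(K_D_M) ~ x)
  cf <- stats::coef(fit)
  se <- tryCatch(
    suppressWarnings(summary(fit)$coefficients[, "Std. Error"]),
    error = function(e) rep(NA_real_, 2))
  new("WoodhullFit", K_D0_M = exp(cf[[1]]), Zdelta = -cf[[2]],
      temperatureK = temperatureK,
      se = stats::setNames(as.numeric(se), c("logK_D0", "Zdelta")))
}

#' Predicted Woodhull dissociation constant at a voltage
#' @param fit a [WoodhullFit]
#' @param V_mV voltage (mV)
#' @return K_D at `V_mV` (mol/L)
#' @export
predictKD <- function(fit, V_mV) {
  fit@K_D0_M * exp(-fit@Zdelta * (V_mV / 1000) * .FARADAY /
                     (.RGAS * fit@temperatureK))
}

#' Reversal potential from a quadratic fit near 0 mV
#'
#' Fits a second-order polynomial to I-V points within the
#' `fitRangeMV` window (default -20..+20 mV) and returns the real root
#' nearest 0 mV.
#'
#' @param V_mV,I_pA the I-V relation
#' @param fitRangeMV half-width of the fitting window around 0 mV
#' @return reversal potential (mV)
#' @export
reversalPotential <- function(V_mV, I_pA, fitRangeMV = 20) {
  sel <- abs(V_mV) <= fitRangeMV + 1e-9
  if (sum(sel) < 3)
    stop("need at least 3 I-V points within the fitting window")
  v <- V_mV[sel]; i <- I_pA[sel]
  cf <- stats::coef(stats::lm(i ~ v + I(v^2)))
  a <- cf[[3]]; b <- cf[[2]]; c0 <- cf[[1]]
  if (abs(a) < 1e-12 * max(1, abs(b))) {
    if (abs(b) < .Machine$double.eps) stop("degenerate (flat) I-V relation")
    roots <- -c0 / b
  } else {
    disc <- b^2 - 4 * a * c0
    if (disc < 0) stop("fitted quadratic has no real root in the fit range")
    roots <- c((-b + sqrt(disc)) / (2 * a), (-b - sqrt(disc)) / (2 * a))
  }
  roots[which.min(abs(roots))]
}

#' Conductance-voltage relation
#'
#' `G(V) = I(V) / (V - V_rev)` for points outside the exclusion window
#' around 0 mV (where the small driving force makes G unreliable).
#' Points at `V == V_rev` are dropped with a warning. Optionally
#' normalizes to a stated reference conductance.
#'
#' @param V_mV,I_pA the I-V relation
#' @param V_rev_mV reversal potential (see [reversalPotential()])
#' @param exclusionMV half-width of the excluded voltage window
#' @param normalizeTo optional reference conductance to divide by
#' @return a [GVCurve]
#' @export
conductanceVoltage <- function(V_mV, I_pA, V_rev_mV, exclusionMV = 20,
                               normalizeTo = NULL) {
  keep <- abs(V_mV) >= exclusionMV - 1e-9
  if (!any(keep))
    warning("all points fall inside the exclusion window; empty G-V curve")
  v <- V_mV[keep]; i <- I_pA[keep]
  atRev <- abs(v - V_rev_mV) < 1e-9
  if (any(atRev)) {
    warning("dropping ", sum(atRev), " point(s) at V == V_rev")
    v <- v[!atRev]; i <- i[!atRev]
  }
  g <- i / (v - V_rev_mV)
  if (!is.null(normalizeTo)) g <- g / normalizeTo
  new("GVCurve", V_rev_mV = V_rev_mV,
      points = data.frame(V_mV = v, G = g),
      exclusionMV = exclusionMV, normalized = !is.null(normalizeTo))
}
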