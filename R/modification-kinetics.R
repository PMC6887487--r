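#' Build a modification time course from a sweep set
#'
#' For each sweep, measures the leak-subtracted steady-state agonist
#' current (the agonist epoch read before any reagent exposure within
#' the sweep). Experiment time is measured from the start of the first
#' exposure sweep (t = 0) and the course is normalized to that sweep's
#' steady-state read — the last agonist measurement taken before any
#' reagent has acted — so pre-exposure sweeps carry normalized currents
#' above 1 under rundown, negative times and zero cumulative exposure.
#' Cumulative
#' exposure sums the protocol-declared reagent-epoch durations of the
#' sweeps already completed (within a sweep, the steady-state read
#' precedes the exposure).
#'
#' @param set a [SweepSet]
#' @param reagentId reagent to track (default: any annotated reagent)
#' @param agonistEpoch,controlEpoch epoch labels for [leakSubtract()]
#' @param windowFraction steady-state window fraction
#' @return a [TimeCourse]
#' @export
buildTimeCourse <- function(set, reagentId = NULL,
                            agonistEpoch = "agonist",
                            controlEpoch = "pre",
                            windowFraction = 0.25) {
  stopifnot(is(set, "SweepSet"))
  sw <- set@sweeps
  if (!length(sw)) stop("empty sweep set")
  expDur <- vapply(sw, function(s) {
    ep <- s@epochs
    sel <- !is.na(ep$reagent_id) &
      (if (is.null(reagentId)) TRUE else ep$reagent_id == reagentId)
    sum(ep$end_s[sel] - ep$start_s[sel])
  }, numeric(1))
  exposed <- expDur > 0
  if (!any(exposed)) stop("sweep set contains no reagent-exposure sweep")
  f <- which(exposed)[1]
  if (f == 1)
    stop("no pre-exposure sweep: normalization is undefined")
  I <- vapply(sw, leakSubtract, numeric(1),
              agonistEpoch = agonistEpoch, controlEpoch = controlEpoch,
              windowFraction = windowFraction)
  t0 <- sw[[f]]@t_s[1]
  tExp <- vapply(sw, function(s) s@t_s[1], numeric(1)) - t0
  cumExp <- c(0, cumsum(expDur))[seq_along(sw)]   # exposure before sweep k
  normSweep <- sw[[f]]@index
  d <- data.frame(sweep = vapply(sw, function(s) s@index, integer(1)),
                  experiment_time_s = tExp,
                  cumulative_exposure_s = cumExp,
                  I_leak_sub_pA = I,
                  I_norm = I / I[f],
                  exposed = exposed)
  new("TimeCourse", data = d, normalizationSweep = normSweep)
}

#' Fit a mono-exponential to a modification time course
#'
#' Least-squares fit of `A * exp(-t/tau) + c` on cumulative-exposure
#' time, using the rows at and after t = 0. The `"fixed_0.9_0.1"` form
#' constrains A = 0.9 and c = 0.1 (used for slower reagents where the
#' full decay is not reached). A course with no detectable decay is
#' returned with `tauS = Inf` and `converged = FALSE`.
#'
#' @param tc a [TimeCourse]
#' @param form `"free"` or `"fixed_0.9_0.1"`
#' @return an [ExpFit]
#' @export
fitMonoexponential <- function(tc, form = c("free", "fixed_0.9_0.1")) {
  form <- match.arg(form)
  d <- tc@data[tc@data$experiment_time_s >= 0, ]
  if (nrow(d) < 3) stop("need at least 3 rows at t >= 0")
  x <- d$cumulative_exposure_s
  y <- d$I_norm
  span <- max(x) - min(x)
  if (span <= 0) stop("cumulative exposure does not advance")
  if (stats::sd(y) < 1e-12 || (max(y) - min(y)) < 1e-10)
    return(new("ExpFit", tauS = Inf, amplitude = 0, plateau = mean(y),
               form = form, converged = FALSE))
  ## tau start from the log-linear slope of the decaying part
  yl <- y - min(y)
  pos <- yl > max(yl) * 1e-3
  tau0 <- span / 3
  if (sum(pos) >= 2) {
    sl <- stats::coef(stats::lm(log(yl[pos]) ~ x[pos]))[[2]]
    if (is.finite(sl) && sl < 0) tau0 <- -1 / sl
  }
  upper <- 100 * span
  tau0 <- min(max(tau0, 1e-9), upper)
  fit <- if (form == "free") {
    try(minpack.lm::nls.lm(
      par = list(A = y[1] - y[length(y)], tau = tau0, c0 = y[length(y)]),
      fn = function(p) y - (p$A * exp(-x / p$tau) + p$c0),
      lower = c(-Inf, 1e-12, -Inf), upper = c(Inf, upper, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  } else {
    try(minpack.lm::nls.lm(
      par = list(tau = tau0),
      fn = function(p) y - (0.9 * exp(-x / p$tau) + 0.1),
      lower = 1e-12, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  }
  if (inherits(fit, "try-error") || fit$info == 0 || fit$info == 5)
    stop("mono-exponential fit failed",
         if (!inherits(fit, "try-error")) paste0(": ", fit$message))
  cf <- fit$par
  tau <- cf[["tau"]]
  atBound <- tau >= upper * (1 - 1e-6)
  if (form == "free")
    new("ExpFit", tauS = if (atBound) Inf else tau, amplitude = cf[["A"]],
        plateau = cf[["c0"]], form = form, converged = !atBound)
  else
    new("ExpFit", tauS = if (atBound) Inf else tau, amplitude = 0.9,
        plateau = 0.1, form = form, converged = !atBound)
}

#' Bimolecular modification rate from a fitted time constant
#'
#' `k = (1/tau) / conc`, converting the fitted time constant of
#' irreversible current loss into a second-order modification rate
#' constant.
#'
#' @param fit an [ExpFit] (or a numeric time constant in seconds)
#' @param freeConcM free reagent concentration (mol/L), > 0
#' @return rate constant (M^-1 s^-1)
#' @export
modificationRate <- function(fit, freeConcM) {
  if (freeConcM <= 0) stop("free concentration must be > 0")
  tau <- if (is(fit, "ExpFit")) fit@tauS else fit
  (1 / tau) / freeConcM
}

#' Fit the rundown curve of a reagent-free experiment
#'
#' Fits `(1 - c) * exp(-t/tau_r) + c` on experiment time to the
#' normalized course of an experiment without reagent exposures,
#' describing the activity-dependent current decline alone.
#'
#' @param tc a [TimeCourse] (or data.frame with `experiment_time_s` and
#'   `I_norm`) from a no-reagent protocol
#' @return a [RundownFit]
#' @export
fitRundown <- function(tc) {
  d <- if (is(tc, "TimeCourse")) tc@data else tc
  if (nrow(d) < 4) stop("need at least 4 rows to fit rundown")
  x <- d$experiment_time_s
  y <- d$I_norm
  if (stats::sd(y) < 1e-12)
    return(new("RundownFit", plateauC = 1, tauRs = Inf))
  fit <- try(minpack.lm::nls.lm(
    par = list(c0 = max(0, min(1, y[length(y)])),
               tau = max(diff(range(x)) / 2, 1e-6)),
    fn = function(p) y - ((1 - p$c0) * exp(-x / p$tau) + p$c0),
    lower = c(0, 1e-9), upper = c(1, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error") || fit$info == 0 || fit$info == 5)
    stop("rundown fit failed",
         if (!inherits(fit, "try-error")) paste0(": ", fit$message))
  cf <- fit$par
  new("RundownFit", plateauC = cf[["c0"]], tauRs = cf[["tau"]])
}

#' Predicted rundown factor
#' @param fit a [RundownFit]
#' @param t_s experiment time (s)
#' @return predicted normalized current
#' @export
predictRundown <- function(fit, t_s) {
  (1 - fit@plateauC) * exp(-t_s / fit@tauRs) + fit@plateauC
}

#' Divide-out rundown correction
#'
#' Divides the rows at t >= 0 of a modification time course by the
#' fitted rundown curve evaluated at the same experiment times,
#' compensating the reagent course for activity-dependent decline
#' measured in matched reagent-free experiments. Rows at t < 0 are left
#' untouched.
#'
#' @param tc a [TimeCourse]
#' @param rundown a [RundownFit] from a matched no-reagent protocol
#' @return the corrected [TimeCourse]
#' @export
correctRundownDivide <- function(tc, rundown) {
  d <- tc@data
  sel <- d$experiment_time_s >= 0
  r <- predictRundown(rundown, d$experiment_time_s[sel])
  if (any(r <= 0)) stop("rundown curve is non-positive in the corrected range")
  d$I_norm[sel] <- d$I_norm[sel] / r
  d$I_leak_sub_pA[sel] <- d$I_leak_sub_pA[sel] / r
  new("TimeCourse", data = d, normalizationSweep = tc@normalizationSweep)
}

#' Alternating-sweep rundown correction
#'
#' For protocols that strictly alternate unexposed and exposed sweeps,
#' computes the fractional drop between adjacent sweeps,
#' `F_j = (I_j - I_(j+1)) / I_j`, whose values alternately reflect
#' rundown alone (after unexposed sweeps) or rundown plus modification
#' (after exposed sweeps), and reconstructs three courses by the
#' recursions (0-based j):
#' corrected `I_(j+1) = I_j - I_j*F_(2j+1) + I_j*F_(2j)` (reagent effect
#' with the rundown step added back), rundown-only
#' `I_(j+1) = I_j - I_j*F_(2j)`, and reagent-plus-rundown
#' `I_(j+1) = I_j - I_j*F_(2j+1)`.
#'
#' @param currents leak-subtracted steady-state current per sweep (pA),
#'   in recording order
#' @param exposed logical per sweep; must strictly alternate starting
#'   with an unexposed sweep
#' @return list of data.frames `corrected`, `rundownOnly`,
#'   `reagentOnly`, each with columns `step`, `I`, `I_norm`
#' @export
correctRundownAlternating <- function(currents, exposed) {
  n <- length(currents)
  if (n < 4) stop("need at least 4 sweeps")
  if (length(exposed) != n) stop("one exposure flag per sweep required")
  if (!all(exposed == rep(c(FALSE, TRUE), length.out = n)))
    stop("sweeps must strictly alternate unexposed/exposed, starting unexposed")
  if (any(currents == 0)) stop("zero steady-state current in denominator")
  F <- (currents[-n] - currents[-1]) / currents[-n]   # F[j] is F_(j-1), 0-based
  nF <- length(F)
  rec <- function(stepFrac) {
    I <- currents[1]
    for (k in seq_along(stepFrac)) I <- c(I, I[k] * (1 - stepFrac[k]))
    data.frame(step = seq_along(I) - 1L, I = I, I_norm = I / I[1])
  }
  jC <- 0:((nF - 2) %/% 2)                 # needs F_(2j) and F_(2j+1)
  corrected <- rec(F[2 * jC + 2] - F[2 * jC + 1])
  jR <- 0:((nF - 1) %/% 2)                 # needs F_(2j)
  rundownOnly <- rec(F[2 * jR + 1])
  reagentOnly <- rec(F[2 * jC + 2])
  list(corrected = corrected, rundownOnly = rundownOnly,
       reagentOnly = reagentOnly)
}

#' Lower-bound estimate of the agonist-induced Po fold-change
#'
#' Ratio of the steady-state current magnitudes with and without
#' agonist. Because the no-agonist current is dominated by leak, this
#' underestimates the true fold-change in open probability; it is used
#' as a conservative lower bound.
#'
#' @param I_agonist,I_ctrl steady-state currents (pA); `I_ctrl` nonzero
#' @return fold-change estimate (dimensionless, >= 0)
#' @export
poFoldChange <- function(I_agonist, I_ctrl) {
  if (any(I_ctrl == 0)) stop("zero control current")
  abs(I_agonist / I_ctrl)
}

#' State-dependence verdict from open/closed modification rates
#'
#' Compares the open/closed modification-rate ratio with the estimated
#' Po fold-change. If the filter gated access, the rate ratio should
#' match the Po fold-change; a rate ratio far below it (default: less
#' than `filterGateFactor` times the Po fold-change) argues that the
#' filter is not an activation gate. Thresholds are reported in the
#' result, never hidden.
#'
#' @param kOpen,kClosed modification rate constants (M^-1 s^-1), > 0
#' @param poFold estimated Po fold-change, > 0
#' @param filterGateFactor rate ratio below `filterGateFactor * poFold`
#'   yields `"filter-not-gate"`
#' @param gateTol relative tolerance: rate ratio at or above
#'   `poFold * (1 - gateTol)` yields `"gate-consistent"`
#' @param tauOpen,tauClosed,pValue optional extras carried in the result
#' @return a [ModificationResult]
#' @export
stateDependenceVerdict <- function(kOpen, kClosed, poFold,
                                   filterGateFactor = 0.1, gateTol = 0.05,
                                   tauOpen = NA_real_,
                                   tauClosed = NA_real_,
                                   pValue = NA_real_) {
  if (any(c(kOpen, kClosed, poFold) <= 0))
    stop("rates and Po fold-change must be > 0")
  ratio <- kOpen / kClosed
  verdict <- if (ratio >= poFold * (1 - gateTol)) "gate-consistent"
  else if (ratio < filterGateFactor * poFold) "filter-not-gate"
  else "indeterminate"
  new("ModificationResult", kOpen = kOpen, kClosed = kClosed,
      tauOpen = tauOpen, tauClosed = tauClosed, rateRatio = ratio,
      poFoldChange = poFold, verdict = verdict, pValue = pValue,
      thresholds = c(filterGateFactor = filterGateFactor,
                     gateTol = gateTol))
}

#' Welch's two-tailed t-test
#'
#' Heteroscedastic (unequal-variance) two-sample t-test with
#' Welch-Satterthwaite degrees of freedom.
#'
#' @param a,b numeric samples, each of length >= 2
#' @return list with `t`, `df` and two-tailed `p`
#' @export
welchTTest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("degenerate input: both samples have zero variance")
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Rundown quality-control exclusion
#'
#' Discards a cell when the agonist-activated current declined by more
#' than 50% over the initial reagent-free sweeps (strictly more: a cell
#' at exactly 50% is kept).
#'
#' @param preCurrents leak-subtracted agonist currents of the
#'   pre-exposure sweeps, in order
#' @return `"keep"` or `"discard"`
#' @export
qcRundownExclusion <- function(preCurrents) {
  if (length(preCurrents) < 2) stop("need at least 2 pre-exposure sweeps")
  ratio <- abs(preCurrents[length(preCurrents)]) / abs(preCurrents[1])
  if (ratio < 0.5) "discard" else "keep"
}
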