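#' @import methods
NULL

## ---- sweep data model -------------------------------------------------

#' Required columns of the epoch table carried by a SweepRecord
#' @noRd
.epochCols <- c("start_s", "end_s", "label", "agonist_id", "agonist_conc_M",
                "reagent_id", "reagent_free_conc_M", "voltage_mV")

#' SweepRecord: one annotated patch-clamp sweep
#'
#' A single current trace with its solution/voltage protocol. Time is in
#' seconds on the experiment clock (absolute, so sweeps in one
#' [SweepSet] share a common time axis), current in pA. The epoch table
#' annotates contiguous solution periods: which agonist and reactive
#' reagent were present, at what free concentration, and the holding
#' potential.
#'
#' @slot index zero-based sweep index within its set
#' @slot t_s numeric, strictly increasing sample times (s)
#' @slot i_pA numeric, sampled current (pA), same length as `t_s`
#' @slot epochs data.frame with columns `start_s`, `end_s`, `label`,
#'   `agonist_id`, `agonist_conc_M`, `reagent_id`, `reagent_free_conc_M`,
#'   `voltage_mV`; non-overlapping, ordered, inside the sampled range
#' @slot sampleRateHz nominal sampling rate (Hz)
#' @export
setClass("SweepRecord",
  representation(index = "integer", t_s = "numeric", i_pA = "numeric",
                 epochs = "data.frame", sampleRateHz = "numeric"))

setValidity("SweepRecord", function(object) {
  msg <- character()
  if (length(object@t_s) != length(object@i_pA))
    msg <- c(msg, "t_s and i_pA must have the same length")
  if (length(object@t_s) > 1 && any(diff(object@t_s) <= 0))
    msg <- c(msg, "t_s must be strictly increasing")
  ep <- object@epochs
  if (!all(.epochCols %in% names(ep)))
    msg <- c(msg, paste("epochs must have columns:",
                        paste(.epochCols, collapse = ", ")))
  if (nrow(ep) > 0 && all(.epochCols %in% names(ep))) {
    if (any(ep$end_s <= ep$start_s))
      msg <- c(msg, "every epoch must have end_s > start_s")
    if (any(ep$agonist_conc_M < 0) || any(ep$reagent_free_conc_M < 0))
      msg <- c(msg, "concentrations must be >= 0")
    if (nrow(ep) > 1 && any(ep$start_s[-1] < ep$end_s[-nrow(ep)] - 1e-12))
      msg <- c(msg, "epochs must be ordered and non-overlapping")
    if (length(object@t_s) > 0 &&
        (min(ep$start_s) < object@t_s[1] - 1e-9 ||
         max(ep$end_s) > object@t_s[length(object@t_s)] + 1e-9))
      msg <- c(msg, "epochs must lie within the sampled time range")
  }
  if (length(msg)) msg else TRUE
})

#' SweepSet: an ordered collection of sweeps from one experiment
#'
#' @slot sweeps list of [SweepRecord] with consecutive indices from 0
#' @slot meta list of free-form metadata (construct, temperature_K,
#'   provenance; for synthetic sets the generator seed and ground truth)
#' @export
setClass("SweepSet", representation(sweeps = "list", meta = "list"))

setValidity("SweepSet", function(object) {
  msg <- character()
  if (length(object@sweeps)) {
    if (!all(vapply(object@sweeps, is, logical(1), "SweepRecord")))
      msg <- c(msg, "sweeps must all be SweepRecord objects")
    else {
      idx <- vapply(object@sweeps, function(s) s@index, integer(1))
      if (!identical(idx, seq_along(idx) - 1L))
        msg <- c(msg, "sweep indices must be consecutive from 0")
    }
  }
  if (length(msg)) msg else TRUE
})

## ---- time courses and fits --------------------------------------------

#' TimeCourse: normalized steady-state current per sweep
#'
#' One row per sweep: leak-subtracted steady-state agonist current,
#' normalized current, experiment time relative to the first reagent
#' exposure (t = 0), and cumulative reagent-exposure time.
#'
#' @slot data data.frame with columns `sweep`, `experiment_time_s`,
#'   `cumulative_exposure_s`, `I_leak_sub_pA`, `I_norm`, `exposed`
#' @slot normalizationSweep index of the sweep used for normalization
#' @export
setClass("TimeCourse",
  representation(data = "data.frame", normalizationSweep = "integer"))

setValidity("TimeCourse", function(object) {
  d <- object@data
  need <- c("sweep", "experiment_time_s", "cumulative_exposure_s",
            "I_leak_sub_pA", "I_norm", "exposed")
  if (!all(need %in% names(d)))
    return(paste("data must have columns:", paste(need, collapse = ", ")))
  if (nrow(d) > 1 && any(diff(d$cumulative_exposure_s) < -1e-12))
    return("cumulative_exposure_s must be non-decreasing")
  i <- match(object@normalizationSweep, d$sweep)
  if (!is.na(i) && abs(d$I_norm[i] - 1) > 1e-9)
    return("I_norm must equal 1 at the normalization sweep")
  TRUE
})

#' ExpFit: mono-exponential fit A*exp(-t/tau) + c
#'
#' @slot tauS time constant (s); `Inf` when no decay was detectable
#' @slot amplitude fitted (or fixed) amplitude A
#' @slot plateau fitted (or fixed) plateau c
#' @slot form `"free"` or `"fixed_0.9_0.1"`
#' @slot converged logical fit diagnostic
#' @export
setClass("ExpFit",
  representation(tauS = "numeric", amplitude = "numeric",
                 plateau = "numeric", form = "character",
                 converged = "logical"))

setValidity("ExpFit", function(object) {
  if (!is.infinite(object@tauS) && object@tauS <= 0)
    return("tauS must be > 0") else TRUE
})

#' RundownFit: activity-dependent current decline (1-c)*exp(-t/tau_r) + c
#'
#' @slot plateauC plateau fraction c in \[0, 1\]
#' @slot tauRs rundown time constant (s)
#' @export
setClass("RundownFit", representation(plateauC = "numeric", tauRs = "numeric"))

setValidity("RundownFit", function(object) {
  msg <- character()
  if (object@plateauC < 0 || object@plateauC > 1)
    msg <- c(msg, "plateauC must be in [0, 1]")
  if (object@tauRs <= 0) msg <- c(msg, "tauRs must be > 0")
  if (length(msg)) msg else TRUE
})

#' HillFit: dose-response fit F = base + (max-base)/(1 + (K/x)^s)
#'
#' @slot K_M midpoint (apparent dissociation constant, mol/L)
#' @slot base,maxF lower and upper asymptotes
#' @slot s Hill coefficient (fixed or fitted)
#' @slot se named numeric of parameter standard errors (where estimated)
#' @slot sFixed logical, whether s was held fixed
#' @slot converged logical
#' @export
setClass("HillFit",
  representation(K_M = "numeric", base = "numeric", maxF = "numeric",
                 s = "numeric", se = "numeric", sFixed = "logical",
                 converged = "logical"))

setValidity("HillFit", function(object)
  if (object@K_M <= 0) "K_M must be > 0" else TRUE)

#' WoodhullFit: voltage-dependent block K_D(V) = K_D0 * exp(-Zdelta*V*F/RT)
#'
#' @slot K_D0_M apparent dissociation constant at 0 mV (mol/L)
#' @slot Zdelta effective valence times fractional electrical distance
#' @slot temperatureK temperature used for F/RT
#' @slot se named numeric of standard errors on log(K_D0) and Zdelta
#' @export
setClass("WoodhullFit",
  representation(K_D0_M = "numeric", Zdelta = "numeric",
                 temperatureK = "numeric", se = "numeric"))

setValidity("WoodhullFit", function(object)
  if (object@K_D0_M <= 0) "K_D0_M must be > 0" else TRUE)

#' GVCurve: conductance-voltage relation
#'
#' @slot V_rev_mV reversal potential (mV)
#' @slot points data.frame with columns `V_mV`, `G`
#' @slot exclusionMV half-width of the voltage window around 0 mV whose
#'   points were excluded before computing G
#' @slot normalized logical, whether G was normalized to a reference
#' @export
setClass("GVCurve",
  representation(V_rev_mV = "numeric", points = "data.frame",
                 exclusionMV = "numeric", normalized = "logical"))

setValidity("GVCurve", function(object) {
  p <- object@points
  if (nrow(p) && any(abs(p$V_mV) < object@exclusionMV))
    return("points inside the exclusion window must be absent")
  TRUE
})

#' NoiseResult: stationary noise analysis of an ensemble series
#'
#' @slot iSinglePA single-channel current estimate (pA)
#' @slot nChannels channel-count estimate (real-valued)
#' @slot table data.frame with one row per agonist concentration:
#'   `conc_M`, `mean_I_pA`, `var_pA2`, `Po`, `Po_flag`
#' @slot converged logical
#' @export
setClass("NoiseResult",
  representation(iSinglePA = "numeric", nChannels = "numeric",
                 table = "data.frame", converged = "logical"))

#' ModificationResult: state-dependence comparison and verdict
#'
#' @slot kOpen,kClosed bimolecular modification rates (M^-1 s^-1)
#' @slot tauOpen,tauClosed fitted time constants (s)
#' @slot rateRatio kOpen/kClosed
#' @slot poFoldChange estimated fold-change in open probability
#' @slot verdict `"filter-not-gate"`, `"gate-consistent"` or
#'   `"indeterminate"`
#' @slot pValue Welch test p-value comparing per-cell rates (NA if not run)
#' @slot thresholds named numeric of the decision thresholds used
#' @export
setClass("ModificationResult",
  representation(kOpen = "numeric", kClosed = "numeric",
                 tauOpen = "numeric", tauClosed = "numeric",
                 rateRatio = "numeric", poFoldChange = "numeric",
                 verdict = "character", pValue = "numeric",
                 thresholds = "numeric"))

setValidity("ModificationResult", function(object) {
  if (any(c(object@kOpen, object@kClosed) < 0))
    return("rates must be >= 0")
  TRUE
})

## ---- kinetic model ----------------------------------------------------

#' KineticScheme: five-state modification scheme
#'
#' States: S1 inaccessible-unbound, S2 inaccessible-bound, S3
#' accessible-unbound, S4 accessible-bound, S5 modified (absorbing).
#' Reagent binding/unbinding at `k0*conc` / `k1` (in both conformations
#' under the default topology), conformational exchange
#' inaccessible->accessible at `k2` and back at `k3` (in both liganded
#' branches), and irreversible modification S4 -> S5 at `kRX`.
#'
#' @slot k0 binding rate constant (M^-1 s^-1)
#' @slot k1 unbinding rate (s^-1)
#' @slot k2 inaccessible-to-accessible rate (s^-1)
#' @slot k3 accessible-to-inaccessible rate (s^-1)
#' @slot kRX modification rate from the accessible-bound state (s^-1)
#' @slot concM reagent concentration (mol/L)
#' @slot topology `"full"` (binding in both conformations) or
#'   `"accessible-only"` (no S1<->S2 binding)
#' @slot Q 5x5 generator matrix (rows sum to zero, absorbing S5 row zero)
#' @export
setClass("KineticScheme",
  representation(k0 = "numeric", k1 = "numeric", k2 = "numeric",
                 k3 = "numeric", kRX = "numeric", concM = "numeric",
                 topology = "character", Q = "matrix"))

setValidity("KineticScheme", function(object) {
  msg <- character()
  if (any(c(object@k0, object@k1, object@k2, object@k3, object@kRX,
            object@concM) < 0))
    msg <- c(msg, "all rates and the concentration must be >= 0")
  Q <- object@Q
  if (!all(dim(Q) == c(5, 5))) msg <- c(msg, "Q must be 5x5")
  else {
    if (any(abs(rowSums(Q)) > 1e-8)) msg <- c(msg, "Q rows must sum to 0")
    if (any(Q[row(Q) != col(Q)] < 0))
      msg <- c(msg, "off-diagonal entries of Q must be >= 0")
    if (any(Q[5, ] != 0)) msg <- c(msg, "absorbing state row must be zero")
  }
  if (length(msg)) msg else TRUE
})

#' OccupancyTrajectory: propagated state probabilities
#'
#' @slot times time grid (s)
#' @slot occupancy matrix, one row per time, columns S1..S5
#' @slot scheme the [KineticScheme] that generated it
#' @export
setClass("OccupancyTrajectory",
  representation(times = "numeric", occupancy = "matrix",
                 scheme = "KineticScheme"))

setValidity("OccupancyTrajectory", function(object) {
  p <- object@occupancy
  msg <- character()
  if (nrow(p) != length(object@times))
    msg <- c(msg, "occupancy must have one row per time point")
  if (any(abs(rowSums(p) - 1) > 1e-8))
    msg <- c(msg, "each occupancy row must sum to 1 within 1e-8")
  if (any(p < -1e-10) || any(p > 1 + 1e-10))
    msg <- c(msg, "occupancies must lie in [0, 1]")
  if (nrow(p) > 1 && any(diff(p[, 5]) < -1e-9))
    msg <- c(msg, "modified-state occupancy must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' Speciation: acid-base partition of a thiol-reactive reagent
#'
#' @slot totalM total concentration (mol/L)
#' @slot pH,pKa solution pH and reagent pKa
#' @slot cationM protonated (charged) species concentration (mol/L)
#' @slot neutralM deprotonated (neutral) species concentration (mol/L)
#' @export
setClass("Speciation",
  representation(totalM = "numeric", pH = "numeric", pKa = "numeric",
                 cationM = "numeric", neutralM = "numeric"))

setValidity("Speciation", function(object) {
  msg <- character()
  if (object@cationM < 0 || object@neutralM < 0)
    msg <- c(msg, "species concentrations must be >= 0")
  if (abs(object@cationM + object@neutralM - object@totalM) >
      1e-12 * max(1, object@totalM))
    msg <- c(msg, "species must sum to the total concentration")
  if (length(msg)) msg else TRUE
})

## ---- generator truth --------------------------------------------------

#' GroundTruth: generative parameters for synthetic experiments
#'
#' Holds every quantity the analysis stages try to recover: channel count
#' and single-channel current, the agonist dependence of open
#' probability, leak baseline and drift, rundown plateau/time constant,
#' voltage-dependent block parameters, state-dependent modification rate
#' constants, and the Gaussian noise level.
#'
#' @slot nChannels number of channels in the cell
#' @slot iSinglePA single-channel current at the working voltage (pA)
#' @slot poBase,poMax open probability without agonist and at saturation
#' @slot poKHalfM,poHill Hill parameters of Po vs agonist concentration
#' @slot leakPA leak baseline (pA)
#' @slot leakSlopePAps leak drift (pA/s of experiment time)
#' @slot rundownC,rundownTauS rundown plateau fraction and time constant
#'   (s of cumulative agonist-on time); `rundownC = 1` disables rundown
#' @slot rundownClock `"agonist-on"` or `"wall"`
#' @slot blockKD0M,blockZdelta reversible-block parameters (Woodhull)
#' @slot kOpen,kClosed modification rate constants (M^-1 s^-1)
#' @slot noiseSdPA Gaussian noise SD added to every sample (pA)
#' @slot temperatureK temperature (K)
#' @slot seed RNG seed
#' @export
setClass("GroundTruth",
  representation(nChannels = "numeric", iSinglePA = "numeric",
                 poBase = "numeric", poMax = "numeric",
                 poKHalfM = "numeric", poHill = "numeric",
                 leakPA = "numeric", leakSlopePAps = "numeric",
                 rundownC = "numeric", rundownTauS = "numeric",
                 rundownClock = "character",
                 blockKD0M = "numeric", blockZdelta = "numeric",
                 kOpen = "numeric", kClosed = "numeric",
                 noiseSdPA = "numeric", temperatureK = "numeric",
                 seed = "integer"))

setValidity("GroundTruth", function(object) {
  msg <- character()
  po <- c(object@poBase, object@poMax)
  if (any(po < 0) || any(po > 1)) msg <- c(msg, "Po must be in [0, 1]")
  if (object@rundownTauS <= 0) msg <- c(msg, "rundownTauS must be > 0")
  if (object@rundownC < 0 || object@rundownC > 1)
    msg <- c(msg, "rundownC must be in [0, 1]")
  if (object@kOpen < 0 || object@kClosed < 0)
    msg <- c(msg, "modification rate constants must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ProtocolSpec: sweep protocol for a synthetic experiment
#'
#' @slot nPresweeps agonist-only sweeps recorded before any exposure
#' @slot nExposureSweeps sweeps carrying (or, under the alternating
#'   protocol, alternating with) a reagent exposure
#' @slot exposureS reagent-exposure duration per exposed sweep (s)
#' @slot exposureState `"open"` (reagent co-applied with agonist) or
#'   `"closed"` (reagent applied after agonist washout)
#' @slot agonistId,agonistConcM agonist identity and concentration
#' @slot reagentId,reagentFreeConcM reagent identity ("Ag", "MTSEA",
#'   "MTSET") and free concentration (mol/L)
#' @slot voltageMV holding potential (mV)
#' @slot alternatingReagent logical; alternate unexposed/exposed sweeps
#'   (the MTS protocol; exposures fall on the odd sweeps of the block)
#' @slot sweepPeriodS sweep start-to-start interval (s)
#' @slot sampleRateHz sampling rate of the synthetic traces (Hz)
#' @export
setClass("ProtocolSpec",
  representation(nPresweeps = "integer", nExposureSweeps = "integer",
                 exposureS = "numeric", exposureState = "character",
                 agonistId = "character", agonistConcM = "numeric",
                 reagentId = "character", reagentFreeConcM = "numeric",
                 voltageMV = "numeric", alternatingReagent = "logical",
                 sweepPeriodS = "numeric", sampleRateHz = "numeric"))

setValidity("ProtocolSpec", function(object) {
  msg <- character()
  if (object@nPresweeps < 0 || object@nExposureSweeps < 0)
    msg <- c(msg, "sweep counts must be >= 0")
  if (object@exposureS <= 0 || object@sweepPeriodS <= 0)
    msg <- c(msg, "durations must be > 0")
  if (!object@exposureState %in% c("open", "closed"))
    msg <- c(msg, "exposureState must be 'open' or 'closed'")
  if (length(msg)) msg else TRUE
})
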