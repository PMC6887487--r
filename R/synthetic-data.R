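## Faraday constant / gas constant, SI units; F/(R*T) in 1/V
.FARADAY <- 96485.33212
.RGAS <- 8.31446262

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Ground truth for a synthetic SCAM experiment
#'
#' Defaults emulate a whole-cell recording of an agonist-gated channel at
#' -60 mV: 1000 channels of -3 pA, open probability rising from 0.005 to
#' 0.9 with a Hill dependence on agonist (K_half 0.25 mM, coefficient 2),
#' -20 pA leak, rundown to a 4.5% plateau with an 84.57 s time constant
#' of cumulative agonist-on time, reversible voltage-dependent block with
#' K_D(0 mV) = 5.2 nM and Zdelta = -0.89, and irreversible modification
#' rate constants of 2.94e7 (open) and 1.16e7 (closed) M^-1 s^-1.
#'
#' @param nChannels,iSinglePA channel count and single-channel current (pA)
#' @param poBase,poMax,poKHalfM,poHill open-probability model
#' @param leakPA,leakSlopePAps leak baseline (pA) and drift (pA/s)
#' @param rundownC,rundownTauS rundown plateau fraction and time constant
#'   (s); `rundownC = 1` disables rundown
#' @param rundownClock `"agonist-on"` (default) or `"wall"`
#' @param blockKD0M,blockZdelta reversible-block parameters
#' @param kOpen,kClosed modification rate constants (M^-1 s^-1)
#' @param noiseSdPA Gaussian sample noise SD (pA)
#' @param temperatureK temperature (K); default 295.15 (22 C)
#' @param seed RNG seed recorded with the experiment
#' @return a validated [GroundTruth]
#' @export
groundTruth <- function(nChannels = 1000, iSinglePA = -3,
                        poBase = 0.005, poMax = 0.9,
                        poKHalfM = 2.5e-4, poHill = 2,
                        leakPA = -20, leakSlopePAps = 0,
                        rundownC = 1, rundownTauS = 84.57,
                        rundownClock = "agonist-on",
                        blockKD0M = 5.2e-9, blockZdelta = -0.89,
                        kOpen = 2.94e7, kClosed = 1.16e7,
                        noiseSdPA = 0, temperatureK = 295.15, seed = 1) {
  new("GroundTruth", nChannels = nChannels, iSinglePA = iSinglePA,
      poBase = poBase, poMax = poMax, poKHalfM = poKHalfM, poHill = poHill,
      leakPA = leakPA, leakSlopePAps = leakSlopePAps,
      rundownC = rundownC, rundownTauS = rundownTauS,
      rundownClock = match.arg(rundownClock, c("agonist-on", "wall")),
      blockKD0M = blockKD0M, blockZdelta = blockZdelta,
      kOpen = kOpen, kClosed = kClosed, noiseSdPA = noiseSdPA,
      temperatureK = temperatureK, seed = as.integer(seed))
}

#' Sweep protocol for a synthetic SCAM experiment
#'
#' Defaults follow the standard accessibility protocol: six agonist-only
#' presweeps to assess rundown, then six sweeps each carrying one reagent
#' exposure (1 s in the open state), 50 nM free Ag+ at -60 mV, one sweep
#' every 15 s. With `alternatingReagent = TRUE` the exposure block
#' alternates unexposed/exposed sweeps (the MTS protocol), exposures on
#' the odd sweeps of the block.
#'
#' @param nPresweeps,nExposureSweeps sweep counts (see class docs)
#' @param exposureS exposure duration per exposed sweep (s)
#' @param exposureState `"open"` or `"closed"`
#' @param agonistId,agonistConcM agonist and concentration (mol/L)
#' @param reagentId,reagentFreeConcM reagent and free concentration (mol/L)
#' @param voltageMV holding potential (mV)
#' @param alternatingReagent alternate unexposed/exposed sweeps
#' @param sweepPeriodS sweep start-to-start interval (s)
#' @param sampleRateHz sampling rate of the synthetic traces
#' @return a validated [ProtocolSpec]
#' @export
protocolSpec <- function(nPresweeps = 6, nExposureSweeps = 6,
                         exposureS = 1, exposureState = "open",
                         agonistId = "2APB", agonistConcM = 3e-3,
                         reagentId = "Ag", reagentFreeConcM = 50e-9,
                         voltageMV = -60, alternatingReagent = FALSE,
                         sweepPeriodS = 15, sampleRateHz = 100) {
  new("ProtocolSpec", nPresweeps = as.integer(nPresweeps),
      nExposureSweeps = as.integer(nExposureSweeps),
      exposureS = exposureS,
      exposureState = match.arg(exposureState, c("open", "closed")),
      agonistId = agonistId, agonistConcM = agonistConcM,
      reagentId = reagentId, reagentFreeConcM = reagentFreeConcM,
      voltageMV = voltageMV, alternatingReagent = alternatingReagent,
      sweepPeriodS = sweepPeriodS, sampleRateHz = sampleRateHz)
}

.hillPo <- function(truth, concM) {
  if (concM <= 0) return(truth@poBase)
  truth@poBase + (truth@poMax - truth@poBase) /
    (1 + (truth@poKHalfM / concM)^truth@poHill)
}

.blockKD <- function(truth, voltageMV) {
  truth@blockKD0M *
    exp(-truth@blockZdelta * (voltageMV / 1000) * .FARADAY /
          (.RGAS * truth@temperatureK))
}

.rundownFactor <- function(truth, tOn) {
  (1 - truth@rundownC) * exp(-tOn / truth@rundownTauS) + truth@rundownC
}

## epoch layout of one sweep, relative to sweep start
.sweepEpochLayout <- function(protocol, exposed) {
  p <- protocol
  ag <- list(id = p@agonistId, conc = p@agonistConcM)
  rows <- list(list(lab = "pre", dur = 2, ag = FALSE, re = FALSE))
  rows <- c(rows, list(list(lab = "agonist", dur = 4, ag = TRUE, re = FALSE)))
  if (exposed) {
    if (p@exposureState == "open") {
      rows <- c(rows, list(list(lab = "reagent", dur = p@exposureS,
                                ag = TRUE, re = TRUE)))
    } else {
      rows <- c(rows, list(list(lab = "wash", dur = 2, ag = FALSE, re = FALSE)),
                list(list(lab = "reagent", dur = p@exposureS,
                          ag = FALSE, re = TRUE)))
    }
  }
  rows <- c(rows, list(list(lab = "post", dur = 2, ag = FALSE, re = FALSE)))
  start <- cumsum(c(0, vapply(rows, function(r) r$dur, numeric(1))))
  data.frame(label = vapply(rows, `[[`, character(1), "lab"),
             start = start[-length(start)],
             end = start[-1],
             agonist = vapply(rows, `[[`, logical(1), "ag"),
             reagent = vapply(rows, `[[`, logical(1), "re"),
             stringsAsFactors = FALSE)
}

#' Simulate a SCAM modification experiment with known ground truth
#'
#' Generates a [SweepSet] under the generative model
#' `I(t) = leak(t) + u(t) * r(t) * b(t) * N * Po(t) * i + noise`, where
#' `u` is the unmodified channel fraction (declining as
#' `du/dt = -k_state * conc * u` during reagent exposures, with the rate
#' constant chosen by whether agonist is present), `r` the rundown factor
#' `(1-c) * exp(-t_on/tau_r) + c` on cumulative agonist-on time, `b` the
#' unblocked fraction `1/(1 + conc/K_D(V))` during reversible Ag+
#' epochs, and `Po` the Hill open probability for the agonist present.
#' Identical (truth, protocol, seed) give an identical sweep set.
#'
#' @param truth a [GroundTruth]
#' @param protocol a [ProtocolSpec]
#' @return list with elements `set` (a [SweepSet]) and `truthRecord`
#'   (per-sweep table of exposed flags, exposure durations, true
#'   unmodified fraction and rundown factor at the steady-state
#'   measurement, plus the inputs)
#' @export
simulateExperiment <- function(truth, protocol) {
  validObject(truth); validObject(protocol)
  p <- protocol
  nTotal <- p@nPresweeps + p@nExposureSweeps
  exposed <- logical(nTotal)
  if (nTotal > p@nPresweeps) {
    blk <- seq(p@nPresweeps + 1, nTotal)
    exposed[blk] <- if (p@alternatingReagent)
      (seq_along(blk) - 1) %% 2 == 1 else TRUE
  }
  dt <- 1 / p@sampleRateHz
  u <- 1          # unmodified fraction
  tOn <- 0        # cumulative agonist-on time
  rec <- vector("list", nTotal)
  perSweep <- data.frame(sweep = seq_len(nTotal) - 1L, exposed = exposed,
                         exposure_s = 0, u_meas = NA_real_,
                         rundown_meas = NA_real_)
  .withSeed(truth@seed, {
    for (k in seq_len(nTotal)) {
      lay <- .sweepEpochLayout(p, exposed[k])
      s0 <- (k - 1) * p@sweepPeriodS
      dur <- lay$end[nrow(lay)]
      if (dur > p@sweepPeriodS + 1e-9)
        stop("sweepPeriodS shorter than the sweep duration (", dur, " s)")
      tAll <- iAll <- numeric(0)
      for (j in seq_len(nrow(lay))) {
        tt <- seq(lay$start[j], lay$end[j], by = dt)
        if (j < nrow(lay)) tt <- tt[tt < lay$end[j] - 1e-12]
        agC <- if (lay$agonist[j]) p@agonistConcM else 0
        po <- .hillPo(truth, agC)
        b <- 1
        kmod <- 0
        if (lay$reagent[j]) {
          if (p@reagentId == "Ag")
            b <- 1 / (1 + p@reagentFreeConcM / .blockKD(truth, p@voltageMV))
          kmod <- (if (lay$agonist[j]) truth@kOpen else truth@kClosed) *
            p@reagentFreeConcM
        }
        rel <- tt - lay$start[j]
        uHere <- u * exp(-kmod * rel)
        tOnHere <- if (truth@rundownClock == "agonist-on")
          tOn + if (lay$agonist[j]) rel else 0 else s0 + tt
        r <- .rundownFactor(truth, tOnHere)
        leak <- truth@leakPA + truth@leakSlopePAps * (s0 + tt)
        sig <- uHere * r * b * truth@nChannels * po * truth@iSinglePA
        ii <- leak + sig
        if (truth@noiseSdPA > 0)
          ii <- ii + stats::rnorm(length(ii), 0, truth@noiseSdPA)
        ## record truth at the steady-state read point of the agonist epoch
        if (lay$label[j] == "agonist") {
          perSweep$u_meas[k] <- u
          ## read point: midpoint of the trailing-quarter window
          perSweep$rundown_meas[k] <- .rundownFactor(
            truth, if (truth@rundownClock == "agonist-on")
              tOn + 0.875 * (lay$end[j] - lay$start[j])
            else s0 + 0.875 * lay$end[j] + 0.125 * lay$start[j])
        }
        ## advance state to epoch end
        epDur <- lay$end[j] - lay$start[j]
        u <- u * exp(-kmod * epDur)
        if (lay$agonist[j] && truth@rundownClock == "agonist-on")
          tOn <- tOn + epDur
        if (lay$reagent[j]) perSweep$exposure_s[k] <- epDur
        tAll <- c(tAll, tt); iAll <- c(iAll, ii)
      }
      ## trailing sample closing the final epoch
      ep <- solutionEpochs(
        s0 + lay$start, s0 + lay$end, lay$label,
        agonist_id = ifelse(lay$agonist, p@agonistId, NA_character_),
        agonist_conc_M = ifelse(lay$agonist, p@agonistConcM, 0),
        reagent_id = ifelse(lay$reagent, p@reagentId, NA_character_),
        reagent_free_conc_M = ifelse(lay$reagent, p@reagentFreeConcM, 0),
        voltage_mV = p@voltageMV)
      rec[[k]] <- sweepRecord(k - 1L, s0 + tAll, iAll, ep, p@sampleRateHz)
    }
  })
  set <- sweepSet(rec, meta = list(
    construct = "synthetic", temperature_K = truth@temperatureK,
    provenance = "simulateExperiment", seed = truth@seed,
    exposure_state = p@exposureState, reagent_id = p@reagentId,
    reagent_free_conc_M = p@reagentFreeConcM,
    alternating = p@alternatingReagent))
  list(set = set,
       truthRecord = list(truth = truth, protocol = p, perSweep = perSweep))
}

#' Simulate a stationary noise-analysis trace ensemble
#'
#' Each sample is an independent binomial snapshot
#' `Binomial(N, Po) * i`, plus optional Gaussian instrumentation noise —
#' the generative counterpart of an ensemble of short constant-voltage
#' traces recorded at steady state.
#'
#' @param N channel count
#' @param iPA single-channel current (pA)
#' @param Po open probability in \[0, 1\]
#' @param nTraces,nSamples ensemble dimensions (traces x samples)
#' @param noiseSdPA Gaussian noise SD (pA)
#' @param seed RNG seed
#' @return `nTraces` x `nSamples` numeric matrix of currents (pA)
#' @export
simulateNoiseEnsemble <- function(N, iPA, Po, nTraces = 50,
                                  nSamples = 8000, noiseSdPA = 0,
                                  seed = 1) {
  if (Po < 0 || Po > 1) stop("Po must be in [0, 1]")
  .withSeed(seed, {
    m <- matrix(stats::rbinom(nTraces * nSamples, N, Po) * iPA,
                nrow = nTraces)
    if (noiseSdPA > 0)
      m <- m + matrix(stats::rnorm(nTraces * nSamples, 0, noiseSdPA),
                      nrow = nTraces)
    m
  })
}
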