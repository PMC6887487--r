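#' Number of sweeps in a SweepSet
#' @param x a [SweepSet]
#' @return integer count
#' @export
setGeneric("nSweeps", function(x) standardGeneric("nSweeps"))

#' @rdname nSweeps
#' @export
setMethod("nSweeps", "SweepSet", function(x) length(x@sweeps))

#' Extract the sweep list from a SweepSet
#' @param x a [SweepSet]
#' @return list of [SweepRecord]
#' @export
setGeneric("sweeps", function(x) standardGeneric("sweeps"))

#' @rdname sweeps
#' @export
setMethod("sweeps", "SweepSet", function(x) x@sweeps)

#' Epoch annotation table of a sweep
#' @param x a [SweepRecord]
#' @return data.frame of solution epochs
#' @export
setGeneric("epochs", function(x) standardGeneric("epochs"))

#' @rdname epochs
#' @export
setMethod("epochs", "SweepRecord", function(x) x@epochs)

#' Fitted time constant
#' @param x an [ExpFit]
#' @return time constant in seconds
#' @export
setGeneric("tauS", function(x) standardGeneric("tauS"))

#' @rdname tauS
#' @export
setMethod("tauS", "ExpFit", function(x) x@tauS)

#' Row data of a TimeCourse
#' @param x a [TimeCourse]
#' @return data.frame, one row per sweep
#' @export
setGeneric("tcData", function(x) standardGeneric("tcData"))

#' @rdname tcData
#' @export
setMethod("tcData", "TimeCourse", function(x) x@data)

#' Generator matrix of a kinetic scheme
#' @param x a [KineticScheme]
#' @return 5x5 generator matrix (s^-1)
#' @export
setGeneric("generatorMatrix", function(x) standardGeneric("generatorMatrix"))

#' @rdname generatorMatrix
#' @export
setMethod("generatorMatrix", "KineticScheme", function(x) x@Q)

#' State occupancies of a propagated trajectory
#' @param x an [OccupancyTrajectory]
#' @return matrix with one row per time point, columns S1..S5
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))

#' @rdname occupancy
#' @export
setMethod("occupancy", "OccupancyTrajectory", function(x) x@occupancy)

setMethod("show", "SweepSet", function(object) {
  cat("SweepSet with", nSweeps(object), "sweeps\n")
  if (nSweeps(object)) {
    s <- object@sweeps[[1]]
    cat("  first sweep:", length(s@t_s), "samples at",
        s@sampleRateHz, "Hz,", nrow(s@epochs), "epochs\n")
  }
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
})

setMethod("show", "TimeCourse", function(object) {
  d <- object@data
  cat("TimeCourse with", nrow(d), "rows (", sum(d$exposed),
      "exposed ), normalized at sweep", object@normalizationSweep, "\n")
})

setMethod("show", "ExpFit", function(object) {
  cat(sprintf("ExpFit [%s]: tau = %.4g s, A = %.3g, plateau = %.3g%s\n",
              object@form, object@tauS, object@amplitude, object@plateau,
              if (object@converged) "" else " (not converged)"))
})

setMethod("show", "HillFit", function(object) {
  cat(sprintf("HillFit: K = %.4g M, base = %.3g, max = %.3g, s = %.3g%s\n",
              object@K_M, object@base, object@maxF, object@s,
              if (object@sFixed) " (fixed)" else ""))
})

setMethod("show", "WoodhullFit", function(object) {
  cat(sprintf("WoodhullFit: K_D(0 mV) = %.4g M, Zdelta = %.3g (T = %.2f K)\n",
              object@K_D0_M, object@Zdelta, object@temperatureK))
})

setMethod("show", "NoiseResult", function(object) {
  cat(sprintf("NoiseResult: i = %.4g pA, N = %.4g channels, %d concentrations\n",
              object@iSinglePA, object@nChannels, nrow(object@table)))
})

setMethod("show", "KineticScheme", function(object) {
  cat(sprintf(
    "KineticScheme (%s): k0 = %.3g /M/s, k1 = %.3g /s, k2 = %.3g /s, k3 = %.3g /s, kRX = %.3g /s at %.3g M\n",
    object@topology, object@k0, object@k1, object@k2, object@k3,
    object@kRX, object@concM))
})

setMethod("show", "OccupancyTrajectory", function(object) {
  cat(sprintf("OccupancyTrajectory: %d time points over [%.3g, %.3g] s; final modified fraction %.4g\n",
              length(object@times), min(object@times), max(object@times),
              object@occupancy[nrow(object@occupancy), 5]))
})

setMethod("show", "ModificationResult", function(object) {
  cat(sprintf("ModificationResult: k_open = %.4g, k_closed = %.4g /M/s (ratio %.3g), Po fold-change %.3g\n  verdict: %s\n",
              object@kOpen, object@kClosed, object@rateRatio,
              object@poFoldChange, object@verdict))
})

setMethod("show", "Speciation", function(object) {
  cat(sprintf("Speciation at pH %.2f (pKa %.2f): cation %.4g M, neutral %.4g M of %.4g M total\n",
              object@pH, object@pKa, object@cationM, object@neutralM,
              object@totalM))
})
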