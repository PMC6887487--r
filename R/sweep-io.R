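#' Construct a solution-epoch table
#'
#' Helper building the epoch annotation carried by a [SweepRecord]. All
#' arguments are recycled to a common length.
#'
#' @param start_s,end_s epoch boundaries (s, experiment clock)
#' @param label epoch label (e.g. "pre", "agonist", "reagent")
#' @param agonist_id,agonist_conc_M agonist identity (NA if absent) and
#'   concentration (mol/L, 0 if absent)
#' @param reagent_id,reagent_free_conc_M reactive reagent identity
#'   ("Ag", "MTSEA", "MTSET" or NA) and free concentration (mol/L)
#' @param voltage_mV holding potential (mV)
#' @return data.frame suitable for the `epochs` slot of a [SweepRecord]
#' @export
solutionEpochs <- function(start_s, end_s, label,
                           agonist_id = NA_character_, agonist_conc_M = 0,
                           reagent_id = NA_character_,
                           reagent_free_conc_M = 0, voltage_mV = -60) {
  data.frame(start_s = start_s, end_s = end_s, label = label,
             agonist_id = agonist_id, agonist_conc_M = agonist_conc_M,
             reagent_id = reagent_id,
             reagent_free_conc_M = reagent_free_conc_M,
             voltage_mV = voltage_mV, stringsAsFactors = FALSE)
}

#' Construct a SweepRecord
#'
#' @param index zero-based sweep index
#' @param t_s sample times (s), strictly increasing
#' @param i_pA sampled current (pA)
#' @param epochs epoch table (see [solutionEpochs()])
#' @param sampleRateHz nominal sampling rate; inferred from `t_s` when
#'   missing
#' @return a validated [SweepRecord]
#' @export
sweepRecord <- function(index, t_s, i_pA, epochs,
                        sampleRateHz = NULL) {
  if (is.null(sampleRateHz))
    sampleRateHz <- if (length(t_s) > 1) 1 / stats::median(diff(t_s)) else NA_real_
  new("SweepRecord", index = as.integer(index), t_s = as.numeric(t_s),
      i_pA = as.numeric(i_pA), epochs = epochs,
      sampleRateHz = as.numeric(sampleRateHz))
}

#' Construct a SweepSet
#'
#' @param sweeps list of [SweepRecord], indices consecutive from 0
#' @param meta metadata list (construct, temperature_K, provenance, ...)
#' @return a validated [SweepSet]
#' @export
sweepSet <- function(sweeps = list(), meta = list()) {
  new("SweepSet", sweeps = sweeps, meta = meta)
}

## numeric fields are serialized with 17 significant digits so that the
## write -> read round trip is bit-exact for doubles
.fmtNum <- function(x) sprintf("%.17g", x)

#' Write a sweep bundle
#'
#' Serializes a [SweepSet] to a directory holding `protocol.json` (the
#' per-sweep epoch tables plus metadata) and one `sweep_<k>.csv` trace
#' file per sweep with header `time_s,current_pA`. The serialization is
#' canonical: writing, reading and writing again produces a byte-identical
#' `protocol.json`.
#'
#' @param set a [SweepSet]
#' @param path directory to create (must be creatable/writable)
#' @return `path`, invisibly
#' @export
writeSweepBundle <- function(set, path) {
  stopifnot(is(set, "SweepSet"))
  validObject(set)
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stop("cannot create bundle directory: ", path)
  proto <- list(
    format = "sweep-bundle-v1",
    meta = set@meta,
    sweeps = lapply(set@sweeps, function(s) {
      ep <- s@epochs
      list(index = s@index,
           file = sprintf("sweep_%d.csv", s@index),
           sample_rate_Hz = s@sampleRateHz,
           epochs = lapply(seq_len(nrow(ep)), function(k) {
             as.list(ep[k, , drop = FALSE])
           }))
    }))
  json <- jsonlite::toJSON(proto, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null", pretty = TRUE)
  writeLines(json, file.path(path, "protocol.json"))
  for (s in set@sweeps) {
    con <- file(file.path(path, sprintf("sweep_%d.csv", s@index)), "w")
    writeLines("time_s,current_pA", con)
    if (length(s@t_s))
      writeLines(paste(.fmtNum(s@t_s), .fmtNum(s@i_pA), sep = ","), con)
    close(con)
  }
  invisible(path)
}

#' Read a sweep bundle
#'
#' Inverse of [writeSweepBundle()]. Validates every invariant of the
#' sweep data model and reports the offending sweep on failure.
#'
#' @param path bundle directory containing `protocol.json`
#' @return a validated [SweepSet]
#' @export
readSweepBundle <- function(path) {
  pj <- file.path(path, "protocol.json")
  if (!file.exists(pj))
    stop("not a sweep bundle (missing protocol.json): ", path)
  proto <- jsonlite::fromJSON(pj, simplifyVector = FALSE)
  if (is.null(proto$format) || proto$format != "sweep-bundle-v1")
    stop("unrecognized bundle format in ", pj)
  sweeps <- lapply(proto$sweeps, function(ps) {
    f <- file.path(path, ps$file)
    if (!file.exists(f))
      stop("bundle inconsistent: missing trace file for sweep ", ps$index)
    tr <- utils::read.csv(f, colClasses = "numeric")
    if (!identical(names(tr), c("time_s", "current_pA")))
      stop("bad trace header in ", f)
    ep <- do.call(rbind, lapply(ps$epochs, function(e) {
      e <- lapply(e, function(v) if (is.null(v)) NA else v)
      solutionEpochs(e$start_s, e$end_s, e$label,
                     as.character(e$agonist_id), e$agonist_conc_M,
                     as.character(e$reagent_id), e$reagent_free_conc_M,
                     e$voltage_mV)
    }))
    if (is.null(ep)) ep <- solutionEpochs(numeric(), numeric(), character())
    s <- try(sweepRecord(ps$index, tr$time_s, tr$current_pA, ep,
                         ps$sample_rate_Hz), silent = TRUE)
    if (inherits(s, "try-error"))
      stop("invalid sweep ", ps$index, ": ", attr(s, "condition")$message)
    s
  })
  meta <- proto$meta
  if (is.null(meta)) meta <- list()
  sweepSet(sweeps, meta)
}

.findEpoch <- function(sweep, epochLabel) {
  k <- which(sweep@epochs$label == epochLabel)
  if (!length(k))
    stop("sweep ", sweep@index, " has no epoch labelled '", epochLabel, "'")
  k[1]
}

#' Mean steady-state current in the trailing window of an epoch
#'
#' Averages the samples falling in the trailing `windowFraction` of the
#' named epoch — the steady-state portion of the response. The default
#' window is the trailing quarter.
#'
#' @param sweep a [SweepRecord]
#' @param epochLabel label of the epoch to measure
#' @param windowFraction fraction of the epoch, from its end, to average
#'   over (in (0, 1])
#' @return mean current (pA)
#' @export
epochMeanCurrent <- function(sweep, epochLabel, windowFraction = 0.25) {
  stopifnot(windowFraction > 0, windowFraction <= 1)
  k <- .findEpoch(sweep, epochLabel)
  a <- sweep@epochs$start_s[k]
  b <- sweep@epochs$end_s[k]
  w0 <- b - windowFraction * (b - a)
  ## an epoch owns samples in [start, end): the sample at the boundary
  ## belongs to the next solution
  sel <- sweep@t_s >= w0 - 1e-12 & sweep@t_s < b - 1e-12
  if (!any(sel)) sel <- sweep@t_s >= w0 - 1e-12 & sweep@t_s <= b + 1e-12
  if (!any(sel))
    stop("no samples in the steady-state window of epoch '", epochLabel,
         "' of sweep ", sweep@index)
  mean(sweep@i_pA[sel])
}

#' Leak-subtracted steady-state agonist current
#'
#' Subtracts the control (no-agonist) steady-state current, measured
#' right before agonist application, from the agonist steady-state
#' current of the same sweep; this corrects for leak-current drift
#' between sweeps.
#'
#' @param sweep a [SweepRecord]
#' @param agonistEpoch,controlEpoch epoch labels
#' @inheritParams epochMeanCurrent
#' @return leak-subtracted current (pA)
#' @export
leakSubtract <- function(sweep, agonistEpoch = "agonist",
                         controlEpoch = "pre", windowFraction = 0.25) {
  epochMeanCurrent(sweep, agonistEpoch, windowFraction) -
    epochMeanCurrent(sweep, controlEpoch, windowFraction)
}
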