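#' Validate a pipeline configuration
#'
#' Schema and cross-field checks for [runPipeline()] configurations.
#' A configuration is a plain named list; see [runPipeline()] for the
#' recognized fields.
#'
#' @param config named list
#' @return character vector of human-readable errors (empty when valid)
#' @export
validateConfig <- function(config) {
  errs <- character()
  chk <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  chk(is.list(config), "config must be a list")
  if (!is.list(config)) return(errs)
  chk(!is.null(config$seed) && is.numeric(config$seed),
      "config$seed (integer) is required")
  chk(!is.null(config$outDir), "config$outDir is required")
  synthetic <- !is.null(config$truth) || !is.null(config$protocolOpen)
  if (synthetic) {
    chk(!is.null(config$protocolOpen) && !is.null(config$protocolClosed),
        "synthetic runs need protocolOpen and protocolClosed lists")
  } else {
    chk(!is.null(config$bundleOpen) && !is.null(config$bundleClosed),
        "provide either synthetic truth/protocols or bundleOpen/bundleClosed")
    for (f in c("bundleOpen", "bundleClosed"))
      if (!is.null(config[[f]]))
        chk(dir.exists(config[[f]]),
            paste0("config$", f, " does not exist: ", config[[f]]))
    chk(!is.null(config$reagentFreeConcM) && config$reagentFreeConcM > 0,
        "bundle runs need a positive config$reagentFreeConcM")
  }
  correction <- config$correction %||% "none"
  chk(correction %in% c("none", "divide", "alternating"),
      "config$correction must be 'none', 'divide' or 'alternating'")
  if (correction == "alternating" && synthetic) {
    alt <- isTRUE(config$protocolOpen$alternatingReagent) &&
      isTRUE(config$protocolClosed$alternatingReagent)
    chk(alt, "alternating correction requires alternating protocols")
  }
  errs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## wrap an alternating-corrected course as a TimeCourse for the fitter
.tcFromCourse <- function(course, exposureS) {
  d <- data.frame(sweep = course$step,
                  experiment_time_s = course$step * exposureS,
                  cumulative_exposure_s = course$step * exposureS,
                  I_leak_sub_pA = course$I, I_norm = course$I_norm,
                  exposed = TRUE)
  new("TimeCourse", data = d, normalizationSweep = 0L)
}

.analyzeState <- function(set, protocol, correction, fitForm, rundownFit,
                          log) {
  reagentConc <- protocol@reagentFreeConcM
  if (correction == "alternating") {
    currents <- vapply(set@sweeps, leakSubtract, numeric(1))
    tc0 <- buildTimeCourse(set, reagentId = protocol@reagentId)
    blk <- seq(protocol@nPresweeps + 1, nSweeps(set))
    alt <- correctRundownAlternating(currents[blk],
                                     tc0@data$exposed[blk])
    tc <- .tcFromCourse(alt$corrected, protocol@exposureS)
    log("alternating correction:", length(blk), "sweeps ->",
        nrow(alt$corrected), "corrected points")
  } else {
    tc <- buildTimeCourse(set, reagentId = protocol@reagentId)
    if (correction == "divide") {
      tc <- correctRundownDivide(tc, rundownFit)
      log("divide correction with plateau", rundownFit@plateauC,
          "tau", rundownFit@tauRs, "s")
    }
  }
  fit <- fitMonoexponential(tc, form = fitForm)
  k <- modificationRate(fit, reagentConc)
  log(sprintf("tau = %.4g s -> k = %.4g /M/s at %.3g M free reagent",
              fit@tauS, k, reagentConc))
  list(tc = tc, fit = fit, k = k)
}

#' Run the full state-dependent accessibility pipeline
#'
#' Simulates (or loads) an open-state and a closed-state modification
#' experiment, applies the configured rundown correction, fits
#' mono-exponential time courses, converts to bimolecular rates,
#' estimates the agonist-induced Po fold-change, and issues the
#' state-dependence verdict. Writes tidy CSV time courses, a JSON
#' summary and a log to `outDir`; runs are idempotent for a fixed seed.
#'
#' Recognized config fields: `seed`, `outDir`, `truth` (list of
#' [groundTruth()] arguments), `protocolOpen` / `protocolClosed` (lists
#' of [protocolSpec()] arguments), or `bundleOpen` / `bundleClosed`
#' (paths) with `reagentFreeConcM`; `correction` (`"none"`, `"divide"`,
#' `"alternating"`), `fitForm` (`"free"` or `"fixed_0.9_0.1"`),
#' `filterGateFactor`, `gateTol`.
#'
#' @param config named list (see [validateConfig()])
#' @return a [ModificationResult], invisibly; side effect: report files
#'   under `config$outDir`
#' @export
runPipeline <- function(config) {
  errs <- validateConfig(config)
  if (length(errs)) stop("invalid config:\n  ", paste(errs, collapse = "\n  "))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  logLines <- character()
  log <- function(...) {
    line <- paste(...)
    logLines <<- c(logLines, line)
    invisible(line)
  }
  seed <- as.integer(config$seed)
  correction <- config$correction %||% "none"
  fitForm <- config$fitForm %||% "free"
  log("seed:", seed, "| correction:", correction, "| fit form:", fitForm)

  synthetic <- !is.null(config$truth) || !is.null(config$protocolOpen)
  if (synthetic) {
    truthArgs <- config$truth %||% list()
    pOpen <- do.call(protocolSpec,
                     utils::modifyList(list(exposureState = "open"),
                                       config$protocolOpen %||% list()))
    pClosed <- do.call(protocolSpec,
                       utils::modifyList(list(exposureState = "closed"),
                                         config$protocolClosed %||% list()))
    simOpen <- simulateExperiment(
      do.call(groundTruth, utils::modifyList(truthArgs, list(seed = seed))),
      pOpen)
    simClosed <- simulateExperiment(
      do.call(groundTruth,
              utils::modifyList(truthArgs, list(seed = seed + 1L))),
      pClosed)
    setOpen <- simOpen$set; setClosed <- simClosed$set
    rundownFit <- NULL
    if (correction == "divide") {
      ## matched reagent-free control: same truth, modification disabled
      ctrlTruth <- do.call(groundTruth, utils::modifyList(
        truthArgs, list(kOpen = 0, kClosed = 0, seed = seed + 2L)))
      ctrl <- simulateExperiment(ctrlTruth, pOpen)
      tcCtrl <- try(buildTimeCourse(ctrl$set), silent = TRUE)
      rundownFit <- fitRundown(tcCtrl@data)
      log("fitted rundown control: plateau", rundownFit@plateauC,
          "tau", rundownFit@tauRs, "s")
    }
  } else {
    setOpen <- readSweepBundle(config$bundleOpen)
    setClosed <- readSweepBundle(config$bundleClosed)
    conc <- config$reagentFreeConcM
    pOpen <- protocolSpec(exposureState = "open", reagentFreeConcM = conc)
    pClosed <- protocolSpec(exposureState = "closed",
                            reagentFreeConcM = conc)
    rundownFit <- if (!is.null(config$rundownC))
      new("RundownFit", plateauC = config$rundownC,
          tauRs = config$rundownTauS) else NULL
  }

  ## QC on the pre-exposure sweeps
  for (nm in c("open", "closed")) {
    set <- if (nm == "open") setOpen else setClosed
    tc <- buildTimeCourse(set)
    pre <- tc@data$I_leak_sub_pA[tc@data$experiment_time_s < 0]
    if (length(pre) >= 2)
      log("QC", nm, "state:", qcRundownExclusion(pre))
  }

  resOpen <- .analyzeState(setOpen, pOpen, correction, fitForm,
                           rundownFit, log)
  resClosed <- .analyzeState(setClosed, pClosed, correction, fitForm,
                             rundownFit, log)

  ## Po fold-change lower bound from the pre-exposure open-state sweeps
  preIdx <- which(!buildTimeCourse(setOpen)@data$exposed)
  folds <- vapply(setOpen@sweeps[preIdx], function(s)
    poFoldChange(epochMeanCurrent(s, "agonist"),
                 epochMeanCurrent(s, "pre")), numeric(1))
  poFold <- mean(folds)
  log(sprintf("Po fold-change (lower bound) = %.4g from %d sweeps",
              poFold, length(folds)))

  verdict <- stateDependenceVerdict(
    resOpen$k, resClosed$k, poFold,
    filterGateFactor = config$filterGateFactor %||% 0.1,
    gateTol = config$gateTol %||% 0.05,
    tauOpen = resOpen$fit@tauS, tauClosed = resClosed$fit@tauS)
  log("verdict:", verdict@verdict, "| rate ratio:", verdict@rateRatio)

  utils::write.csv(resOpen$tc@data,
                   file.path(config$outDir, "timecourse_open.csv"),
                   row.names = FALSE)
  utils::write.csv(resClosed$tc@data,
                   file.path(config$outDir, "timecourse_closed.csv"),
                   row.names = FALSE)
  summary <- list(seed = seed, correction = correction, fitForm = fitForm,
                  k_open = resOpen$k, k_closed = resClosed$k,
                  tau_open_s = resOpen$fit@tauS,
                  tau_closed_s = resClosed$fit@tauS,
                  rate_ratio = verdict@rateRatio,
                  po_fold_change = poFold,
                  thresholds = as.list(verdict@thresholds),
                  verdict = verdict@verdict)
  jsonlite::write_json(summary, file.path(config$outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(logLines, file.path(config$outDir, "run.log"))
  invisible(verdict)
}
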