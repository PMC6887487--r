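test_that("time courses are normalized at the first-exposure read (t = 0)", {
  sim <- simulateExperiment(groundTruth(noiseSdPA = 0, kOpen = 0,
                                        kClosed = 0),
                            protocolSpec())
  tc <- buildTimeCourse(sim$set, "Ag")
  d <- tcData(tc)
  expect_true(all(abs(d$I_norm - 1) < 1e-9))   # k = 0: flat
  expect_equal(d$I_norm[d$sweep == tc@normalizationSweep], 1)
  expect_equal(tc@normalizationSweep, 6L)
  ## pre-exposure rows: negative time, zero cumulative exposure
  pre <- d[!d$exposed, ]
  expect_true(all(pre$experiment_time_s < 0))
  expect_true(all(pre$cumulative_exposure_s == 0))
  expect_true(all(diff(d$cumulative_exposure_s) >= 0))
  ## a set with no pre-exposure sweep cannot be normalized
  noPre <- sweepSet(lapply(seq_len(nSweeps(sim$set) - 6), function(k) {
    s <- sweeps(sim$set)[[k + 6]]
    initialize(s, index = k - 1L)
  }), meta = list())
  expect_error(buildTimeCourse(noPre, "Ag"), "normalization")
})

test_that("mono-exponential fits recover exact time constants", {
  mk <- function(x, y) {
    d <- data.frame(sweep = seq_along(x) - 1L, experiment_time_s = x,
                    cumulative_exposure_s = x, I_leak_sub_pA = y,
                    I_norm = y, exposed = TRUE)
    new("TimeCourse", data = d, normalizationSweep = 0L)
  }
  x <- seq(0, 10, by = 0.5)
  tcFixed <- mk(x, 0.9 * exp(-x / 2) + 0.1)
  expect_lt(abs(tauS(fitMonoexponential(tcFixed, "fixed_0.9_0.1")) / 2 - 1),
            1e-6)
  fitFree <- fitMonoexponential(tcFixed, "free")
  expect_lt(abs(tauS(fitFree) / 2 - 1), 1e-6)
  expect_lt(abs(fitFree@amplitude - 0.9), 1e-6)
  expect_lt(abs(fitFree@plateau - 0.1), 1e-6)
  ## exp(-1.5 m) at 1 s exposures: tau = 2/3, A -> 1, c -> 0
  m <- 0:5
  f2 <- fitMonoexponential(mk(m, exp(-1.5 * m)), "free")
  expect_lt(abs(tauS(f2) / (2 / 3) - 1), 1e-6)
  expect_lt(abs(f2@amplitude - 1), 1e-6)
  expect_lt(abs(f2@plateau), 1e-6)
  ## flat course: no decay, tau flagged infinite
  flat <- fitMonoexponential(mk(m, rep(1, 6)), "free")
  expect_true(is.infinite(tauS(flat)))
  expect_false(flat@converged)
})

test_that("modification rates are (1/tau)/concentration", {
  expect_equal(modificationRate(20, 50e-9), 1.0e6)
  ## tau = 0.611 s at 50 nM free reagent gives 3.27e7 /M/s
  expect_equal(modificationRate(0.611, 50e-9) / 1e7, 3.27, tolerance = 2e-3)
  ## rate halves when the concentration doubles at fixed tau
  expect_equal(modificationRate(20, 100e-9), 0.5e6)
  ## and halves again when tau doubles at fixed concentration
  expect_equal(modificationRate(40, 50e-9), 0.5e6)
  expect_error(modificationRate(20, 0), "> 0")
})

test_that("rundown fits recover the decline parameters", {
  t <- seq(0, 180, by = 15)
  y <- (1 - 0.045) * exp(-t / 84.57) + 0.045
  d <- data.frame(experiment_time_s = t, I_norm = y)
  fit <- fitRundown(d)
  expect_lt(abs(fit@plateauC / 0.045 - 1), 1e-6)
  expect_lt(abs(fit@tauRs / 84.57 - 1), 1e-6)
  ## flat course: no rundown
  flat <- fitRundown(data.frame(experiment_time_s = t, I_norm = rep(1, 13)))
  expect_equal(flat@plateauC, 1)
  ## noisy recovery over 100 seeds
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    yn <- y * (1 + rnorm(length(y), 0, 0.02))
    f <- fitRundown(data.frame(experiment_time_s = t, I_norm = yn))
    abs(f@tauRs / 84.57 - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.1)
})

test_that("divide-out rundown correction isolates modification", {
  ## a course equal to the rundown curve corrects to 1 after t = 0
  t <- seq(-75, 90, by = 15)
  rd <- new("RundownFit", plateauC = 0.045, tauRs = 84.57)
  y <- predictRundown(rd, t)
  y <- y / y[t == 0]      # normalized at t = 0 as built time courses are
  d <- data.frame(sweep = seq_along(t) - 1L, experiment_time_s = t,
                  cumulative_exposure_s = pmax(t, 0),
                  I_leak_sub_pA = y, I_norm = predictRundown(rd, t),
                  exposed = t >= 0)
  tc <- new("TimeCourse", data = d, normalizationSweep = 5L)
  corr <- correctRundownDivide(tc, rd)
  post <- tcData(corr)[t >= 0, ]
  expect_true(all(abs(post$I_norm - 1) < 1e-12))
  ## t < 0 rows untouched
  expect_equal(tcData(corr)$I_norm[t < 0], d$I_norm[t < 0])
  ## plateau 1 (no rundown) leaves the course unchanged
  ident <- correctRundownDivide(tc, new("RundownFit", plateauC = 1,
                                        tauRs = 10))
  expect_equal(tcData(ident)$I_norm, d$I_norm)
})

test_that("rundown x modification factorizes and divides out exactly", {
  tr <- groundTruth(noiseSdPA = 0, kOpen = 3e7,
                    rundownC = 0.045, rundownTauS = 84.57,
                    rundownClock = "wall")
  sim <- simulateExperiment(tr, protocolSpec())
  tc <- buildTimeCourse(sim$set, "Ag")
  ## rundown reference measured from a matched reagent-free experiment
  ctrl <- simulateExperiment(groundTruth(noiseSdPA = 0, kOpen = 0,
                                         kClosed = 0, rundownC = 0.045,
                                         rundownTauS = 84.57,
                                         rundownClock = "wall"),
                             protocolSpec())
  tcCtrl <- buildTimeCourse(ctrl$set, "Ag")
  post <- tcData(tc)$experiment_time_s >= 0
  ratio <- tcData(tc)$I_norm[post] / tcData(tcCtrl)$I_norm[post]
  m <- seq_len(sum(post)) - 1
  expect_equal(ratio, exp(-1.5 * m), tolerance = 1e-9)
  ## dividing by the fitted rundown curve recovers the pure decay
  rd <- fitRundown(tcData(tcCtrl))
  corr <- correctRundownDivide(tc, rd)
  expect_equal(tcData(corr)$I_norm[post], exp(-1.5 * m), tolerance = 1e-6)
})

test_that("alternating correction reproduces the hand-computed recursion", {
  I <- c(100, 95, 76, 72.2, 57.76)
  out <- correctRundownAlternating(I, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$corrected$I, c(100, 85, 72.25), tolerance = 1e-12)
  expect_equal(out$rundownOnly$I, c(100, 95, 90.25), tolerance = 1e-12)
  expect_equal(out$reagentOnly$I, c(100, 80, 64), tolerance = 1e-12)
  ## equal drops on both phases cancel: corrected course flat
  Ieq <- 100 * 0.9^(0:5)
  eq <- correctRundownAlternating(Ieq, rep(c(FALSE, TRUE), 3))
  expect_true(all(abs(eq$corrected$I_norm - 1) < 1e-12))
  ## no rundown: corrected equals the raw exposed-phase decline
  Inr <- c(100, 100, 80, 80, 64, 64)
  nr <- correctRundownAlternating(Inr, rep(c(FALSE, TRUE), 3))
  expect_equal(nr$corrected$I, c(100, 80, 64), tolerance = 1e-12)
  expect_error(correctRundownAlternating(I, c(TRUE, FALSE, TRUE, FALSE, TRUE)),
               "alternate")
  expect_error(correctRundownAlternating(c(100, 0, 50, 25),
                                         rep(c(FALSE, TRUE), 2)), "zero")
})

test_that("Po fold-change is a lower bound on the true change", {
  expect_equal(poFoldChange(-5000, -50), 100)
  expect_equal(poFoldChange(-50, -50), 1)
  expect_error(poFoldChange(-50, 0), "zero")
  ## generator truth: Po 0.9 vs 0.005 (180-fold), leak shrinks the estimate
  tr <- groundTruth(noiseSdPA = 0, kOpen = 0, kClosed = 0, leakPA = -10,
                    poMax = 0.9, poBase = 0.005, poKHalfM = 1e-5)
  sim <- simulateExperiment(tr, protocolSpec(nPresweeps = 1,
                                             nExposureSweeps = 1))
  s <- sweeps(sim$set)[[1]]
  est <- poFoldChange(epochMeanCurrent(s, "agonist"),
                      epochMeanCurrent(s, "pre"))
  truthFold <- .hillPoOracle(tr, 3e-3) / tr@poBase
  expect_gt(truthFold, 170)
  expect_lt(est, truthFold)
})

test_that("the state-dependence verdict compares rates with the Po change", {
  v1 <- stateDependenceVerdict(2.8e7, 1e7, 150)
  expect_equal(v1@verdict, "filter-not-gate")
  expect_equal(v1@rateRatio, 2.8)
  v2 <- stateDependenceVerdict(100, 1, 100)
  expect_equal(v2@verdict, "gate-consistent")
  v3 <- stateDependenceVerdict(30, 1, 100)
  expect_equal(v3@verdict, "indeterminate")
  expect_error(stateDependenceVerdict(0, 1, 100), "> 0")
})

test_that("Welch's t-test matches the closed-form statistic", {
  x <- c(1, 2, 3)
  same <- welchTTest(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  far <- welchTTest(x, x + 1000)
  expect_lt(far$p, 1e-6)
  expect_error(welchTTest(c(1, 1), c(2, 2)), "degenerate")
  ## oracle: hand-computed Welch statistic and Satterthwaite df
  set.seed(9)
  for (k in 1:5) {
    a <- rnorm(6, 0, 1); b <- rnorm(9, 0.5, 2)
    got <- welchTTest(a, b)
    sa <- var(a) / length(a); sb <- var(b) / length(b)
    tRef <- (mean(a) - mean(b)) / sqrt(sa + sb)
    dfRef <- (sa + sb)^2 / (sa^2 / (length(a) - 1) + sb^2 / (length(b) - 1))
    pRef <- 2 * pt(-abs(tRef), dfRef)
    expect_lt(abs(got$t - tRef), 1e-10)
    expect_lt(abs(got$df - dfRef), 1e-10)
    expect_lt(abs(got$p - pRef), 1e-10)
  }
})

test_that("rundown QC discards cells losing more than half their current", {
  expect_equal(qcRundownExclusion(c(-100, -80, -49)), "discard")
  expect_equal(qcRundownExclusion(c(-100, -80, -51)), "keep")
  expect_equal(qcRundownExclusion(c(-100, -50)), "keep")  # strictly more
  expect_error(qcRundownExclusion(-100), "at least 2")
})

test_that("recovered rates are accurate under realistic noise", {
  ## end-to-end: simulate, build course, fit, convert; 2% signal noise
  ks <- c(1e6, 1e7, 3e7)
  exposure <- c(8, 1, 0.5)
  errs <- unlist(lapply(seq_along(ks), function(j) {
    vapply(1:8, function(s) {
      tr <- groundTruth(kOpen = ks[j], noiseSdPA = 51, seed = 1000 + s)
      p <- protocolSpec(nExposureSweeps = 10, exposureS = exposure[j],
                        sweepPeriodS = 20)
      sim <- simulateExperiment(tr, p)
      tc <- buildTimeCourse(sim$set, "Ag")
      k <- modificationRate(fitMonoexponential(tc), 50e-9)
      abs(k / ks[j] - 1)
    }, numeric(1))
  }))
  expect_lt(median(errs), 0.15)
})
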