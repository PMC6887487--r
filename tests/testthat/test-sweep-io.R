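test_that("sweep bundles round-trip exactly and serialize canonically", {
  sim <- simulateExperiment(groundTruth(noiseSdPA = 5, seed = 11),
                            protocolSpec(nPresweeps = 1,
                                         nExposureSweeps = 1))
  set <- sim$set
  d1 <- withr::local_tempdir()
  writeSweepBundle(set, d1)
  back <- readSweepBundle(d1)
  expect_equal(nSweeps(back), nSweeps(set))
  for (k in seq_len(nSweeps(set))) {
    expect_identical(back@sweeps[[k]]@t_s, set@sweeps[[k]]@t_s)
    expect_identical(back@sweeps[[k]]@i_pA, set@sweeps[[k]]@i_pA)
    expect_equal(epochs(back@sweeps[[k]]), epochs(set@sweeps[[k]]))
  }
  ## write -> read -> write is byte-identical on the protocol
  d2 <- withr::local_tempdir()
  writeSweepBundle(back, d2)
  expect_identical(readLines(file.path(d1, "protocol.json")),
                   readLines(file.path(d2, "protocol.json")))
})

test_that("an empty SweepSet writes a valid bundle with no trace files", {
  d <- withr::local_tempdir()
  writeSweepBundle(sweepSet(), d)
  expect_length(list.files(d, pattern = "^sweep_"), 0)
  expect_equal(nSweeps(readSweepBundle(d)), 0)
})

test_that("invalid epochs and inconsistent bundles are rejected", {
  ep <- solutionEpochs(5, 1, "pre")     # end < start
  expect_error(sweepRecord(0, 0:10, rep(0, 11), ep), "end_s > start_s")
  ## non-monotonic time
  ok <- solutionEpochs(0, 10, "pre")
  expect_error(sweepRecord(0, c(0, 2, 1), c(0, 0, 0), ok),
               "strictly increasing")
  ## bundle with a missing trace file
  sim <- simulateExperiment(groundTruth(seed = 2),
                            protocolSpec(nPresweeps = 1,
                                         nExposureSweeps = 1))
  d <- withr::local_tempdir()
  writeSweepBundle(sim$set, d)
  file.remove(file.path(d, "sweep_1.csv"))
  expect_error(readSweepBundle(d), "sweep 1")
  expect_error(readSweepBundle(withr::local_tempdir()), "protocol.json")
})

test_that("the generator contract holds: exposures only after the presweeps", {
  sim <- simulateExperiment(groundTruth(seed = 1),
                            protocolSpec(nPresweeps = 6,
                                         nExposureSweeps = 6))
  expect_equal(nSweeps(sim$set), 12)
  hasAg <- vapply(sweeps(sim$set), function(s)
    any(!is.na(epochs(s)$reagent_id) & epochs(s)$reagent_id == "Ag"),
    logical(1))
  expect_identical(which(hasAg) - 1L, 6:11)
  expect_identical(sim$truthRecord$perSweep$exposed, hasAg)
})

test_that("epochMeanCurrent averages the trailing window", {
  s <- makeSweep(f = function(t) rep(-100, length(t)))
  expect_equal(epochMeanCurrent(s, "agonist", 0.9), -100)
  ## linear ramp: closed-form mean of the trailing quarter of [0, 10]
  r <- makeSweep(f = function(t) -t, labels = "pre")
  got <- epochMeanCurrent(r, "pre", 0.25)
  expect_lt(abs(got - (-8.75)), 0.01)   # within one sample spacing
  ## refinement invariance for a piecewise-constant trace
  pc <- function(t) ifelse(t < 5, -10, -40)
  v1 <- epochMeanCurrent(makeSweep(f = pc, labels = "pre", rate = 50), "pre")
  v2 <- epochMeanCurrent(makeSweep(f = pc, labels = "pre", rate = 1000), "pre")
  expect_lt(abs(v1 - v2), 1e-6)
  expect_error(epochMeanCurrent(s, "nonexistent"), "no epoch")
})

test_that("a single-sample window returns that sample", {
  t <- c(0, 4, 9.99)
  ep <- solutionEpochs(0, 9.99, "pre")
  s <- sweepRecord(0, t, c(-1, -2, -7), ep)
  expect_equal(epochMeanCurrent(s, "pre", 0.2), -7)
})

test_that("leak subtraction is a difference of epoch means and vanishes on itself", {
  s <- makeSweep(f = function(t) ifelse(t < 5, -50, -5000))
  expect_equal(leakSubtract(s), -4950)
  expect_equal(leakSubtract(s, "pre", "pre"), 0)
  expect_equal(leakSubtract(s, "agonist", "agonist"), 0)
  ## zero-noise generator: leak cancels exactly
  tr <- groundTruth(leakPA = 20, noiseSdPA = 0, kOpen = 0, kClosed = 0,
                    poBase = 0)
  sim <- simulateExperiment(tr, protocolSpec(nPresweeps = 1,
                                             nExposureSweeps = 1))
  sig <- tr@nChannels * .hillPoOracle(tr, 3e-3) * tr@iSinglePA
  expect_equal(leakSubtract(sweeps(sim$set)[[1]]), sig, tolerance = 1e-12)
})
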