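test_that("the generator matrix encodes exactly the allowed transitions", {
  sc <- kineticScheme(0.5e5, 50, 0.06, 10, 500, 2e-3)
  Q <- unname(generatorMatrix(sc))
  expect_equal(rowSums(Q), rep(0, 5), tolerance = 1e-12)
  kb <- 0.5e5 * 2e-3
  expect_equal(Q[1, 2], kb); expect_equal(Q[3, 4], kb)
  expect_equal(Q[2, 1], 50); expect_equal(Q[4, 3], 50)
  expect_equal(Q[1, 3], 0.06); expect_equal(Q[2, 4], 0.06)
  expect_equal(Q[3, 1], 10);   expect_equal(Q[4, 2], 10)
  expect_equal(Q[4, 5], 500)
  ## nothing else off-diagonal
  off <- Q; diag(off) <- 0
  off[cbind(c(1, 3, 2, 4, 1, 2, 3, 4, 4),
            c(2, 4, 1, 3, 3, 4, 1, 2, 5))] <- 0
  expect_true(all(off == 0))
  ## detailed balance around the 4-state cycle
  expect_equal(Q[1, 2] * Q[2, 4] * Q[4, 3] * Q[3, 1],
               Q[1, 3] * Q[3, 4] * Q[4, 2] * Q[2, 1], tolerance = 1e-9)
  expect_error(kineticScheme(-1, 50, 0.06, 10, 500, 2e-3), ">= 0")
})

test_that("the default initial distribution is the unbound conformational equilibrium", {
  sc <- kineticScheme(0.5e5, 50, 0.06, 10, 500, 2e-3)
  p0 <- initialDistribution(sc)
  expect_equal(p0[3], 0.06 / 10.06, tolerance = 1e-12)
  expect_equal(p0[3], 0.00596, tolerance = 1e-3)
  expect_equal(sum(p0), 1)
  expect_equal(p0[c(2, 4, 5)], rep(0, 3))
  sym <- kineticScheme(0.5e5, 50, 5, 5, 500, 2e-3)
  expect_equal(initialDistribution(sym)[c(1, 3)], c(0.5, 0.5))
  ## at zero ligand, pre-equilibration in ligand changes nothing
  z <- kineticScheme(0.5e5, 50, 0.06, 10, 500, 0)
  expect_equal(initialDistribution(z, TRUE), initialDistribution(z, FALSE))
  expect_error(initialDistribution(kineticScheme(1, 1, 0, 0, 1, 1)),
               "k2 \\+ k3")
})

test_that("propagation conserves probability and reaches known limits", {
  sc <- kineticScheme(0.5e5, 50, 0.06, 10, 500, 2e-3)
  tg <- seq(0, 60, length.out = 121)
  traj <- propagate(sc, tg)
  occ <- unname(occupancy(traj))
  expect_equal(occ[1, ], initialDistribution(sc), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(abs(rowSums(occ) - 1) < 1e-8))
  expect_true(all(diff(occ[, 5]) >= -1e-9))   # absorbing state
  ## kRX = 0: never modified, long-time 4-state equilibrium
  eq <- kineticScheme(0.5e5, 50, 0.06, 10, 0, 2e-3)
  trajEq <- propagate(eq, c(0, 2000))
  pEnd <- unname(occupancy(trajEq)[2, ])
  expect_equal(pEnd[5], 0, tolerance = 1e-12)
  pAcc <- 0.06 / 10.06
  kb <- 0.5e5 * 2e-3
  pB <- kb / (kb + 50)
  expect_equal(pEnd[1:4],
               c((1 - pAcc) * (1 - pB), (1 - pAcc) * pB,
                 pAcc * (1 - pB), pAcc * pB),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(unmodifiedFraction(trajEq) == 1))
  expect_error(propagate(sc, tg, p0 = c(1, 1, 0, 0, 0)), "probability")
})

test_that("the model time constant behaves as the kinetics dictate", {
  ## 10x k2 (agonist shift) decreases tau 10-fold at 2 mM
  tauNo <- as.numeric(modelTau(schemeNoAgonist(2e-3)))
  tauAg <- as.numeric(modelTau(schemeWithAgonist(2e-3)))
  expect_lt(abs(tauNo / tauAg / 10 - 1), 0.05)
  ## fit and spectral estimates agree in the rate-limiting regime
  t1 <- modelTau(schemeNoAgonist(1e-2))
  expect_lt(abs(as.numeric(t1) / attr(t1, "tauEigen") - 1), 0.05)
  ## k2 rate-limiting at saturating reagent: tau -> 1/k2
  lim <- kineticScheme(1e5, 50, 0.01, 10, 500, 0.1)
  expect_lt(abs(as.numeric(modelTau(lim)) * 0.01 - 1), 0.05)
  ## doubling every rate halves tau (pure time rescaling)
  half <- kineticScheme(1e5, 100, 0.12, 20, 1000, 2e-3)
  base <- kineticScheme(0.5e5, 50, 0.06, 10, 500, 2e-3)
  expect_lt(abs(as.numeric(modelTau(half)) * 2 /
                  as.numeric(modelTau(base)) - 1), 1e-6)
})

test_that("tau fold-change tables scale as observed concentration series", {
  sc <- schemeNoAgonist(1e-2)
  tab <- tauFoldChangeTable(sc, 1e-2)
  expect_equal(tab$fold, 1, tolerance = 1e-12)
  ## access-limited regime: kRX huge, binding >> unbinding and k3
  fast <- kineticScheme(1e7, 1, 0.05, 0.1, 1e6, 1e-2)
  tabF <- tauFoldChangeTable(fast, c(1e-2, 1e-3, 1e-4))
  expect_true(all(abs(tabF$fold - 1) < 0.05))
  ## invariance of folds under a common time rescaling
  tab1 <- tauFoldChangeTable(schemeNoAgonist(1e-2), c(2e-3, 1e-4))
  sc2 <- kineticScheme(1e5, 100, 0.12, 20, 1000, 1e-2)
  tab2 <- tauFoldChangeTable(sc2, c(2e-3, 1e-4))
  expect_equal(tab1$fold, tab2$fold, tolerance = 1e-6)
})

test_that("the stochastic oracle agrees with deterministic propagation", {
  sc <- schemeWithAgonist(2e-3)
  ## determinism
  g1 <- gillespieOracle(sc, 500, 5, seed = 4)
  g2 <- gillespieOracle(sc, 500, 5, seed = 4)
  expect_identical(g1$unmodified, g2$unmodified)
  ## kRX = 0: nothing is ever modified
  g0 <- gillespieOracle(kineticScheme(0.5e5, 50, 0.6, 10, 0, 2e-3),
                        1000, 5, seed = 1)
  expect_true(all(g0$unmodified == 1))
  ## pointwise agreement within 3 binomial SE at n = 1e4
  n <- 1e4
  tauE <- attr(modelTau(sc), "tauEigen")
  g <- gillespieOracle(sc, n, 4 * tauE, seed = 1)
  p <- unmodifiedFraction(propagate(sc, g$times))
  bound <- 3 * sqrt(p * (1 - p) / n)
  expect_true(all(abs(g$unmodified - p) <= bound + 1e-12))
})

test_that("reagent speciation follows Henderson-Hasselbalch exactly", {
  half <- mtsSpeciation(2e-3, pH = 8.5, pKa = 8.5)
  expect_equal(half@cationM, 1e-3)
  expect_equal(half@neutralM, 1e-3)
  ## 2 mM at pH 7.4 / pKa 8.5 (independent closed form)
  sp <- mtsSpeciation(2e-3, 7.4)
  cation <- 2e-3 * 10^(-7.4) / (10^(-8.5) + 10^(-7.4))
  expect_equal(sp@cationM, cation, tolerance = 1e-12)
  expect_equal(sp@cationM, 1.85e-3, tolerance = 2e-3)
  expect_equal(sp@neutralM, 0.147e-3, tolerance = 2e-3)
  expect_equal(sp@cationM / sp@neutralM, 12.6, tolerance = 1e-2)
  ## conservation is exact
  expect_equal(sp@cationM + sp@neutralM, 2e-3, tolerance = 1e-15)
  ## high-pH limit: all neutral
  hi <- mtsSpeciation(2e-3, 14)
  expect_lt(hi@cationM / 2e-3, 1e-4)
})
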