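#' Build the five-state modification scheme
#'
#' Constructs the continuous-time Markov scheme for reagent modification
#' of a pore cysteine: the pore exchanges between an inaccessible and an
#' accessible conformation (`k2` forward, `k3` back), the reagent binds
#' and unbinds (`k0 * conc`, `k1`), and the cysteine is irreversibly
#' modified from the accessible-bound state at `kRX`. Under the default
#' `"full"` topology binding occurs in both conformations with the same
#' constants and conformational exchange occurs in both liganded
#' branches, so the four-state cycle satisfies detailed balance by
#' construction; `"accessible-only"` removes binding in the
#' inaccessible conformation.
#'
#' @param k0 binding rate constant (M^-1 s^-1)
#' @param k1 unbinding rate (s^-1)
#' @param k2,k3 conformational rates (s^-1)
#' @param kRX modification rate (s^-1)
#' @param concM reagent concentration (mol/L)
#' @param topology `"full"` or `"accessible-only"`
#' @return a validated [KineticScheme]
#' @export
kineticScheme <- function(k0, k1, k2, k3, kRX, concM,
                          topology = c("full", "accessible-only")) {
  topology <- match.arg(topology)
  if (any(c(k0, k1, k2, k3, kRX, concM) < 0))
    stop("rates and concentration must be >= 0")
  Q <- matrix(0, 5, 5,
              dimnames = list(NULL, c("S1", "S2", "S3", "S4", "S5")))
  kb <- k0 * concM
  if (topology == "full") { Q[1, 2] <- kb; Q[2, 1] <- k1 }
  Q[3, 4] <- kb; Q[4, 3] <- k1
  Q[1, 3] <- k2; Q[3, 1] <- k3
  Q[2, 4] <- k2; Q[4, 2] <- k3
  Q[4, 5] <- kRX
  diag(Q) <- -rowSums(Q)
  new("KineticScheme", k0 = k0, k1 = k1, k2 = k2, k3 = k3, kRX = kRX,
      concM = concM, topology = topology, Q = Q)
}

#' Initial state distribution for the scheme
#'
#' By default the unbound states at conformational equilibrium:
#' `S1 = k3/(k2 + k3)`, `S3 = k2/(k2 + k3)` (exposure starts from a
#' reagent-free bath). With `preEquilibratedInLigand = TRUE`, the full
#' four-state equilibrium in the reagent.
#'
#' @param scheme a [KineticScheme]
#' @param preEquilibratedInLigand logical
#' @return numeric occupancy row of length 5 summing to 1
#' @export
initialDistribution <- function(scheme, preEquilibratedInLigand = FALSE) {
  k2 <- scheme@k2; k3 <- scheme@k3
  if (k2 + k3 == 0) stop("k2 + k3 must be > 0")
  pAcc <- k2 / (k2 + k3)
  if (!preEquilibratedInLigand)
    return(c(1 - pAcc, 0, pAcc, 0, 0))
  kb <- scheme@k0 * scheme@concM
  pB <- if (kb + scheme@k1 > 0) kb / (kb + scheme@k1) else 0
  if (scheme@topology == "accessible-only") {
    ## no bound inaccessible state reachable at equilibrium entry; solve
    ## the 4-state stationary balance of the transient block instead
    p <- c((1 - pAcc) * 1, 0, pAcc * (1 - pB), pAcc * pB, 0)
    return(p / sum(p))
  }
  c((1 - pAcc) * (1 - pB), (1 - pAcc) * pB, pAcc * (1 - pB), pAcc * pB, 0)
}

#' Propagate state occupancies
#'
#' Deterministic propagation `p(t) = p0 %*% expm(Q t)` via the matrix
#' exponential of the 5x5 generator — exact, with no integration
#' tolerance. Probability is conserved to 1e-8 at every grid point.
#'
#' @param scheme a [KineticScheme]
#' @param tGrid time grid (s), non-negative
#' @param p0 initial distribution (defaults to [initialDistribution()])
#' @return an [OccupancyTrajectory]
#' @export
propagate <- function(scheme, tGrid, p0 = initialDistribution(scheme)) {
  if (abs(sum(p0) - 1) > 1e-8 || any(p0 < 0))
    stop("p0 must be a probability distribution over the 5 states")
  tGrid <- sort(unique(as.numeric(tGrid)))
  if (any(tGrid < 0)) stop("time grid must be non-negative")
  Q <- scheme@Q
  occ <- matrix(0, length(tGrid), 5,
                dimnames = list(NULL, colnames(Q)))
  ## step-wise products of matrix exponentials over the grid increments
  p <- p0
  tPrev <- 0
  for (k in seq_along(tGrid)) {
    dtk <- tGrid[k] - tPrev
    if (dtk > 0)
      p <- as.numeric(p %*% as.matrix(Matrix::expm(Q * dtk)))
    p <- pmin(pmax(p, 0), 1)
    p <- p / sum(p)
    occ[k, ] <- p
    tPrev <- tGrid[k]
  }
  new("OccupancyTrajectory", times = tGrid, occupancy = occ,
      scheme = scheme)
}

#' Unmodified channel fraction of a trajectory
#'
#' @param traj an [OccupancyTrajectory]
#' @return numeric vector `1 - P(modified)` along the grid
#' @export
unmodifiedFraction <- function(traj) 1 - traj@occupancy[, 5]

## slowest transient relaxation rate of the scheme (4x4 transient block)
.tauEigen <- function(scheme) {
  A <- scheme@Q[1:4, 1:4]
  ev <- eigen(A, only.values = TRUE)$values
  1 / min(abs(Re(ev)))
}

#' Model time constant of modification
#'
#' Propagates the scheme from the default initial distribution on a
#' grid spanning several relaxation times, fits
#' `A * exp(-t/tau) + c` (all free) to the unmodified fraction, and
#' returns tau. The fit is cross-checked against the spectral estimate
#' `1/|lambda_min|` of the transient sub-generator; the attribute
#' `"tauEigen"` carries that estimate.
#'
#' @param scheme a [KineticScheme] with `kRX > 0` and `concM > 0`
#' @param nGrid number of grid points
#' @param spanTaus grid length in units of the spectral time constant
#' @return fitted tau (s), with attribute `tauEigen`
#' @export
modelTau <- function(scheme, nGrid = 400, spanTaus = 8) {
  if (scheme@kRX <= 0 || scheme@concM <= 0)
    stop("modelTau requires kRX > 0 and concM > 0")
  tauE <- .tauEigen(scheme)
  tg <- seq(0, spanTaus * tauE, length.out = nGrid)
  u <- unmodifiedFraction(propagate(scheme, tg))
  fit <- try(minpack.lm::nlsLM(
    u ~ A * exp(-tg / tau) + c0,
    start = list(A = 1, tau = tauE, c0 = 0),
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("mono-exponential fit to the model course failed ",
         "(spectral estimate: ", signif(tauE, 6), " s)")
  tau <- stats::coef(fit)[["tau"]]
  attr(tau, "tauEigen") <- tauE
  tau
}

#' Time-constant fold changes across reagent concentrations
#'
#' Recomputes the fitted model time constant at each concentration and
#' reports the fold change relative to a reference concentration.
#'
#' @param scheme a [KineticScheme]; its rates are reused, only the
#'   concentration varies
#' @param conc_M concentrations to evaluate (mol/L)
#' @param referenceConcM reference (default 0.01 M, i.e. 10 mM)
#' @return data.frame with columns `conc_M`, `tau_s`, `fold`
#' @export
tauFoldChangeTable <- function(scheme, conc_M, referenceConcM = 1e-2) {
  all_c <- unique(c(referenceConcM, conc_M))
  taus <- vapply(all_c, function(cc) {
    as.numeric(modelTau(kineticScheme(scheme@k0, scheme@k1, scheme@k2,
                                      scheme@k3, scheme@kRX, cc,
                                      scheme@topology)))
  }, numeric(1))
  ref <- taus[match(referenceConcM, all_c)]
  idx <- match(conc_M, all_c)
  data.frame(conc_M = conc_M, tau_s = taus[idx], fold = taus[idx] / ref)
}

#' Stochastic (Gillespie) oracle for the scheme
#'
#' Exact stochastic simulation of `nChannels` independent channels from
#' the initial distribution; returns the empirical unmodified fraction
#' over a time grid. Serves as an independent cross-check of
#' [propagate()].
#'
#' @param scheme a [KineticScheme]
#' @param nChannels number of channels (>= 1)
#' @param tEnd simulation end time (s)
#' @param seed RNG seed
#' @param tGrid optional evaluation grid (default: 201 points to `tEnd`)
#' @param p0 initial distribution
#' @return list with `times` and empirical `unmodified` fraction
#' @export
gillespieOracle <- function(scheme, nChannels, tEnd, seed = 1,
                            tGrid = NULL,
                            p0 = initialDistribution(scheme)) {
  stopifnot(nChannels >= 1)
  if (is.null(tGrid)) tGrid <- seq(0, tEnd, length.out = 201)
  absTimes <- .withSeed(seed,
    gillespie_absorption_times(scheme@Q, p0, as.integer(nChannels), tEnd))
  unmod <- vapply(tGrid, function(t) mean(absTimes > t), numeric(1))
  list(times = tGrid, unmodified = unmod)
}

#' Acid-base speciation of an MTS reagent
#'
#' Henderson-Hasselbalch partition of a weak base between its
#' protonated (cationic) and neutral forms:
#' `cation = total * [H+] / (Ka + [H+])`, `neutral = total - cation`.
#'
#' @param totalM total reagent concentration (mol/L)
#' @param pH solution pH
#' @param pKa reagent pKa (default 8.5, the MTSEA value)
#' @return a [Speciation]
#' @export
mtsSpeciation <- function(totalM, pH, pKa = 8.5) {
  if (totalM < 0) stop("total concentration must be >= 0")
  H <- 10^(-pH)
  Ka <- 10^(-pKa)
  cation <- totalM * H / (Ka + H)
  new("Speciation", totalM = totalM, pH = pH, pKa = pKa,
      cationM = cation, neutralM = totalM - cation)
}
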