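---
title: "Quantifying state-dependent pore accessibility from patch-clamp sweeps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying state-dependent pore accessibility from patch-clamp sweeps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreSCAM)
```

## The measurement and its logic

A cysteine substituted at a pore-lining position below an ion
channel's selectivity filter reacts nearly irreversibly with
thiol-reactive probes (Ag⁺, MTSEA, MTSET) applied from the
extracellular side. Each reaction event silences one channel, so the
leak-subtracted steady-state agonist current decays sweep by sweep as
exposures accumulate. The decay time constant τ, converted to a
bimolecular rate `k = (1/τ)/[X]free`, measures how fast the probe
reaches the engineered site. Comparing `k` between experiments in
which the probe is applied with the agonist (channels mostly open) and
without it (channels mostly closed) asks directly whether the filter
gates access: a filter that closes over the permeation pathway should
suppress the closed-state rate by at least the fold-change in open
probability, while similar rates in both states mean the filter is not
an activation gate.

`poreSCAM` implements this analysis and its supporting measurements as
composable functions over an S4 data model (`SweepRecord`/`SweepSet`
for annotated traces, `TimeCourse` for per-sweep summaries, fit
classes for each estimator). This vignette records the assumptions,
parameter choices and numerical decisions behind each stage.

## Time courses, leak subtraction, and normalization

Each sweep is annotated with solution epochs. The steady-state read of
an epoch is the mean over its trailing quarter
(`windowFraction = 0.25`); the averaging window is a package choice —
one long enough to suppress noise but safely inside the plateau of the
agonist response. An epoch owns samples in `[start, end)`, so the
boundary sample belongs to the next solution.

Leak is removed per sweep by subtracting the no-agonist control read
taken immediately before agonist application
(`leakSubtract()`), which tracks slow leak drift. The time course is
normalized at the steady-state read of the first exposure sweep: that
read is taken before the exposure within the sweep, so it is the last
measurement unaffected by the reagent, and it is assigned t = 0.
Pre-exposure sweeps carry negative experiment time, zero cumulative
exposure, and normalized currents above 1 when rundown is present.
Cumulative exposure time sums the protocol-declared reagent epoch
durations; solution exchange in these protocols is machine-timed, so
nominal durations are the appropriate clock.

## Rundown and its two corrections

Repeated activation causes a slow, modification-independent current
decline ("rundown") that is well described by
`(1 − c)·exp(−t/τ_r) + c`. Three regimes are supported, mirroring how
such experiments are actually analyzed:

* **No correction** — when exposures are chosen so that modification
  is much faster than rundown, quantified by the six reagent-free
  presweeps. `qcRundownExclusion()` discards cells losing more than
  50% of their current over those presweeps (strictly more: exactly
  half keeps the cell).
* **Divide-out** (`fitRundown()` + `correctRundownDivide()`) — fit the
  rundown curve to matched reagent-free experiments and divide the
  t ≥ 0 portion of the modification course by it. Because the fitted
  form equals 1 at t = 0, it is consistent with the t = 0
  normalization above; rows at t < 0 are left untouched.
* **Alternating protocol** (`correctRundownAlternating()`) — sweeps
  alternate unexposed/exposed while everything else is identical. The
  fractional drop between adjacent sweeps, `F_j = (I_j − I_{j+1})/I_j`,
  then alternately reflects rundown alone or rundown plus
  modification, and the corrected course adds the rundown step back:
  `I_{j+1} = I_j − I_j·F_{2j+1} + I_j·F_{2j}` (0-based j). The
  companion recursions isolate the rundown-only and reagent-only
  courses. The exposure acting during sweep j manifests in the read of
  sweep j + 1, because the read precedes the exposure within a sweep;
  the implementation follows that bookkeeping and requires the block
  to start with an unexposed sweep.

## Exponential fitting and rates

`fitMonoexponential()` fits `A·exp(−t/τ) + c` on cumulative exposure
time by Levenberg–Marquardt (`minpack.lm::nls.lm`), with all three
parameters free by default, or with A and c fixed at 0.9 and 0.1 for
slow reagents whose decay is not followed to completion. The τ start
value comes from the log-linear slope of the decaying part (falling
back to span/3), with bounds `(0, 100 × span]`; a course with no
detectable decay returns `tauS = Inf` flagged unconverged rather than
a spurious finite constant. Rates are `modificationRate(fit, conc) =
(1/τ)/conc`, e.g. τ = 0.611 s at 50 nM gives 3.27×10⁷ M⁻¹s⁻¹.

The verdict (`stateDependenceVerdict()`) compares `k_open/k_closed`
with the agonist-induced P_o fold-change estimated as
`|I_agonist/I_control|` — a deliberate lower bound, since leak
dominates the control current. The decision thresholds (rate ratio
below 0.1 × the P_o fold-change → "filter-not-gate"; within 5% of it →
"gate-consistent"; otherwise "indeterminate") are package choices,
always reported in the result object. Per-cell rate comparisons use
Welch's heteroscedastic two-tailed t-test.

## Block and noise analyses

Reversible block is quantified as
`F = 1 − (I_Ag − I_ctrl)/(I_0 − I_ctrl)` (unclipped; affine-invariant
in the three currents). Dose-response curves are fit with the Hill
equation with the coefficient fixed at 1 by default and base/max free,
since neither leak nor the unblocked maximum is perfectly constrained;
the midpoint is parameterized as log K for positivity across the
nM–pM range. Voltage dependence follows the Woodhull model
`K_D(V) = K_D(0)·exp(−Zδ·VF/RT)` fitted on log K_D (multiplicative
errors), with T = 295.15 K (22 °C, RT/F ≈ 25.44 mV) by default.
Reversal potentials come from a quadratic fit to I–V points within
±20 mV (root nearest 0 mV); conductances `G = I/(V − V_rev)` exclude
that window, where the small driving force makes G unstable.

Stationary noise analysis uses the unbiased (M − 1) pointwise ensemble
variance, trailing-window steady-state summaries, and a linear
least-squares fit of `σ² = Ī·i − Ī²/N` in the `(i, 1/N)`
parameterization, which is well conditioned in the near-linear low-P_o
regime. Baseline-variance subtraction is off by default (an explicit
`baselineVar` argument enables it). P_o values outside [−0.05, 1.05]
are flagged, never clipped.

## The five-state modification model

`kineticScheme()` builds the continuous-time Markov model used to
interpret concentration series: states inaccessible/accessible ×
unbound/bound plus an absorbing modified state; binding at `k0·[X]`
and unbinding at `k1` in both conformations, conformational exchange
at `k2` (to accessible) and `k3` (back) in both liganded branches, and
modification at `kRX` from the accessible-bound state only. With
identical constants on parallel edges the four-state cycle satisfies
detailed balance by construction. The drawn topology does not fully
constrain whether the inaccessible conformation can bind the reagent;
binding in both conformations is the minimal symmetric closure and the
default, with `topology = "accessible-only"` available for the
alternative.

Propagation is by matrix exponential of the 5×5 generator — exact, no
integration tolerances — with probability conservation enforced at
1e-8. The default initial condition is the unbound conformational
equilibrium `S1 = k3/(k2+k3)`, `S3 = k2/(k2+k3)` (exposures start from
a reagent-free bath); full pre-equilibration in ligand is available.
`modelTau()` fits a free mono-exponential to the unmodified fraction
on a 400-point grid spanning 8 spectral time constants (the spectral
estimate `1/|λ_min|` of the transient sub-generator is returned as an
attribute and agrees with the fit within 5% in the rate-limiting
regime). `gillespieOracle()` is an exact stochastic simulator
(compiled, using R's RNG for reproducibility) kept purely as an
independent cross-check of the deterministic propagation.

With the reference parameters (k0 = 0.5×10⁵ M⁻¹s⁻¹, k1 = 50 s⁻¹,
k2 = 0.06 s⁻¹, k3 = 10 s⁻¹, kRX = 500 s⁻¹), diluting the reagent
100-, 1000- or 10000-fold from 10 mM increases τ far less than
proportionally (≈2.7-, 19-, 184-fold; `scripts/acceptance.R`
recomputes these), while a 10-fold increase of k2 — the modeled effect
of agonist — decreases τ almost exactly 10-fold. This asymmetry is the
model's diagnostic signature: access, not bulk concentration, is rate
limiting at high reagent. `mtsSpeciation()` supplies the
Henderson–Hasselbalch partition (MTSEA pKa 8.5) needed to express
concentrations as the reactive cationic species.

## The synthetic-experiment generator

`simulateExperiment()` generates sweep bundles from
`I(t) = leak(t) + u·r·b·N·P_o·i + ε`, with `u` the unmodified fraction
(`du/dt = −k_state·[X]·u` during exposures, `k_state` selected by
agonist presence), `r` the rundown factor on cumulative agonist-on
time, `b` the equilibrium unblocked fraction during reversible Ag⁺
epochs, and ε white Gaussian noise. Defaults emulate a whole-cell
recording at −60 mV: 1000 channels of −3 pA, P_o from 0.005 to 0.9
with Hill K_half 0.25 mM and coefficient 2 for the agonist, −20 pA
leak, rundown plateau 0.045 with τ_r 84.57 s, block K_D(0) 5.2 nM with
Zδ −0.89, and modification rate constants 2.94×10⁷ (open) and
1.16×10⁷ M⁻¹s⁻¹ (closed); protocols default to six presweeps plus six
exposure sweeps (1 s exposures open, 2 s closed) at 50 nM free Ag⁺,
one sweep per 15 s, sampled at 100 Hz. The rundown clock advances only
during agonist application by default (rundown follows activation
cycles), with a wall-clock option.

What the generator does *not* emulate bounds what passing tests show
about real data: noise is white Gaussian rather than the 1/f-plus-shot
mixture of real patches; single-channel gating appears only as
binomial snapshots in noise ensembles (no correlated open/closed
kinetics within a sweep); block is instantaneous-equilibrium; solution
exchange is ideal step-shaped; and series-resistance and capacitance
artifacts are absent. Recovery benchmarks on these synthetic data
validate the estimators' correctness, not their robustness to every
pathology of a rig.

## Numerical choices and problem sizes

Nonlinear fits use Levenberg–Marquardt throughout; linear
sub-problems (Woodhull, variance–mean, reversal potential) use
ordinary least squares. Degenerate inputs error loudly (zero
denominators, missing pre-exposure sweeps, non-alternating flags)
rather than returning silently clipped values. Sweep bundles serialize
numbers at 17 significant digits, so write → read round-trips are
bit-exact and re-serialization is byte-identical.

The test suite validates recovery at the scale of the real
experiments: modification-rate recovery over truth rates
{10⁶, 10⁷, 3×10⁷} M⁻¹s⁻¹ at 50 nM with 2% signal noise (20 seeds
each, median error < 15%); Woodhull recovery from 100 noisy
dose-response families; noise-analysis recovery from 50 × 8000-sample
binomial ensembles across a P_o grid (i and N within 10%); and
deterministic-vs-stochastic agreement of the kinetic model at 10⁵
channels within three binomial standard errors pointwise. Exposure
durations in the rate-recovery benchmarks scale inversely with the
truth rate (0.5–8 s), as an experimenter would choose them so that
modification dominates rundown over the recorded sweeps.

## Limitations

Mono-exponential fitting assumes a single dominant modification
pathway; multi-exponential courses (mixed populations, partial block)
are out of scope. The kinetic model is forward-only — it predicts τ
from assumed rate constants but does not fit them to data. The P_o
fold-change is a lower bound, so "gate-consistent" outcomes near the
boundary are conservative. Block analysis assumes equilibrium
occupancy within each sweep and a single binding site; saturation of
voltage dependence at negative potentials is deliberately not
modeled.
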