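Package: poreSCAM
Title: State-Dependent Cysteine Accessibility and Pore-Block Analysis for
    Ion-Channel Patch-Clamp Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying state-dependent accessibility of
    engineered cysteines in ion-channel pores from whole-cell patch-clamp
    sweep sets (substituted-cysteine accessibility method, SCAM).
    Implements modification time-course construction with leak subtraction
    and two rundown-correction algorithms, mono-exponential rate fitting
    and conversion to bimolecular modification rates, Woodhull analysis of
    voltage-dependent pore block, Hill dose-response fitting,
    conductance-voltage curves with polynomial reversal-potential
    estimation, stationary noise analysis (variance-mean parabola) for
    single-channel current and channel count, a five-state continuous-time
    Markov model of reagent binding and irreversible modification with a
    stochastic (Gillespie) oracle, Henderson-Hasselbalch speciation of
    thiol-reactive reagents, and a synthetic-experiment generator with
    known ground truth so every analysis stage is testable without
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    minpack.lm,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
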