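# shared fixtures and independent closed forms used as oracles

FARADAY <- 96485.33212
RGAS <- 8.31446262

woodhullKD <- function(V_mV, KD0, Zdelta, tempK = 295.15)
  KD0 * exp(-Zdelta * (V_mV / 1000) * FARADAY / (RGAS * tempK))

hillF <- function(conc, base, maxF, K, s) base + (maxF - base) / (1 + (K / conc)^s)

.hillPoOracle <- function(tr, conc)
  tr@poBase + (tr@poMax - tr@poBase) / (1 + (tr@poKHalfM / conc)^tr@poHill)

# a minimal two-epoch sweep with an analytic current
makeSweep <- function(index = 0, f = function(t) rep(-100, length(t)),
                      dur = 10, rate = 100,
                      labels = c("pre", "agonist"),
                      voltage = -60) {
  t <- seq(0, dur, by = 1 / rate)
  bnd <- seq(0, dur, length.out = length(labels) + 1)
  ep <- solutionEpochs(bnd[-length(bnd)], bnd[-1], labels,
                       agonist_id = ifelse(labels == "agonist", "2APB",
                                           NA_character_),
                       agonist_conc_M = ifelse(labels == "agonist", 3e-3, 0),
                       voltage_mV = voltage)
  sweepRecord(index, t, f(t), ep, rate)
}

# reference parameters of the five-state modification scheme
schemeNoAgonist <- function(concM) kineticScheme(0.5e5, 50, 0.06, 10, 500, concM)
schemeWithAgonist <- function(concM) kineticScheme(0.5e5, 50, 0.6, 10, 500, concM)
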