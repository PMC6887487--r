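#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation of independent channels on a small
// continuous-time Markov chain with one absorbing state (the last).
// Returns, per channel, the time of absorption (capped at tEnd + 1 when
// the channel is not absorbed within the horizon). Uses R's RNG so that
// set.seed() on the R side makes runs reproducible.
// [[Rcpp::export]]
NumericVector gillespie_absorption_times(NumericMatrix Q,
                                         NumericVector p0,
                                         int nChannels,
                                         double tEnd) {
  const int ns = Q.nrow();
  const int absorbing = ns - 1;

  // per-state exit rate and cumulative jump distribution
  std::vector<double> exitRate(ns);
  std::vector< std::vector<double> > cumProb(ns, std::vector<double>(ns));
  for (int s = 0; s < ns; ++s) {
    double tot = 0.0;
    for (int k = 0; k < ns; ++k)
      if (k != s) tot += Q(s, k);
    exitRate[s] = tot;
    double acc = 0.0;
    for (int k = 0; k < ns; ++k) {
      if (k != s && tot > 0) acc += Q(s, k) / tot;
      cumProb[s][k] = acc;
    }
  }
  std::vector<double> cumP0(ns);
  double acc0 = 0.0;
  for (int s = 0; s < ns; ++s) { acc0 += p0[s]; cumP0[s] = acc0; }

  NumericVector out(nChannels);
  RNGScope scope;
  for (int ch = 0; ch < nChannels; ++ch) {
    double u = unif_rand();
    int state = 0;
    while (state < ns - 1 && u > cumP0[state]) ++state;
    double t = 0.0;
    while (state != absorbing) {
      if (exitRate[state] <= 0.0) { t = tEnd + 1.0; break; }
      t += exp_rand() / exitRate[state];
      if (t > tEnd) { t = tEnd + 1.0; break; }
      double v = unif_rand();
      int nxt = 0;
      while (nxt < ns - 1 && v > cumProb[state][nxt]) ++nxt;
      state = nxt;
    }
    out[ch] = (state == absorbing) ? t : tEnd + 1.0;
  }
  return out;
}
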