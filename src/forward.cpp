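#include <Rcpp.h>
using namespace Rcpp;

// Forward-algorithm log-likelihoods for multievent encounter histories over
// the four-state space {N, L, H, D}.
//
// events : n x T integer event codes (0 = not captured); entries before the
//          first capture are ignored.
// first  : 1-based occasion of first capture per history.
// strat  : n x T 1-based stratum index at each occasion. The transition from
//          occasion t to t+1 uses the stratum at the departure occasion t;
//          the event at t+1 uses the stratum at t+1 (strata only differ over
//          time for age-structured models, where the class advances).
// M      : list of S combined 4x4 matrices, survival %*% state transition.
// B      : list of S 4 x E event (emission) matrices.
// B0     : list of S first-capture assignment matrices: as B but with the
//          capture probability conditioned out (entry is conditional on
//          capture, so p does not appear at the first occasion).
// init   : length-4 initial state distribution (1-pi, pi/2, pi/2, 0).
//
// Each history is scaled at every step; returns per-history log-likelihoods.
// [[Rcpp::export]]
NumericVector cmr_forward_loglik(IntegerMatrix events, IntegerVector first,
                                 IntegerMatrix strat, List M, List B, List B0,
                                 NumericVector init) {
  const int n = events.nrow(), T = events.ncol(), S = M.size();
  std::vector<NumericMatrix> Ms, Bs, B0s;
  Ms.reserve(S); Bs.reserve(S); B0s.reserve(S);
  for (int s = 0; s < S; ++s) {
    Ms.push_back(as<NumericMatrix>(M[s]));
    Bs.push_back(as<NumericMatrix>(B[s]));
    B0s.push_back(as<NumericMatrix>(B0[s]));
  }
  NumericVector out(n);
  double a[4], anew[4];
  for (int i = 0; i < n; ++i) {
    const int t0 = first[i] - 1;
    const int e0 = events(i, t0);
    const NumericMatrix &b0 = B0s[strat(i, t0) - 1];
    double tot = 0.0;
    for (int s = 0; s < 4; ++s) { a[s] = init[s] * b0(s, e0); tot += a[s]; }
    if (tot <= 0.0) { out[i] = R_NegInf; continue; }
    double ll = std::log(tot);
    for (int s = 0; s < 4; ++s) a[s] /= tot;
    bool dead_end = false;
    for (int t = t0 + 1; t < T; ++t) {
      const NumericMatrix &m = Ms[strat(i, t - 1) - 1];
      const NumericMatrix &b = Bs[strat(i, t) - 1];
      const int e = events(i, t);
      tot = 0.0;
      for (int s2 = 0; s2 < 4; ++s2) {
        double v = 0.0;
        for (int s1 = 0; s1 < 4; ++s1) v += a[s1] * m(s1, s2);
        v *= b(s2, e);
        anew[s2] = v;
        tot += v;
      }
      if (tot <= 0.0) { dead_end = true; break; }
      ll += std::log(tot);
      for (int s = 0; s < 4; ++s) a[s] = anew[s] / tot;
    }
    out[i] = dead_end ? R_NegInf : ll;
  }
  return out;
}
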