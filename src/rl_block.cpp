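#include <Rcpp.h>
using namespace Rcpp;

// Delta-rule / softmax pass over a block of trials on one state-space.
// states: 1-based state index per trial; action: 1 = go, 2 = pass,
// 0 = missed (skipped entirely). Choice probabilities come from the
// pre-update values with max-subtraction; the improbable action's
// probability is computed from its own exponential so it never collapses
// to zero by cancellation. Returns per-trial series, the final value
// table and (optionally) the pre-update table trajectory.
// [[Rcpp::export]]
List rl_block(IntegerVector states, IntegerVector action,
              NumericVector reward, NumericMatrix q_init,
              double alpha, double beta, bool traj) {
  const int n = states.size();
  const int S = q_init.nrow();
  NumericMatrix q = clone(q_init);
  NumericVector p_go(n, NA_REAL), p_action(n, NA_REAL);
  NumericVector q_chosen(n, NA_REAL), rpe(n, NA_REAL);
  NumericVector qt;
  if (traj) {
    qt = NumericVector(Dimension(n, S, 2));
    std::fill(qt.begin(), qt.end(), NA_REAL);
  }
  for (int t = 0; t < n; ++t) {
    if (traj) {
      for (int s = 0; s < S; ++s) {
        qt[t + n * s] = q(s, 0);
        qt[t + n * s + n * S] = q(s, 1);
      }
    }
    const int a = action[t];
    if (a == 0) continue;
    const int s = states[t] - 1;
    const double zg = beta * q(s, 0), zp = beta * q(s, 1);
    const double m = zg > zp ? zg : zp;
    const double eg = std::exp(zg - m), ep = std::exp(zp - m);
    const double tot = eg + ep;
    p_go[t] = eg / tot;
    const int ai = a - 1;
    p_action[t] = (ai == 0 ? eg : ep) / tot;
    q_chosen[t] = q(s, ai);
    rpe[t] = reward[t] - q(s, ai);
    q(s, ai) += alpha * (reward[t] - q(s, ai));
  }
  return List::create(_["p_go"] = p_go, _["p_action"] = p_action,
                      _["q_chosen"] = q_chosen, _["rpe"] = rpe,
                      _["q"] = q, _["q_traj"] = qt);
}
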