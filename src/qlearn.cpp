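#include <Rcpp.h>
using namespace Rcpp;

// Pointwise log-likelihood of one time-ordered training sequence under the
// asymmetric Q-learning model with a softmax (logistic) choice rule.
//
// a_idx / b_idx are 1-based indices of the two faces shown, chose_a is 1 if
// face_a was chosen, outcome is 1 (happy) / 0 (angry). Expected values start
// at q0 and only the chosen face is updated, with alpha_reward applied to
// positive prediction errors and alpha_punish to negative ones. A zero
// prediction error (reachable only at q exactly 0 or 1) takes alpha_reward
// for a happy outcome and alpha_punish for an angry one.
// [[Rcpp::export]]
NumericVector qlearn_loglik_cpp(IntegerVector a_idx, IntegerVector b_idx,
                                IntegerVector chose_a, IntegerVector outcome,
                                double alpha_reward, double alpha_punish,
                                double beta, NumericVector q0) {
  int n = a_idx.size();
  NumericVector q = clone(q0);
  NumericVector ll(n);
  for (int t = 0; t < n; ++t) {
    int a = a_idx[t] - 1, b = b_idx[t] - 1;
    double x = beta * (q[a] - q[b]);
    ll[t] = chose_a[t] ? -R::log1pexp(-x) : -R::log1pexp(x);
    int c = chose_a[t] ? a : b;
    double pe = (double)outcome[t] - q[c];
    double alpha;
    if (pe > 0.0)      alpha = alpha_reward;
    else if (pe < 0.0) alpha = alpha_punish;
    else               alpha = outcome[t] == 1 ? alpha_reward : alpha_punish;
    q[c] += alpha * pe;
  }
  return ll;
}
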