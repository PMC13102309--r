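#include <Rcpp.h>
using namespace Rcpp;

// Overflow-safe two-option softmax: probability of option 1.
static inline double softmax_p1(double q1, double q2, double beta) {
  double x1 = beta * q1, x2 = beta * q2;
  double m = x1 > x2 ? x1 : x2;
  double e1 = std::exp(x1 - m), e2 = std::exp(x2 - m);
  return e1 / (e1 + e2);
}

// Replay a Q-learning model over an observed action/reward sequence and
// return the predictive choice probabilities at each trial (values entering
// the trial, i.e. before the trial's own outcome is learned).
// alpha_pos == alpha_neg and alpha_u == 0 gives the two-parameter model.
// Ties (delta == 0) take the positive-error learning rate.
// [[Rcpp::export]]
List mf_replay_cpp(IntegerVector action, NumericVector reward,
                   double alpha_pos, double alpha_neg, double alpha_u,
                   double beta, double q0) {
  int n = action.size();
  NumericVector p1(n), pch(n);
  double q[3] = {0.0, q0, q0};
  for (int t = 0; t < n; ++t) {
    double p = softmax_p1(q[1], q[2], beta);
    p1[t] = p;
    int a = action[t];
    pch[t] = (a == 1) ? p : 1.0 - p;
    double delta = reward[t] - q[a];
    double al = (delta >= 0.0) ? alpha_pos : alpha_neg;
    q[a] += al * delta;
    q[3 - a] += alpha_u * delta;
  }
  return List::create(_["p1"] = p1, _["p_chosen"] = pch);
}

// Simulate one autonomous episode of a Q-learning agent on a fixed
// better-option schedule. Uses R's RNG so results follow set.seed().
// [[Rcpp::export]]
List mf_episode_cpp(IntegerVector better, double alpha_pos, double alpha_neg,
                    double alpha_u, double beta, double q0,
                    double mean_high, double mean_low, double reward_sd) {
  int n = better.size();
  IntegerVector action(n);
  NumericVector reward(n), pch(n);
  double q[3] = {0.0, q0, q0};
  for (int t = 0; t < n; ++t) {
    double p = softmax_p1(q[1], q[2], beta);
    int a = (unif_rand() < p) ? 1 : 2;
    action[t] = a;
    pch[t] = (a == 1) ? p : 1.0 - p;
    double mu = (a == better[t]) ? mean_high : mean_low;
    double r = ::Rf_rnorm(mu, reward_sd);
    reward[t] = r;
    double delta = r - q[a];
    double al = (delta >= 0.0) ? alpha_pos : alpha_neg;
    q[a] += al * delta;
    q[3 - a] += alpha_u * delta;
  }
  return List::create(_["action"] = action, _["reward"] = reward,
                      _["p_chosen"] = pch);
}
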