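#include <Rcpp.h>
using namespace Rcpp;

// One-episode rollout of the notification environment and (optionally) the
// softmax policy. All randomness enters through the pre-drawn uniform
// vectors, so the rollout is a deterministic function of its inputs and
// matches the step-by-step R implementation exactly.
//
// mode: 0 = agent-side clipping (R), 1 = environment-side suppression (C),
//       2 = unrestricted (B before its switch).
//
// [[Rcpp::export]]
List rollout_episode_cpp(NumericMatrix W1, NumericVector b1,
                         NumericMatrix W2, NumericVector b2,
                         NumericMatrix S, NumericVector ratio,
                         IntegerVector gaps,
                         NumericVector u_env, NumericVector u_agent,
                         IntegerVector schedule,
                         double sigma, double mu, double m0, double u0,
                         int hsr0, int budget, double reward_per_run,
                         int mode) {
  const int n = S.nrow(), d_static = S.ncol();
  const int d = d_static + 2;
  const int h = W1.nrow();
  const bool use_policy = schedule.size() == 0;

  NumericMatrix X(n, d);
  IntegerVector actions(n), forced(n), notif(n), runs(n);
  NumericVector rewards(n), mem(n), urge(n);

  double m = m0, u = u0;
  int last_action = 0, hsr = hsr0, sends = 0, used = 0;
  std::vector<double> hid(h);

  for (int t = 0; t < n; ++t) {
    if (t > 0) {
      for (int k = 0; k < gaps[t]; ++k) {
        m *= sigma;
        u = last_action ? 0.0 : std::min(1.0, u + mu);
        last_action = 0;
        hsr += 1;
      }
    }
    const double bud_norm =
        std::max(0, budget - used) / (double)std::max(1, budget);
    const double rec_norm = std::min(hsr, 72) / 72.0;
    for (int j = 0; j < d_static; ++j) X(t, j) = S(t, j);
    X(t, d_static) = bud_norm;
    X(t, d_static + 1) = rec_norm;

    int a;
    if (use_policy) {
      if (mode == 0 && sends >= budget) {
        a = 0;
        forced[t] = 1;
      } else {
        for (int i = 0; i < h; ++i) {
          double z = b1[i];
          for (int j = 0; j < d; ++j) z += W1(i, j) * X(t, j);
          hid[i] = std::tanh(z);
        }
        double l0 = b2[0], l1 = b2[1];
        for (int i = 0; i < h; ++i) {
          l0 += W2(0, i) * hid[i];
          l1 += W2(1, i) * hid[i];
        }
        const double p_send = 1.0 / (1.0 + std::exp(l0 - l1));
        a = (u_agent[t] < p_send) ? 1 : 0;
      }
    } else {
      a = schedule[t];
    }
    actions[t] = a;
    sends += a;

    int delivered = a;
    if (mode == 1 && used >= budget) delivered = 0;
    used += delivered;
    notif[t] = delivered;

    m = delivered ? 1.0 : sigma * m;
    u = last_action ? 0.0 : std::min(1.0, u + mu);
    const double p = std::min(1.0, ratio[t] * u * m);
    const int run = (u_env[t] < p) ? 1 : 0;
    rewards[t] = run * reward_per_run;
    runs[t] = run;
    mem[t] = m;
    urge[t] = u;
    last_action = run;
    hsr = run ? 0 : hsr + 1;
  }

  return List::create(_["X"] = X, _["actions"] = actions,
                      _["forced"] = forced, _["rewards"] = rewards,
                      _["notifications"] = notif, _["runs"] = runs,
                      _["memory"] = mem, _["urge"] = urge,
                      _["delivered"] = used);
}
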