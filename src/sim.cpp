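#include <Rcpp.h>
using namespace Rcpp;

// Fast agent-through-task simulator. Consumes R's uniform stream in
// exactly the same order as the R reference path (run_session with
// make_agent_policy): per trial one uniform for the choice, one for
// the win draw, and one for the credit draw when the trial wins. The
// two paths therefore produce identical sessions for the same seed,
// which the test suite asserts.

// [[Rcpp::export]]
List sim_agent_cpp(NumericVector p_t, NumericVector p_nt,
                   IntegerVector target, IntegerVector criterion,
                   IntegerVector max_trials, List win_credits,
                   List win_probs, bool advance, int model,
                   NumericVector params, bool fictive, int coding,
                   NumericVector mean_credit) {
  int S = p_t.size();
  int cap = 0;
  for (int k = 0; k < S; ++k) cap += max_trials[k];
  IntegerVector stage_idx(cap), t_in(cap), choice(cap);
  LogicalVector correct(cap), win(cap);
  NumericVector credits(cap);
  std::vector<int> completion;
  completion.reserve(S);
  double v0 = 0, v1 = 0, n0 = 0, n1 = 0;
  double phi = params[0], rho = params[1], beta = params[2];
  double a_rew = params[0], a_pun = params[1];
  int n = 0;
  for (int k = 0; k < S; ++k) {
    NumericVector wc = win_credits[k], wp = win_probs[k];
    int K = wc.size();
    int run = 0;
    bool done = false;
    for (int t = 1; t <= max_trials[k]; ++t) {
      // softmax choice, matching choice_probabilities() bit for bit
      double x0 = beta * v0, x1 = beta * v1, p1;
      if (x1 >= x0) {
        p1 = 1.0 / (exp(x0 - x1) + 1.0);
      } else {
        double e = exp(x1 - x0);
        p1 = e / (e + 1.0);
      }
      int ch = (unif_rand() < p1) ? 1 : 0;
      bool ok = (ch == target[k]);
      double p = ok ? p_t[k] : p_nt[k];
      bool w = (unif_rand() < p);
      double cr = 0.0;
      if (w) {
        double u = unif_rand();
        double cum = 0.0;
        int idx = 0;
        for (int j = 0; j < K - 1; ++j) {
          cum += wp[j];
          if (cum <= u) ++idx;
        }
        cr = wc[idx];
      }
      run = ok ? run + 1 : 0;
      stage_idx[n] = k + 1;
      t_in[n] = t;
      choice[n] = ch;
      correct[n] = ok;
      credits[n] = cr;
      win[n] = w;
      ++n;
      // model update for the next trial
      double payoff = w ? (coding == 0 ? 1.0 : cr / mean_credit[k]) : -1.0;
      if (model == 0) {
        if (ch == 1) {
          double nn = rho * n1 + 1.0;
          v1 = (phi * n1 * v1 + payoff) / nn;
          n1 = nn;
        } else {
          double nn = rho * n0 + 1.0;
          v0 = (phi * n0 * v0 + payoff) / nn;
          n0 = nn;
        }
      } else {
        double vc = (ch == 1) ? v1 : v0;
        double vu = (ch == 1) ? v0 : v1;
        if (payoff >= 0) {
          vc += a_rew * (payoff - vc);
          if (fictive) vu += a_pun * (-payoff - vu);
        } else {
          vc += a_pun * (payoff - vc);
          if (fictive) vu += a_rew * (-payoff - vu);
        }
        if (ch == 1) { v1 = vc; v0 = vu; } else { v0 = vc; v1 = vu; }
      }
      if (run >= criterion[k]) { done = true; break; }
    }
    completion.push_back(done ? 1 : 0);
    if (!done && !advance) break;
  }
  Range idx(0, n - 1);
  return List::create(
    _["stage_index"] = stage_idx[idx], _["trial_in_stage"] = t_in[idx],
    _["choice"] = choice[idx], _["correct"] = correct[idx],
    _["credits"] = credits[idx], _["win"] = win[idx],
    _["completion"] = wrap(completion));
}
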