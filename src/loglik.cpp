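#include <Rcpp.h>
using namespace Rcpp;

// Sequential per-trial likelihood recursions. Choices are 0/1 option
// indices; payoffs are already coded (sign or magnitude) by the caller.

// [[Rcpp::export]]
double ll_ewa_cpp(IntegerVector choice, NumericVector payoff,
                  double phi, double rho, double beta) {
  int n = choice.size();
  double A0 = 0.0, A1 = 0.0, n0 = 0.0, n1 = 0.0, ll = 0.0;
  for (int t = 0; t < n; ++t) {
    double d = beta * (A1 - A0);
    // log softmax, stable for large |d|
    ll += (choice[t] == 1) ? -R::log1pexp(-d) : -R::log1pexp(d);
    if (choice[t] == 1) {
      double nn = rho * n1 + 1.0;
      A1 = (phi * n1 * A1 + payoff[t]) / nn;
      n1 = nn;
    } else {
      double nn = rho * n0 + 1.0;
      A0 = (phi * n0 * A0 + payoff[t]) / nn;
      n0 = nn;
    }
  }
  return ll;
}

// [[Rcpp::export]]
double ll_rp_cpp(IntegerVector choice, NumericVector payoff,
                 double a_rew, double a_pun, double beta, bool fictive) {
  int n = choice.size();
  double v0 = 0.0, v1 = 0.0, ll = 0.0;
  for (int t = 0; t < n; ++t) {
    double d = beta * (v1 - v0);
    ll += (choice[t] == 1) ? -R::log1pexp(-d) : -R::log1pexp(d);
    double out = payoff[t];
    double vc = (choice[t] == 1) ? v1 : v0;
    double vu = (choice[t] == 1) ? v0 : v1;
    if (out >= 0) {
      vc += a_rew * (out - vc);
      if (fictive) vu += a_pun * (-out - vu);
    } else {
      vc += a_pun * (out - vc);
      if (fictive) vu += a_rew * (-out - vu);
    }
    if (choice[t] == 1) { v1 = vc; v0 = vu; } else { v0 = vc; v1 = vu; }
  }
  return ll;
}
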