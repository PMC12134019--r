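// Cox partial-likelihood kernel for fixed subject scores (offsets):
// log likelihood, gradient with respect to the scores, and the quadratic
// form J' H J of the score-space Hessian with a parameter Jacobian J.
// Inputs arrive pre-sorted by follow-up time (ascending); tied event times
// form groups handled by Efron's or Breslow's correction.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List cox_pl_sorted(NumericVector ss,        // scores, sorted by time
                   IntegerVector ev_all,    // sorted indices of events (1-based)
                   IntegerVector grp_of_ev, // tie-group id per event (1..ng)
                   IntegerVector d,         // events per group
                   IntegerVector risk_starts, // first sorted index in risk set
                   bool efron,
                   bool want_grad) {
  const int n = ss.size();
  const int ng = d.size();
  const int ne = ev_all.size();

  std::vector<double> w(n), revcum(n + 1);
  for (int i = 0; i < n; ++i) w[i] = std::exp(ss[i]);
  revcum[n] = 0.0;
  for (int i = n - 1; i >= 0; --i) revcum[i] = revcum[i + 1] + w[i];

  // event-side sums per group
  std::vector<double> T(ng, 0.0), ssum(ng, 0.0);
  for (int e = 0; e < ne; ++e) {
    int i = ev_all[e] - 1, j = grp_of_ev[e] - 1;
    T[j] += w[i];
    ssum[j] += ss[i];
  }

  double ll = 0.0;
  std::vector<double> A(ng, 0.0), C(ng, 0.0);
  for (int j = 0; j < ng; ++j) {
    double S = revcum[risk_starts[j] - 1];
    int dj = d[j];
    ll += ssum[j];
    if (!efron || dj == 1) {
      ll -= dj * std::log(S);
      A[j] = dj / S;
    } else {
      for (int l = 0; l < dj; ++l) {
        double f = (double)l / dj;
        double D = S - f * T[j];
        ll -= std::log(D);
        A[j] += 1.0 / D;
        C[j] += f / D;
      }
    }
  }

  List out = List::create(Named("ll") = ll);
  if (want_grad) {
    NumericVector grad(n);
    // G_k = sum of A_j over groups with risk_start <= k (sorted index k)
    double cumA = 0.0;
    int j = 0;
    for (int k = 0; k < n; ++k) {
      while (j < ng && risk_starts[j] - 1 <= k) cumA += A[j++];
      grad[k] = -w[k] * cumA;
    }
    for (int e = 0; e < ne; ++e) {
      int i = ev_all[e] - 1, jj = grp_of_ev[e] - 1;
      grad[i] += 1.0 + w[i] * C[jj];
    }
    out["grad"] = grad;
  }
  return out;
}
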