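// MAP fit of an interaction tree's parameters: maximizes the Efron/Breslow
// Cox partial likelihood of the tree's subject scores (offsets) plus
// standard-normal log priors on beta and each log(1 + theta), by damped
// Newton iterations with eigenvalue-floored steps (the multiplicative model
// has a saddle at the origin and can be multimodal, so raw Newton steps are
// unsafe). Everything arrives pre-sorted by follow-up time.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct PLStruct {
  arma::ivec ev_all;       // 0-based sorted indices of events
  arma::ivec grp;          // 0-based group per event
  arma::ivec d;            // events per group
  arma::ivec rs;           // 0-based risk-set start per group
  bool efron;
};

// scores, Jacobian and P products for parameters x given sorted dosages G
struct ScoreParts {
  arma::vec s, P;
  arma::mat J;
  arma::vec theta, ephi;
};

void score_parts(const arma::mat& G, const arma::vec& x, int k,
                 ScoreParts& sp) {
  const int n = G.n_rows, L = G.n_cols;
  sp.P.ones(n);
  if (k == 1) {
    sp.theta = arma::vec{1.0};
    sp.ephi = arma::vec{1.0};
    sp.P = 1.0 + G.col(0);
  } else {
    sp.theta.set_size(L);
    sp.ephi.set_size(L);
    for (int l = 0; l < L; ++l) {
      sp.ephi[l] = std::exp(x[1 + l]);
      sp.theta[l] = sp.ephi[l] - 1.0;
      sp.P %= (1.0 + sp.theta[l] * G.col(l));
    }
  }
  sp.s = x[0] * (sp.P - 1.0);
  sp.J.set_size(n, k);
  sp.J.col(0) = sp.P - 1.0;
  if (k > 1) {
    for (int l = 0; l < L; ++l) {
      sp.J.col(1 + l) = x[0] * sp.ephi[l] *
        (G.col(l) % sp.P / (1.0 + sp.theta[l] * G.col(l)));
    }
  }
}

// negative log posterior, gradient and (optionally) Hessian at x
// returns false if the value is not finite
bool eval_negpost(const arma::mat& G, const PLStruct& pl, const arma::vec& x,
                  int k, int order, double& value, arma::vec& grad,
                  arma::mat& hess, double* ll_out = nullptr) {
  const int n = G.n_rows;
  const int ng = pl.d.n_elem;
  const int ne = pl.ev_all.n_elem;
  ScoreParts sp;
  score_parts(G, x, k, sp);

  arma::vec w(n), revcum(n + 1);
  for (int i = 0; i < n; ++i) w[i] = std::exp(sp.s[i]);
  revcum[n] = 0.0;
  for (int i = n - 1; i >= 0; --i) revcum[i] = revcum[i + 1] + w[i];

  arma::vec T(ng, arma::fill::zeros), ssum(ng, arma::fill::zeros);
  for (int e = 0; e < ne; ++e) {
    T[pl.grp[e]] += w[pl.ev_all[e]];
    ssum[pl.grp[e]] += sp.s[pl.ev_all[e]];
  }
  double ll = 0.0;
  arma::vec A(ng, arma::fill::zeros), C(ng, arma::fill::zeros);
  for (int j = 0; j < ng; ++j) {
    double S = revcum[pl.rs[j]];
    int dj = pl.d[j];
    ll += ssum[j];
    if (!pl.efron || dj == 1) {
      ll -= dj * std::log(S);
      A[j] = dj / S;
    } else {
      for (int l = 0; l < dj; ++l) {
        double f = (double)l / dj;
        double D = S - f * T[j];
        if (D <= 0) return false;
        ll -= std::log(D);
        A[j] += 1.0 / D;
        C[j] += f / D;
      }
    }
  }
  double logprior = 0.0;
  for (int a = 0; a < k; ++a) logprior += -0.5 * x[a] * x[a];
  logprior -= k * 0.9189385332046727;  // k * log(sqrt(2*pi))
  value = -(ll + logprior);
  if (!std::isfinite(value)) return false;
  if (ll_out) *ll_out = ll;
  if (order < 1) return true;

  // gradient of ll with respect to the scores
  arma::vec gs(n);
  {
    double cumA = 0.0;
    int j = 0;
    for (int i = 0; i < n; ++i) {
      while (j < ng && pl.rs[j] <= i) cumA += A[j++];
      gs[i] = -w[i] * cumA;
    }
    for (int e = 0; e < ne; ++e) {
      int i = pl.ev_all[e];
      gs[i] += 1.0 + w[i] * C[pl.grp[e]];
    }
  }
  grad = -(sp.J.t() * gs - x);   // negpost gradient (prior grad is -x)
  if (order < 2) return true;

  // Hessian: J' H_s J via suffix blocks + second-derivative terms + prior
  arma::mat H(k, k, arma::fill::zeros);
  {
    const double* Jp = sp.J.memptr();           // column-major n x k
    double accS = 0.0;
    std::vector<double> accU(k, 0.0), accQ(k * k, 0.0);
    std::vector<double> Svec(ng), U(ng * k), Q(ng * k * k);
    int j = ng - 1;
    for (int i = n - 1; i >= 0 && j >= 0; --i) {
      double wi = w[i];
      accS += wi;
      for (int a = 0; a < k; ++a) {
        double wja = wi * Jp[a * n + i];
        accU[a] += wja;
        for (int b = a; b < k; ++b) accQ[a * k + b] += wja * Jp[b * n + i];
      }
      while (j >= 0 && pl.rs[j] == i) {
        Svec[j] = accS;
        for (int a = 0; a < k; ++a) U[j * k + a] = accU[a];
        for (int p = 0; p < k * k; ++p) Q[j * k * k + p] = accQ[p];
        --j;
      }
    }
    std::vector<double> Tg(ng, 0.0), E(ng * k, 0.0), Fq(ng * k * k, 0.0);
    for (int e = 0; e < ne; ++e) {
      int i = pl.ev_all[e], jg = pl.grp[e];
      double wi = w[i];
      Tg[jg] += wi;
      for (int a = 0; a < k; ++a) {
        double wja = wi * Jp[a * n + i];
        E[jg * k + a] += wja;
        for (int b = a; b < k; ++b) Fq[jg * k * k + a * k + b] += wja * Jp[b * n + i];
      }
    }
    std::vector<double> uv(k);
    for (int jg = 0; jg < ng; ++jg) {
      int dj = pl.d[jg];
      for (int l = 0; l < dj; ++l) {
        double f = pl.efron ? (double)l / dj : 0.0;
        double D = Svec[jg] - f * Tg[jg];
        for (int a = 0; a < k; ++a) uv[a] = U[jg * k + a] - f * E[jg * k + a];
        for (int a = 0; a < k; ++a) {
          for (int b = a; b < k; ++b) {
            double val = uv[a] * uv[b] / (D * D) -
              (Q[jg * k * k + a * k + b] - f * Fq[jg * k * k + a * k + b]) / D;
            H(a, b) += val;
            if (a != b) H(b, a) += val;
          }
        }
      }
    }
    // second derivatives of s(x); dR_l/dtheta_l = 0
    if (k > 1) {
      const int L = G.n_cols;
      for (int l = 0; l < L; ++l) {
        arma::vec Rl = G.col(l) % sp.P / (1.0 + sp.theta[l] * G.col(l));
        double cross = arma::dot(gs, Rl) * sp.ephi[l];
        H(0, 1 + l) += cross;
        H(1 + l, 0) += cross;
        H(1 + l, 1 + l) += x[0] * cross;
        for (int m = l + 1; m < L; ++m) {
          arma::vec mixv = G.col(l) % G.col(m) % sp.P /
            ((1.0 + sp.theta[l] * G.col(l)) % (1.0 + sp.theta[m] * G.col(m)));
          double mix = x[0] * sp.ephi[l] * sp.ephi[m] * arma::dot(gs, mixv);
          H(1 + l, 1 + m) += mix;
          H(1 + m, 1 + l) += mix;
        }
      }
    }
  }
  hess = -H + arma::eye(k, k);   // negpost Hessian (prior contributes +I)
  return true;
}

} // namespace

// [[Rcpp::export]]
List tree_map_fit(const arma::mat& G,          // sorted dosages, n x L
                  IntegerVector ev_all1,       // 1-based event indices
                  IntegerVector grp1,          // 1-based groups
                  IntegerVector d,
                  IntegerVector rs1,           // 1-based risk starts
                  bool efron,
                  const arma::vec& init,
                  int max_iter = 50) {
  PLStruct pl;
  pl.ev_all = as<arma::ivec>(ev_all1) - 1;
  pl.grp = as<arma::ivec>(grp1) - 1;
  pl.d = as<arma::ivec>(d);
  pl.rs = as<arma::ivec>(rs1) - 1;
  pl.efron = efron;
  const int L = G.n_cols;
  const int k = (L == 1) ? 1 : 1 + L;

  arma::vec x = init, grad(k);
  arma::mat hess(k, k);
  double v;
  if (!eval_negpost(G, pl, x, k, 0, v, grad, hess)) {
    return List::create(Named("ok") = false);
  }
  int restarts = 0, conv = 1;
  for (int it = 0; it < max_iter; ++it) {
    if (!eval_negpost(G, pl, x, k, 2, v, grad, hess)) break;
    arma::vec lam;
    arma::mat V;
    if (!arma::eig_sym(lam, V, arma::symmatu(hess))) break;
    if (arma::abs(grad).max() < 1e-8) {
      if (lam.min() > 0) { conv = 0; break; }
      if (restarts >= 3) { conv = 2; break; }
      ++restarts;
      // escape the saddle along the most negative curvature direction
      arma::vec dir = V.col(lam.index_min());
      arma::vec xa = x + 0.3 * dir, xb = x - 0.3 * dir;
      double va, vb;
      arma::vec gd; arma::mat hd;
      bool oka = eval_negpost(G, pl, xa, k, 0, va, gd, hd);
      bool okb = eval_negpost(G, pl, xb, k, 0, vb, gd, hd);
      if (oka && (!okb || va <= vb)) { x = xa; v = va; }
      else if (okb) { x = xb; v = vb; }
      else { conv = 2; break; }
      continue;
    }
    arma::vec fl = arma::clamp(arma::abs(lam), 1e-8, arma::datum::inf);
    arma::vec step = V * ((V.t() * grad) / fl);
    double t = 1.0;
    bool improved = false;
    while (t >= 1e-9) {
      arma::vec x2 = x - t * step;
      double v2;
      arma::vec gd; arma::mat hd;
      if (eval_negpost(G, pl, x2, k, 0, v2, gd, hd) && v2 < v) {
        double dv = v - v2;
        x = x2;
        v = v2;
        improved = true;
        if (dv < 1e-12) { conv = 0; it = max_iter; }  // converged by value
        break;
      }
      t /= 2.0;
    }
    if (!improved) { conv = 0; break; }  // no further descent possible
  }
  double ll = 0.0;
  eval_negpost(G, pl, x, k, 2, v, grad, hess, &ll);
  return List::create(Named("ok") = true, Named("par") = x,
                      Named("value") = v, Named("convergence") = conv,
                      Named("curvature") = arma::symmatu(hess),
                      Named("ll") = ll,
                      Named("grad_inf") = arma::abs(grad).max());
}
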