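// Saddlepoint hot path: safeguarded Newton solve of K'(t) = s plus the
// Lugannani-Rice tail, fused into single passes over the subjects so the
// genome-wide scan does not pay R-level allocation costs per iteration.
// The pure-R cgf()/solve_saddlepoint() implementations in R/spa.R are the
// reference these kernels are tested against.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double sigmoid(double x) {
  if (x >= 0) {
    return 1.0 / (1.0 + std::exp(-x));
  }
  double e = std::exp(x);
  return e / (1.0 + e);
}

// K'(t) and K''(t) in one pass
static void cgf_d12_c(const double* g, const double* eta, int n, double c1,
                      double t, double& d1, double& d2) {
  double s1 = 0.0, s2 = 0.0;
  for (int i = 0; i < n; i++) {
    double st = sigmoid(eta[i] + g[i] * t);
    s1 += g[i] * st;
    s2 += g[i] * g[i] * st * (1.0 - st);
  }
  d1 = s1 - c1;
  d2 = s2;
}

// K(t), overflow-safe
static double cgf_k_c(const double* g, const double* mu, int n, double c1,
                      double t) {
  double s = 0.0;
  for (int i = 0; i < n; i++) {
    double x = g[i] * t;
    if (x > 0) {
      s += x + std::log(mu[i] + (1.0 - mu[i]) * std::exp(-x));
    } else {
      s += std::log((1.0 - mu[i]) + mu[i] * std::exp(x));
    }
  }
  return s - t * c1;
}

// Upper tail P(S >= s_abs), s_abs > 0. Returns p = NA when the omega
// correction degenerates (caller falls back to the normal approximation).
// [[Rcpp::export]]
List spa_tail_upper_cpp(NumericVector g, NumericVector eta, NumericVector mu,
                        double c1, double s_abs, double var0, double tol,
                        double t_max, int max_iter) {
  int n = g.size();
  const double* gp = g.begin();
  const double* ep = eta.begin();
  const double* mp = mu.begin();
  double d1, d2;

  // bracket / clamp
  cgf_d12_c(gp, ep, n, c1, t_max, d1, d2);
  bool converged = true;
  double t_hat;
  if (d1 <= s_abs) {
    t_hat = t_max;
    converged = false;
  } else {
    double lo = -t_max, hi = t_max;
    t_hat = var0 > 0 ? std::min(s_abs / var0, t_max) : 0.0;
    converged = false;
    for (int it = 0; it < max_iter; it++) {
      cgf_d12_c(gp, ep, n, c1, t_hat, d1, d2);
      double f = d1 - s_abs;
      if (std::fabs(f) < tol * std::max(1.0, std::fabs(s_abs))) {
        converged = true;
        break;
      }
      if (f > 0) hi = t_hat; else lo = t_hat;
      double t_new = d2 > 0 ? t_hat - f / d2 : NA_REAL;
      if (!std::isfinite(t_new) || t_new <= lo || t_new >= hi) {
        t_new = 0.5 * (lo + hi);
      }
      t_hat = t_new;
    }
  }

  double arg = t_hat * s_abs - cgf_k_c(gp, mp, n, c1, t_hat);
  if (!std::isfinite(arg) || arg < 0) {
    return List::create(_["p"] = NA_REAL, _["t_hat"] = t_hat,
                        _["omega"] = NA_REAL, _["nu"] = NA_REAL,
                        _["converged"] = converged);
  }
  double omega = (t_hat >= 0 ? 1.0 : -1.0) * std::sqrt(2.0 * arg);
  cgf_d12_c(gp, ep, n, c1, t_hat, d1, d2);
  double nu = t_hat * std::sqrt(d2);
  if (std::fabs(omega) < 1e-4 || nu <= 0) {
    return List::create(_["p"] = NA_REAL, _["t_hat"] = t_hat,
                        _["omega"] = omega, _["nu"] = nu,
                        _["converged"] = converged);
  }
  double p = R::pnorm(omega + std::log(nu / omega) / omega, 0.0, 1.0, 0, 0);
  return List::create(_["p"] = p, _["t_hat"] = t_hat, _["omega"] = omega,
                      _["nu"] = nu, _["converged"] = converged);
}
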