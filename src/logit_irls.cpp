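#include <Rcpp.h>
using namespace Rcpp;

// Two-parameter logit survival fit by iteratively reweighted least squares
// (Newton scoring).  Model: alive_i ~ Binomial(n_i, p_i) with
// p_i = 1 / (1 + exp(a * t_i - b)), i.e. linear predictor eta = b - a * t.
// Internally the coefficients are beta = (b, s) with s = -a so the design
// matrix is the usual [1, t].
//
// Returns c(a, b, loglik, converged, iterations).  loglik is the binomial
// kernel sum(alive * log(p) + dead * log(1 - p)) without the constant
// choose(n, alive) term.

static inline double clamp01(double p) {
  const double eps = 1e-12;
  if (p < eps) return eps;
  if (p > 1.0 - eps) return 1.0 - eps;
  return p;
}

static double kernel_ll(const NumericVector& t, const NumericVector& alive,
                        const NumericVector& dead, double b, double s) {
  double ll = 0.0;
  for (int i = 0; i < t.size(); ++i) {
    const double p = clamp01(1.0 / (1.0 + std::exp(-(b + s * t[i]))));
    ll += alive[i] * std::log(p) + dead[i] * std::log(1.0 - p);
  }
  return ll;
}

// [[Rcpp::export]]
NumericVector logit_irls_cpp(NumericVector t, NumericVector alive,
                             NumericVector dead, double b0, double s0,
                             double tol, int maxit) {
  const int n = t.size();
  double b = b0, s = s0;
  bool converged = false;
  int iter = 0;
  double ll_cur = kernel_ll(t, alive, dead, b, s);

  for (iter = 1; iter <= maxit; ++iter) {
    // score U and Fisher information J for beta = (b, s)
    double u0 = 0.0, u1 = 0.0;
    double j00 = 0.0, j01 = 0.0, j11 = 0.0;
    for (int i = 0; i < n; ++i) {
      const double eta = b + s * t[i];
      const double p = clamp01(1.0 / (1.0 + std::exp(-eta)));
      const double m = alive[i] + dead[i];
      const double r = alive[i] - m * p;   // residual on the count scale
      const double w = m * p * (1.0 - p);  // binomial working weight
      u0 += r;
      u1 += r * t[i];
      j00 += w;
      j01 += w * t[i];
      j11 += w * t[i] * t[i];
    }
    const double det = j00 * j11 - j01 * j01;
    if (!std::isfinite(det) || std::fabs(det) < 1e-300) break;
    double db = (j11 * u0 - j01 * u1) / det;
    double ds = (j00 * u1 - j01 * u0) / det;
    // step-halving line search: Newton can overshoot on flat or
    // near-separated likelihoods; only accept ascent steps
    double step = 1.0;
    double ll_new = kernel_ll(t, alive, dead, b + db, s + ds);
    int halvings = 0;
    while ((!std::isfinite(ll_new) || ll_new < ll_cur - 1e-12) &&
           halvings < 60) {
      step *= 0.5;
      ++halvings;
      ll_new = kernel_ll(t, alive, dead, b + step * db, s + step * ds);
    }
    b += step * db;
    s += step * ds;
    ll_cur = ll_new;
    if (std::max(std::fabs(step * db), std::fabs(step * ds)) < tol) {
      converged = true;
      break;
    }
  }

  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    const double p = clamp01(1.0 / (1.0 + std::exp(-(b + s * t[i]))));
    ll += alive[i] * std::log(p) + dead[i] * std::log(1.0 - p);
  }

  return NumericVector::create(-s, b, ll, converged ? 1.0 : 0.0,
                               (double)iter);
}

// Binomial log-likelihood kernel of (a, b) on a dataset; used by the
// grid-search oracle helpers and kept in C++ so dense grids stay cheap.
// [[Rcpp::export]]
double logit_loglik_cpp(NumericVector t, NumericVector alive,
                        NumericVector dead, double a, double b) {
  const int n = t.size();
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    const double p = clamp01(1.0 / (1.0 + std::exp(a * t[i] - b)));
    ll += alive[i] * std::log(p) + dead[i] * std::log(1.0 - p);
  }
  return ll;
}
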