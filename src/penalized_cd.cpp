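// Coordinate-descent solvers for penalized logistic and Cox regression
// (LASSO / adaptive LASSO / elastic net / MCP), ncvreg-style:
// outer IRLS on the (partial) likelihood, inner weighted coordinate descent
// on the working response, warm starts along a decreasing lambda path.
//
// Columns of X are assumed standardized (mean 0, population sd 1) by the
// caller; coefficients are returned on that standardized scale.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// One-dimensional update. pen: 0 = elastic-net family (lasso at alpha = 1,
// adaptive lasso via penalty factors), 1 = MCP. For MCP the concavity is
// rescaled per-coordinate by the curvature v_j (gamma_eff = gamma / v_j) so
// the coordinate problem stays strictly convex for any IRLS weights.
static inline double cd_update(double zj, double vj, double lam, double pf,
                               int pen, double alpha, double gamma) {
  if (pen == 0) {
    return soft(zj, lam * alpha * pf) / (vj + lam * (1.0 - alpha) * pf);
  }
  double lp = lam * pf;
  if (std::fabs(zj) <= gamma * lp) return soft(zj, lp) / (vj * (1.0 - 1.0 / gamma));
  return zj / vj;
}

// Weighted coordinate descent on the quadratic working model.
// r holds the working residual z - eta and is updated in place.
static void cd_inner(const NumericMatrix& X, const std::vector<double>& w,
                     std::vector<double>& r, std::vector<double>& beta,
                     double& beta0, bool use_intercept, double lam,
                     const NumericVector& pf, int pen, double alpha,
                     double gamma, const std::vector<double>& v, double tol,
                     int max_sweeps) {
  const int n = X.nrow(), p = X.ncol();
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double maxd = 0.0;
    if (use_intercept) {
      double sw = 0.0, swr = 0.0;
      for (int i = 0; i < n; ++i) { sw += w[i]; swr += w[i] * r[i]; }
      double d0 = (sw > 0.0) ? swr / sw : 0.0;
      if (d0 != 0.0) {
        beta0 += d0;
        for (int i = 0; i < n; ++i) r[i] -= d0;
        if (std::fabs(d0) > maxd) maxd = std::fabs(d0);
      }
    }
    for (int j = 0; j < p; ++j) {
      if (v[j] <= 1e-12) continue;
      const double* xj = &X(0, j);
      double zj = 0.0;
      for (int i = 0; i < n; ++i) zj += w[i] * xj[i] * r[i];
      zj = zj / n + v[j] * beta[j];
      double bnew = cd_update(zj, v[j], lam, pf[j], pen, alpha, gamma);
      double d = bnew - beta[j];
      if (d != 0.0) {
        beta[j] = bnew;
        for (int i = 0; i < n; ++i) r[i] -= d * xj[i];
        double sc = std::fabs(d) * std::sqrt(v[j]);
        if (sc > maxd) maxd = sc;
      }
    }
    if (maxd < tol) break;
  }
}

static inline double clip(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// [[Rcpp::export]]
List cd_logistic_path(NumericMatrix X, NumericVector y, NumericVector lambda,
                      double alpha, double gamma, NumericVector pf, int pen,
                      double tol, int max_outer, int max_sweeps) {
  const int n = X.nrow(), p = X.ncol(), L = lambda.size();
  NumericMatrix betas(p, L);
  NumericVector b0s(L), ll(L);
  IntegerVector iters(L), conv(L);
  NumericVector vout(p);

  std::vector<double> beta(p, 0.0), eta(n), w(n), r(n), v(p, 0.0);
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  double beta0 = std::log(ybar / (1.0 - ybar));
  const double ll_null = n * (ybar * std::log(ybar) +
                              (1.0 - ybar) * std::log(1.0 - ybar));
  bool truncated = false;

  for (int l = 0; l < L; ++l) {
    if (truncated) { conv[l] = 0; continue; }
    double lam = lambda[l];
    int it = 0;
    bool ok = false;
    for (it = 0; it < max_outer; ++it) {
      // linear predictor from current coefficients
      for (int i = 0; i < n; ++i) eta[i] = beta0;
      for (int j = 0; j < p; ++j) {
        if (beta[j] != 0.0) {
          const double* xj = &X(0, j);
          for (int i = 0; i < n; ++i) eta[i] += beta[j] * xj[i];
        }
      }
      for (int i = 0; i < n; ++i) {
        double e = clip(eta[i], -30.0, 30.0);
        double mu = 1.0 / (1.0 + std::exp(-e));
        double wi = mu * (1.0 - mu);
        if (wi < 1e-6) wi = 1e-6;
        w[i] = wi;
        r[i] = (y[i] - mu) / wi;  // working residual z - eta
      }
      for (int j = 0; j < p; ++j) {
        const double* xj = &X(0, j);
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += w[i] * xj[i] * xj[i];
        v[j] = s / n;
      }
      std::vector<double> bprev(beta);
      double b0prev = beta0;
      cd_inner(X, w, r, beta, beta0, true, lam, pf, pen, alpha, gamma, v,
               tol, max_sweeps);
      double maxd = std::fabs(beta0 - b0prev);
      for (int j = 0; j < p; ++j) {
        double d = std::fabs(beta[j] - bprev[j]);
        if (d > maxd) maxd = d;
      }
      if (maxd < tol) { ok = true; break; }
    }
    // log-likelihood at the solution
    double lik = 0.0;
    for (int i = 0; i < n; ++i) eta[i] = beta0;
    for (int j = 0; j < p; ++j) {
      if (beta[j] != 0.0) {
        const double* xj = &X(0, j);
        for (int i = 0; i < n; ++i) eta[i] += beta[j] * xj[i];
      }
    }
    double bmax = 0.0;
    for (int j = 0; j < p; ++j)
      if (std::fabs(beta[j]) > bmax) bmax = std::fabs(beta[j]);
    for (int i = 0; i < n; ++i) {
      double e = clip(eta[i], -30.0, 30.0);
      lik += y[i] * e - std::log1p(std::exp(e));
    }
    for (int j = 0; j < p; ++j) betas(j, l) = beta[j];
    b0s[l] = beta0;
    ll[l] = lik;
    iters[l] = it + 1;
    conv[l] = (ok && bmax < 1e2) ? 1 : 0;
    // saturation (complete-separation region) or divergence: truncate the
    // remainder of the path and restart later fits from the null model
    double dev_ratio = 1.0 - lik / ll_null;
    if (!conv[l] || dev_ratio > 0.995 || bmax > 1e2) {
      if (dev_ratio > 0.995 || bmax > 1e2) conv[l] = 0;
      truncated = true;
      std::fill(beta.begin(), beta.end(), 0.0);
      beta0 = std::log(ybar / (1.0 - ybar));
    }
  }
  for (int j = 0; j < p; ++j) vout[j] = v[j];
  return List::create(_["beta0"] = b0s, _["beta"] = betas, _["loglik"] = ll,
                      _["iter"] = iters, _["converged"] = conv, _["v"] = vout);
}

// Gradient and diagonal Hessian of the Efron partial log-likelihood with
// respect to the linear predictor, plus the log-likelihood itself.
// Rows must be sorted by increasing time.
static void cox_derivs(const std::vector<double>& eta,
                       const NumericVector& time, const IntegerVector& event,
                       std::vector<double>& g, std::vector<double>& h,
                       double& loglik) {
  const int n = eta.size();
  std::vector<double> ex(n);
  for (int i = 0; i < n; ++i) ex[i] = std::exp(clip(eta[i], -200.0, 200.0));
  // suffix sums of exp(eta): risk-set totals
  std::vector<double> cum(n + 1, 0.0);
  for (int i = n - 1; i >= 0; --i) cum[i] = cum[i + 1] + ex[i];

  loglik = 0.0;
  double A = 0.0, A2 = 0.0;  // running sums over processed event groups
  int i = 0;
  for (int s = 0; s < n; ++s) { g[s] = 0.0; h[s] = 0.0; }
  std::vector<double> Ai(n, 0.0), A2i(n, 0.0), bown(n, 0.0), qown(n, 0.0);
  while (i < n) {
    int jj = i;
    while (jj < n && time[jj] == time[i]) ++jj;  // tie group [i, jj)
    int d = 0;
    double S = 0.0, etasum = 0.0;
    for (int k = i; k < jj; ++k) {
      if (event[k] == 1) { ++d; S += ex[k]; etasum += eta[k]; }
    }
    if (d > 0) {
      double R = cum[i];
      double a = 0.0, a2 = 0.0, b = 0.0, q = 0.0;
      for (int l = 0; l < d; ++l) {
        double frac = (double)l / d;
        double phi = R - frac * S;
        loglik -= std::log(phi);
        a += 1.0 / phi;
        a2 += 1.0 / (phi * phi);
        b += frac / phi;
        q += frac * (2.0 - frac) / (phi * phi);
      }
      loglik += etasum;
      A += a;
      A2 += a2;
      for (int k = i; k < jj; ++k) {
        if (event[k] == 1) { bown[k] = b; qown[k] = q; }
      }
    }
    for (int k = i; k < jj; ++k) { Ai[k] = A; A2i[k] = A2; }
    i = jj;
  }
  for (int s = 0; s < n; ++s) {
    double del = (event[s] == 1) ? 1.0 : 0.0;
    g[s] = del - ex[s] * (Ai[s] - del * bown[s]);
    double hs = ex[s] * (Ai[s] - del * bown[s]) -
                ex[s] * ex[s] * (A2i[s] - del * qown[s]);
    h[s] = hs;
  }
}

// [[Rcpp::export]]
List cox_wz(NumericVector eta, NumericVector time, IntegerVector event) {
  const int n = eta.size();
  std::vector<double> e(n), g(n), h(n);
  for (int i = 0; i < n; ++i) e[i] = eta[i];
  double ll = 0.0;
  cox_derivs(e, time, event, g, h, ll);
  NumericVector go(n), ho(n);
  for (int i = 0; i < n; ++i) { go[i] = g[i]; ho[i] = h[i]; }
  return List::create(_["grad"] = go, _["hess"] = ho, _["loglik"] = ll);
}

// [[Rcpp::export]]
List cd_cox_path(NumericMatrix X, NumericVector time, IntegerVector event,
                 NumericVector lambda, double alpha, double gamma,
                 NumericVector pf, int pen, double tol, int max_outer,
                 int max_sweeps) {
  const int n = X.nrow(), p = X.ncol(), L = lambda.size();
  NumericMatrix betas(p, L);
  NumericVector ll(L);
  IntegerVector iters(L), conv(L);
  NumericVector vout(p);

  std::vector<double> beta(p, 0.0), eta(n, 0.0), g(n), hh(n), w(n), r(n),
      v(p, 0.0);
  double lik = 0.0;
  bool truncated = false;

  for (int l = 0; l < L; ++l) {
    if (truncated) { conv[l] = 0; continue; }
    double lam = lambda[l];
    int it = 0;
    bool ok = false;
    for (it = 0; it < max_outer; ++it) {
      for (int i = 0; i < n; ++i) eta[i] = 0.0;
      for (int j = 0; j < p; ++j) {
        if (beta[j] != 0.0) {
          const double* xj = &X(0, j);
          for (int i = 0; i < n; ++i) eta[i] += beta[j] * xj[i];
        }
      }
      cox_derivs(eta, time, event, g, hh, lik);
      for (int i = 0; i < n; ++i) {
        double wi = hh[i];
        if (wi < 1e-8) wi = 1e-8;
        w[i] = wi;
        r[i] = g[i] / wi;  // working residual; w * r == true gradient term
      }
      for (int j = 0; j < p; ++j) {
        const double* xj = &X(0, j);
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += w[i] * xj[i] * xj[i];
        v[j] = s / n;
      }
      std::vector<double> bprev(beta);
      double b0 = 0.0;
      cd_inner(X, w, r, beta, b0, false, lam, pf, pen, alpha, gamma, v, tol,
               max_sweeps);
      double maxd = 0.0;
      for (int j = 0; j < p; ++j) {
        double d = std::fabs(beta[j] - bprev[j]);
        if (d > maxd) maxd = d;
      }
      if (maxd < tol) { ok = true; break; }
    }
    for (int i = 0; i < n; ++i) eta[i] = 0.0;
    for (int j = 0; j < p; ++j) {
      if (beta[j] != 0.0) {
        const double* xj = &X(0, j);
        for (int i = 0; i < n; ++i) eta[i] += beta[j] * xj[i];
      }
    }
    cox_derivs(eta, time, event, g, hh, lik);
    double bmax = 0.0;
    for (int j = 0; j < p; ++j)
      if (std::fabs(beta[j]) > bmax) bmax = std::fabs(beta[j]);
    for (int j = 0; j < p; ++j) betas(j, l) = beta[j];
    ll[l] = lik;
    iters[l] = it + 1;
    conv[l] = (ok && bmax < 1e2) ? 1 : 0;
    if (!conv[l]) {  // monotone-likelihood region: truncate the path
      truncated = true;
      std::fill(beta.begin(), beta.end(), 0.0);
    }
  }
  for (int j = 0; j < p; ++j) vout[j] = v[j];
  return List::create(_["beta"] = betas, _["loglik"] = ll, _["iter"] = iters,
                      _["converged"] = conv, _["v"] = vout);
}
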