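#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Coordinate descent for the L1-penalized working least-squares problem
//   min (1/2n) sum_i w_i (z_i - b0 - x_i'beta)^2 + lambda ||beta||_1
// wrapped, for the logistic family, in an IRLS outer loop. The lambda
// path is walked top-down with warm starts; the sequential strong rule
// screens the feature set so full passes over all p features happen
// only for gradient/KKT checks.

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

struct CDWork {
  std::vector<double> r;      // working residual z - b0 - X beta
  std::vector<double> w;      // observation weights
  std::vector<double> xv;     // (1/n) sum w x^2 per feature (epoch-cached)
  std::vector<int> xv_epoch;  // epoch when xv[j] was computed
  int epoch;
  double wsum;
};

static void xv_refresh(const NumericMatrix& X, CDWork& wk, int j, int n) {
  if (wk.xv_epoch[j] == wk.epoch) return;
  const double* xj = &X(0, j);
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += wk.w[i] * xj[i] * xj[i];
  wk.xv[j] = s / n;
  wk.xv_epoch[j] = wk.epoch;
}

static double intercept_step(CDWork& wk, double& b0, int n) {
  double num = 0.0;
  for (int i = 0; i < n; ++i) num += wk.w[i] * wk.r[i];
  double d0 = num / wk.wsum;
  b0 += d0;
  for (int i = 0; i < n; ++i) wk.r[i] -= d0;
  return std::fabs(d0);
}

static double cd_sweep(const NumericMatrix& X, CDWork& wk,
                       std::vector<double>& beta,
                       const std::vector<int>& which, double lambda, int n) {
  double maxdel = 0.0;
  for (size_t k = 0; k < which.size(); ++k) {
    int j = which[k];
    xv_refresh(X, wk, j, n);
    if (wk.xv[j] <= 0.0) continue;  // constant column stays at zero
    const double* xj = &X(0, j);
    double grad = 0.0;
    for (int i = 0; i < n; ++i) grad += wk.w[i] * xj[i] * wk.r[i];
    grad /= n;
    double bj = beta[j];
    double bnew = soft(grad + wk.xv[j] * bj, lambda) / wk.xv[j];
    double del = bnew - bj;
    if (del != 0.0) {
      for (int i = 0; i < n; ++i) wk.r[i] -= del * xj[i];
      beta[j] = bnew;
      double a = std::fabs(del);
      if (a > maxdel) maxdel = a;
    }
  }
  return maxdel;
}

// gradient (1/n) X' W r for every feature, at the current residual
static void grad_all(const NumericMatrix& X, const CDWork& wk,
                     std::vector<double>& g, int n, int p) {
  for (int j = 0; j < p; ++j) {
    const double* xj = &X(0, j);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += wk.w[i] * xj[i] * wk.r[i];
    g[j] = s / n;
  }
}

// converge the penalized WLS on the features in `set` (active-set inner loop)
static void cd_converge(const NumericMatrix& X, CDWork& wk,
                        std::vector<double>& beta, double& b0,
                        const std::vector<int>& set, double lambda,
                        int n, double tol, int max_iter) {
  std::vector<int> active;
  for (int it = 0; it < max_iter; ++it) {
    double maxdel = intercept_step(wk, b0, n);
    double d = cd_sweep(X, wk, beta, set, lambda, n);
    if (d > maxdel) maxdel = d;
    if (maxdel < tol) break;
    active.clear();
    for (size_t k = 0; k < set.size(); ++k)
      if (beta[set[k]] != 0.0) active.push_back(set[k]);
    for (int inner = 0; inner < max_iter; ++inner) {
      double mi = intercept_step(wk, b0, n);
      double di = cd_sweep(X, wk, beta, active, lambda, n);
      if (di > mi) mi = di;
      if (mi < tol) break;
    }
  }
}

// [[Rcpp::export]]
List cd_path(NumericMatrix X, NumericVector y, NumericVector lambda,
             int family, double tol, int max_iter) {
  // family: 0 = gaussian (squared loss), 1 = binomial (logistic)
  const int n = X.nrow(), p = X.ncol(), L = lambda.size();
  const double wmin = 1e-5, pmin = 1e-10;
  NumericMatrix beta_out(p, L);
  NumericVector b0_out(L);

  CDWork wk;
  wk.r.assign(n, 0.0);
  wk.w.assign(n, 1.0);
  wk.xv.assign(p, 0.0);
  wk.xv_epoch.assign(p, -1);
  wk.epoch = 0;
  wk.wsum = n;

  std::vector<double> beta(p, 0.0), g(p), z(n), lin(n);
  std::vector<char> in_strong(p, 0);
  std::vector<int> strong;
  double b0;

  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;

  if (family == 0) {
    b0 = ybar;
    for (int i = 0; i < n; ++i) wk.r[i] = y[i] - b0;
    wk.epoch++;  // unit weights, first epoch
    grad_all(X, wk, g, n, p);
    for (int l = 0; l < L; ++l) {
      double lam = lambda[l], lam_prev = (l == 0) ? lam : lambda[l - 1];
      double cut = 2.0 * lam - lam_prev;
      strong.clear();
      std::fill(in_strong.begin(), in_strong.end(), 0);
      for (int j = 0; j < p; ++j)
        if (beta[j] != 0.0 || std::fabs(g[j]) >= cut) {
          strong.push_back(j); in_strong[j] = 1;
        }
      for (int round = 0; round < 100; ++round) {
        cd_converge(X, wk, beta, b0, strong, lam, n, tol, max_iter);
        grad_all(X, wk, g, n, p);   // KKT check outside the strong set
        bool viol = false;
        for (int j = 0; j < p; ++j)
          if (!in_strong[j] && std::fabs(g[j]) > lam * (1.0 + 1e-9) + 1e-12) {
            strong.push_back(j); in_strong[j] = 1; viol = true;
          }
        if (!viol) break;
      }
      for (int j = 0; j < p; ++j) beta_out(j, l) = beta[j];
      b0_out[l] = b0;
    }
  } else {
    b0 = std::log(ybar / (1.0 - ybar));
    std::fill(lin.begin(), lin.end(), b0);
    // null-model quadratic approximation seeds the first gradient
    wk.epoch++;
    for (int i = 0; i < n; ++i) {
      double mu = ybar;
      double wi = std::max(mu * (1.0 - mu), wmin);
      wk.w[i] = wi;
      z[i] = b0 + (y[i] - mu) / wi;
      wk.r[i] = z[i] - lin[i];
    }
    wk.wsum = 0.0;
    for (int i = 0; i < n; ++i) wk.wsum += wk.w[i];
    grad_all(X, wk, g, n, p);

    for (int l = 0; l < L; ++l) {
      double lam = lambda[l], lam_prev = (l == 0) ? lam : lambda[l - 1];
      double cut = 2.0 * lam - lam_prev;
      strong.clear();
      std::fill(in_strong.begin(), in_strong.end(), 0);
      for (int j = 0; j < p; ++j)
        if (beta[j] != 0.0 || std::fabs(g[j]) >= cut) {
          strong.push_back(j); in_strong[j] = 1;
        }
      for (int round = 0; round < 100; ++round) {
        // IRLS on the screened feature set
        for (int outer = 0; outer < max_iter; ++outer) {
          wk.epoch++;
          for (int i = 0; i < n; ++i) {
            double li = lin[i];
            double mu = 1.0 / (1.0 + std::exp(-li));
            if (mu < pmin) mu = pmin;
            if (mu > 1.0 - pmin) mu = 1.0 - pmin;
            double wi = std::max(mu * (1.0 - mu), wmin);
            wk.w[i] = wi;
            z[i] = li + (y[i] - mu) / wi;
            wk.r[i] = z[i] - li;
          }
          wk.wsum = 0.0;
          for (int i = 0; i < n; ++i) wk.wsum += wk.w[i];
          std::vector<double> beta_old(beta);
          double b0_old = b0;
          cd_converge(X, wk, beta, b0, strong, lam, n, tol, max_iter);
          for (int i = 0; i < n; ++i) lin[i] = z[i] - wk.r[i];
          double maxdel = std::fabs(b0 - b0_old);
          for (size_t k = 0; k < strong.size(); ++k) {
            double a = std::fabs(beta[strong[k]] - beta_old[strong[k]]);
            if (a > maxdel) maxdel = a;
          }
          if (maxdel < tol) break;
        }
        grad_all(X, wk, g, n, p);   // KKT check at the final weights
        bool viol = false;
        for (int j = 0; j < p; ++j)
          if (!in_strong[j] && std::fabs(g[j]) > lam * (1.0 + 1e-9) + 1e-12) {
            strong.push_back(j); in_strong[j] = 1; viol = true;
          }
        if (!viol) break;
      }
      for (int j = 0; j < p; ++j) beta_out(j, l) = beta[j];
      b0_out[l] = b0;
    }
  }
  return List::create(_["beta"] = beta_out, _["b0"] = b0_out);
}
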