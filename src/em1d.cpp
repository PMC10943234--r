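#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One-dimensional Gaussian-mixture EM with multiple restarts.
// Each restart starts from a row of mu0 (means), a common initial sigma and
// uniform weights, and iterates E/M steps until the log-likelihood changes by
// less than tol or max_iter is reached. The best restart (highest final
// log-likelihood) wins.
//
// The E-step evaluates densities directly (one exp per point and component);
// when every component underflows to zero at a point, that point is assigned
// to the component with the smallest standardized distance, so the update
// never divides by zero and posteriors never become NaN. Moment accumulators
// run on data centered at the sample mean to avoid cancellation in the
// variance update. A variance floor prevents singular collapse; collapsed
// components survive with near-zero weight and are flagged by the caller.

static const double INV_SQRT_2PI = 0.3989422804014327;

static double em_single(const std::vector<double>& xc, double xbar,
                        std::vector<double>& mu, std::vector<double>& sigma,
                        std::vector<double>& w, int max_iter, double tol,
                        double var_floor, bool& converged, int& n_iter) {
  const int n = (int) xc.size();
  const int K = (int) mu.size();
  std::vector<double> dens(K), rsum(K), rx(K), rxx(K), muc(K), amp(K), inv2v(K);
  double ll = -std::numeric_limits<double>::infinity();
  converged = false;
  n_iter = 0;
  for (int iter = 0; iter < max_iter; ++iter) {
    for (int k = 0; k < K; ++k) {
      rsum[k] = 0.0; rx[k] = 0.0; rxx[k] = 0.0;
      muc[k] = mu[k] - xbar;
      amp[k] = w[k] * INV_SQRT_2PI / sigma[k];
      inv2v[k] = 0.5 / (sigma[k] * sigma[k]);
    }
    double ll_new = 0.0;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        double d = xc[i] - muc[k];
        dens[k] = amp[k] * std::exp(-d * d * inv2v[k]);
        s += dens[k];
      }
      if (s > 0.0 && std::isfinite(s)) {
        ll_new += std::log(s);
        double inv_s = 1.0 / s;
        for (int k = 0; k < K; ++k) {
          double r = dens[k] * inv_s;
          rsum[k] += r;
          rx[k] += r * xc[i];
          rxx[k] += r * xc[i] * xc[i];
        }
      } else {
        // total underflow: hard-assign to the nearest component
        int kbest = 0;
        double zbest = std::numeric_limits<double>::infinity();
        for (int k = 0; k < K; ++k) {
          double z = std::fabs(xc[i] - muc[k]) / sigma[k];
          if (z < zbest) { zbest = z; kbest = k; }
        }
        ll_new += std::log(amp[kbest]) - 0.5 * zbest * zbest;
        rsum[kbest] += 1.0;
        rx[kbest] += xc[i];
        rxx[kbest] += xc[i] * xc[i];
      }
    }
    double wtot = 0.0;
    for (int k = 0; k < K; ++k) {
      double m_k, v_k, w_k;
      if (rsum[k] > 1e-300) {
        m_k = rx[k] / rsum[k];
        v_k = rxx[k] / rsum[k] - m_k * m_k;
        w_k = rsum[k] / n;
      } else {                  // dead component: keep location, zero weight
        m_k = muc[k];
        v_k = var_floor;
        w_k = 1e-12;
      }
      if (v_k < var_floor) v_k = var_floor;
      mu[k] = xbar + m_k;
      sigma[k] = std::sqrt(v_k);
      w[k] = w_k;
      wtot += w_k;
    }
    for (int k = 0; k < K; ++k) w[k] /= wtot;
    n_iter = iter + 1;
    if (std::isfinite(ll) && std::fabs(ll_new - ll) < tol) {
      ll = ll_new;
      converged = true;
      break;
    }
    ll = ll_new;
  }
  return ll;
}

// [[Rcpp::export(name = ".em_restarts")]]
List em_restarts(NumericVector x, NumericMatrix mu0, double sigma0,
                 int max_iter, double tol, double var_floor) {
  const int n = x.size();
  const int R = mu0.nrow();
  const int K = mu0.ncol();
  double xbar = 0.0;
  for (int i = 0; i < n; ++i) xbar += x[i];
  xbar /= n;
  std::vector<double> xc(n);
  for (int i = 0; i < n; ++i) xc[i] = x[i] - xbar;
  NumericVector logliks(R);
  double best_ll = -std::numeric_limits<double>::infinity();
  std::vector<double> best_mu(K), best_sigma(K), best_w(K);
  bool best_conv = false;
  int best_iter = 0, best_r = -1;
  for (int r = 0; r < R; ++r) {
    std::vector<double> mu(K), sigma(K, sigma0), w(K, 1.0 / K);
    for (int k = 0; k < K; ++k) mu[k] = mu0(r, k);
    bool conv;
    int it;
    double ll = em_single(xc, xbar, mu, sigma, w, max_iter, tol, var_floor,
                          conv, it);
    logliks[r] = ll;
    if (ll > best_ll) {
      best_ll = ll;
      best_mu = mu; best_sigma = sigma; best_w = w;
      best_conv = conv; best_iter = it; best_r = r;
    }
  }
  return List::create(
    _["mean"] = NumericVector(best_mu.begin(), best_mu.end()),
    _["sd"] = NumericVector(best_sigma.begin(), best_sigma.end()),
    _["weight"] = NumericVector(best_w.begin(), best_w.end()),
    _["log_likelihood"] = best_ll,
    _["converged"] = best_conv,
    _["n_iter"] = best_iter,
    _["best_restart"] = best_r + 1,
    _["restart_logliks"] = logliks);
}
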