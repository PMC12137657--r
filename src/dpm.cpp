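// Dirichlet-process-mixture geographic profiler.
//
// Records are i.i.d. draws from a mixture over sources k of bivariate
// Normal(mu_k, sigma^2 I); the partition prior is a Chinese restaurant
// process with concentration alpha; mu_k has a uniform prior on the
// analysis frame; sigma^2 is shared across components with an
// inverse-gamma prior. Reallocation uses Neal's algorithm 8 with m_aux
// auxiliary components (the uniform mu prior is non-conjugate for
// opening new components). Uses R's RNG so set.seed() in R gives
// bit-for-bit reproducibility.

#include <Rcpp.h>
using namespace Rcpp;

static inline double log_norm2(double dx, double dy, double sigma2) {
  return -0.5 * (dx * dx + dy * dy) / sigma2 - std::log(2.0 * M_PI * sigma2);
}

// [[Rcpp::export(name = ".dpm_chain_cpp")]]
List dpm_chain_cpp(NumericMatrix X, NumericVector frame, double alpha,
                   double a0, double b0, int n_burn, int n_sample,
                   int m_aux, double grid_x0, double grid_y0,
                   double cell, int n_rows, int n_cols,
                   double sigma2_init) {
  const int n = X.nrow();
  const double xmin = frame[0], xmax = frame[1];
  const double ymin = frame[2], ymax = frame[3];

  // state: cluster assignment per record, cluster centres
  std::vector<int> z(n, 0);
  std::vector<double> cx, cy;
  std::vector<int> csize;
  // initialise: single cluster at the data centroid
  double mx = 0, my = 0;
  for (int i = 0; i < n; ++i) { mx += X(i, 0); my += X(i, 1); }
  cx.push_back(mx / n); cy.push_back(my / n); csize.push_back(n);
  double sigma2 = sigma2_init;

  NumericVector sigma_samples(n_sample);
  IntegerVector k_samples(n_sample);
  NumericMatrix surface(n_rows, n_cols);   // accumulates predictive mass
  std::vector<double> out_cx, out_cy;
  std::vector<int> out_sample, out_size;

  const int total_iter = n_burn + n_sample;
  std::vector<double> logw;

  for (int iter = 0; iter < total_iter; ++iter) {
    // (i) reallocate each record
    for (int i = 0; i < n; ++i) {
      int zi = z[i];
      csize[zi]--;
      if (csize[zi] == 0) {           // drop empty cluster
        int last = (int)cx.size() - 1;
        if (zi != last) {
          cx[zi] = cx[last]; cy[zi] = cy[last]; csize[zi] = csize[last];
          for (int j = 0; j < n; ++j) if (z[j] == last) z[j] = zi;
        }
        cx.pop_back(); cy.pop_back(); csize.pop_back();
      }
      int K = (int)cx.size();
      logw.assign(K + m_aux, 0.0);
      // auxiliary centres drawn from the uniform frame prior
      std::vector<double> ax(m_aux), ay(m_aux);
      for (int a = 0; a < m_aux; ++a) {
        ax[a] = R::runif(xmin, xmax);
        ay[a] = R::runif(ymin, ymax);
      }
      for (int k = 0; k < K; ++k)
        logw[k] = std::log((double)csize[k]) +
          log_norm2(X(i, 0) - cx[k], X(i, 1) - cy[k], sigma2);
      for (int a = 0; a < m_aux; ++a)
        logw[K + a] = std::log(alpha / m_aux) +
          log_norm2(X(i, 0) - ax[a], X(i, 1) - ay[a], sigma2);
      double wmax = logw[0];
      for (size_t k = 1; k < logw.size(); ++k) wmax = std::max(wmax, logw[k]);
      double wsum = 0;
      for (size_t k = 0; k < logw.size(); ++k) {
        logw[k] = std::exp(logw[k] - wmax);
        wsum += logw[k];
      }
      double u = R::runif(0.0, wsum);
      int pick = 0;
      double acc = 0;
      for (size_t k = 0; k < logw.size(); ++k) {
        acc += logw[k];
        if (u <= acc) { pick = (int)k; break; }
      }
      if (pick < K) {
        z[i] = pick; csize[pick]++;
      } else {
        cx.push_back(ax[pick - K]); cy.push_back(ay[pick - K]);
        csize.push_back(1);
        z[i] = K;
      }
    }

    // (ii) update centres from conjugate normal posterior, truncated to
    // the frame by rejection (fallback: clamp)
    int K = (int)cx.size();
    std::vector<double> sx(K, 0.0), sy(K, 0.0);
    for (int i = 0; i < n; ++i) { sx[z[i]] += X(i, 0); sy[z[i]] += X(i, 1); }
    for (int k = 0; k < K; ++k) {
      double mean_x = sx[k] / csize[k], mean_y = sy[k] / csize[k];
      double sdk = std::sqrt(sigma2 / csize[k]);
      double px = 0, py = 0;
      bool ok = false;
      for (int t = 0; t < 100; ++t) {
        px = R::rnorm(mean_x, sdk);
        py = R::rnorm(mean_y, sdk);
        if (px >= xmin && px <= xmax && py >= ymin && py <= ymax) {
          ok = true; break;
        }
      }
      if (!ok) {
        px = std::min(std::max(mean_x, xmin), xmax);
        py = std::min(std::max(mean_y, ymin), ymax);
      }
      cx[k] = px; cy[k] = py;
    }

    // (iii) shared sigma^2 from its conjugate inverse-gamma posterior
    double ss = 0;
    for (int i = 0; i < n; ++i) {
      double dx = X(i, 0) - cx[z[i]], dy = X(i, 1) - cy[z[i]];
      ss += dx * dx + dy * dy;
    }
    double a_post = a0 + n;            // n records x 2 dims / 2
    double b_post = b0 + 0.5 * ss;
    sigma2 = b_post / R::rgamma(a_post, 1.0);

    // record post-burn-in samples
    if (iter >= n_burn) {
      int s = iter - n_burn;
      sigma_samples[s] = std::sqrt(sigma2);
      k_samples[s] = K;
      // predictive source-location mass: occupied centres weighted
      // n_k/(n+alpha) binned per cell, plus alpha/(n+alpha) uniform
      double unif = (alpha / (n + alpha)) / (n_rows * n_cols);
      for (int r = 0; r < n_rows; ++r)
        for (int c = 0; c < n_cols; ++c)
          surface(r, c) += unif;
      for (int k = 0; k < K; ++k) {
        int col = (int)std::floor((cx[k] - grid_x0) / cell);
        int row_from_bottom = (int)std::floor((cy[k] - grid_y0) / cell);
        int row = n_rows - 1 - row_from_bottom;   // row 0 = top
        if (col >= 0 && col < n_cols && row >= 0 && row < n_rows)
          surface(row, col) += (double)csize[k] / (n + alpha);
        out_cx.push_back(cx[k]); out_cy.push_back(cy[k]);
        out_sample.push_back(s); out_size.push_back(csize[k]);
      }
    }
  }

  for (int r = 0; r < n_rows; ++r)
    for (int c = 0; c < n_cols; ++c)
      surface(r, c) /= n_sample;

  return List::create(_["sigma"] = sigma_samples,
                      _["k"] = k_samples,
                      _["surface"] = surface,
                      _["centres"] = DataFrame::create(
                        _["x"] = out_cx, _["y"] = out_cy,
                        _["sample"] = out_sample, _["size"] = out_size));
}
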