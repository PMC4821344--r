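#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Brownian dynamics + immobile bleaching + Poisson detection kernel.
//
// Mobile particles take independent per-axis Gaussian steps (variance
// 2*D*dt) in a periodic box centred on the focus; the detection weight of
// a particle at (x,y,z) is exp(-2(x^2+y^2)/wxy^2 - 2 z^2/wz^2), the usual
// 3D-Gaussian confocal profile with lateral 1/e^2 radius wxy and axial
// radius wz = S*wxy. Immobile particles sit at fixed uniform positions and
// bleach irreversibly with per-step survival exp(-k*dt). Counts per bin are
// Poisson with mean brightness*dt*sum(weights) + background*dt.
//
// Uses R's RNG throughout so set.seed() makes traces bit-reproducible.
// [[Rcpp::export(name = ".sim_trace_kernel")]]
IntegerVector sim_trace_kernel(int n_bins, double dt,
                               NumericVector D, IntegerVector n_mobile,
                               int n_immobile, double bleach_rate,
                               double brightness, double background,
                               double wxy, double wz,
                               NumericVector box) {
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  const int ncomp = D.size();
  int n_mob = 0;
  for (int c = 0; c < ncomp; ++c) n_mob += n_mobile[c];

  std::vector<double> x(n_mob), y(n_mob), z(n_mob), sd(n_mob);
  {
    int p = 0;
    for (int c = 0; c < ncomp; ++c) {
      const double s = std::sqrt(2.0 * D[c] * dt);
      for (int j = 0; j < n_mobile[c]; ++j, ++p) {
        x[p] = (unif_rand() - 0.5) * Lx;
        y[p] = (unif_rand() - 0.5) * Ly;
        z[p] = (unif_rand() - 0.5) * Lz;
        sd[p] = s;
      }
    }
  }

  std::vector<double> wimm(n_immobile);      // fixed detection weights
  std::vector<char> alive(n_immobile, 1);
  for (int j = 0; j < n_immobile; ++j) {
    const double xi = (unif_rand() - 0.5) * Lx;
    const double yi = (unif_rand() - 0.5) * Ly;
    const double zi = (unif_rand() - 0.5) * Lz;
    wimm[j] = std::exp(-2.0 * (xi * xi + yi * yi) / (wxy * wxy)
                       - 2.0 * zi * zi / (wz * wz));
  }
  const double p_bleach = 1.0 - std::exp(-bleach_rate * dt);

  const double inv_w2 = 2.0 / (wxy * wxy);
  const double inv_z2 = 2.0 / (wz * wz);
  IntegerVector counts(n_bins);

  for (int t = 0; t < n_bins; ++t) {
    double wsum = 0.0;
    for (int p = 0; p < n_mob; ++p) {
      x[p] += norm_rand() * sd[p];
      y[p] += norm_rand() * sd[p];
      z[p] += norm_rand() * sd[p];
      // wrap into [-L/2, L/2)
      x[p] -= Lx * std::floor(x[p] / Lx + 0.5);
      y[p] -= Ly * std::floor(y[p] / Ly + 0.5);
      z[p] -= Lz * std::floor(z[p] / Lz + 0.5);
      wsum += std::exp(-(x[p] * x[p] + y[p] * y[p]) * inv_w2
                       - z[p] * z[p] * inv_z2);
    }
    if (n_immobile > 0 && p_bleach > 0) {
      for (int j = 0; j < n_immobile; ++j)
        if (alive[j] && unif_rand() < p_bleach) alive[j] = 0;
    }
    for (int j = 0; j < n_immobile; ++j)
      if (alive[j]) wsum += wimm[j];

    const double mu = brightness * dt * wsum + background * dt;
    counts[t] = (mu > 0) ? (int)R::rpois(mu) : 0;
    if (t % 65536 == 0) Rcpp::checkUserInterrupt();
  }
  return counts;
}

// Direct O(n * n_lags) correlator: G(k) = <I_t I_{t+k}> / (<I>_a <I>_b)
// with the two means taken over the overlapping windows (symmetric
// normalization).
// [[Rcpp::export(name = ".acf_direct_kernel")]]
NumericVector acf_direct_kernel(NumericVector xs, IntegerVector lags) {
  const int n = xs.size(), nl = lags.size();
  NumericVector G(nl);
  for (int l = 0; l < nl; ++l) {
    const int k = lags[l];
    const int m = n - k;
    if (m < 2) { G[l] = NA_REAL; continue; }
    double sab = 0.0, sa = 0.0, sb = 0.0;
    for (int i = 0; i < m; ++i) {
      sab += xs[i] * xs[i + k];
      sa += xs[i];
      sb += xs[i + k];
    }
    const double ma = sa / m, mb = sb / m;
    G[l] = (sab / m) / (ma * mb);
  }
  return G;
}
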