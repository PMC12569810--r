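#include <Rcpp.h>
using namespace Rcpp;

// Expected photon count per bin for n_mol molecules performing Brownian
// motion in a periodic box, observed through a 3-D Gaussian detection
// profile exp(-2(x^2+y^2)/w^2 - 2 z^2 / wz^2).
//
// init: n_mol x 3 start positions (box-centred coordinates, [-L/2, L/2)).
// step_sd: per-axis increment SD for one bin (= sqrt(2 D dt)).
// peak_per_bin: photons per bin emitted by a molecule at beam centre.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector sim_trace_brownian_cpp(NumericMatrix init, int n_bins,
                                     double step_sd, double box,
                                     double box_z,
                                     double w2, double wz2,
                                     double peak_per_bin,
                                     bool wrap) {
  const int n_mol = init.nrow();
  const double half = box / 2.0;
  const double half_z = box_z / 2.0;
  std::vector<double> x(n_mol), y(n_mol), z(n_mol);
  for (int m = 0; m < n_mol; ++m) {
    x[m] = init(m, 0); y[m] = init(m, 1); z[m] = init(m, 2);
  }
  NumericVector out(n_bins);
  for (int b = 0; b < n_bins; ++b) {
    double acc = 0.0;
    for (int m = 0; m < n_mol; ++m) {
      if (step_sd > 0.0) {
        x[m] += norm_rand() * step_sd;
        y[m] += norm_rand() * step_sd;
        z[m] += norm_rand() * step_sd;
        if (wrap) {
          if (x[m] >= half || x[m] < -half)
            x[m] -= box * std::floor((x[m] + half) / box);
          if (y[m] >= half || y[m] < -half)
            y[m] -= box * std::floor((y[m] + half) / box);
          if (z[m] >= half_z || z[m] < -half_z)
            z[m] -= box_z * std::floor((z[m] + half_z) / box_z);
        }
      }
      acc += std::exp(-2.0 * (x[m] * x[m] + y[m] * y[m]) / w2
                      - 2.0 * z[m] * z[m] / wz2);
    }
    out[b] = acc * peak_per_bin;
  }
  return out;
}

// Autocovariance sums for arbitrary positive lags:
// g[k] = (1/(n-k)) * sum_i (x_i - mean)(x_{i+k} - mean).
// Normalisation by the squared mean happens in R.
// [[Rcpp::export]]
NumericVector acov_lags_cpp(NumericVector x, IntegerVector lags) {
  const int n = x.size();
  double m = 0.0;
  for (int i = 0; i < n; ++i) m += x[i];
  m /= n;
  NumericVector out(lags.size());
  for (int j = 0; j < lags.size(); ++j) {
    const int k = lags[j];
    if (k < 0 || k >= n) { out[j] = NA_REAL; continue; }
    double s = 0.0;
    for (int i = 0; i + k < n; ++i) s += (x[i] - m) * (x[i + k] - m);
    out[j] = s / (n - k);
  }
  return out;
}
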