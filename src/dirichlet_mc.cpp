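#include <Rcpp.h>
using namespace Rcpp;

// Marsaglia-Tsang (2000) gamma sampler on R's RNG stream (unif_rand /
// norm_rand), noticeably faster than R::rgamma for the millions of draws a
// Monte Carlo Dirichlet table needs. Shapes < 1 use the standard boost
// gamma(a) = gamma(a + 1) * U^(1/a).
static double rgamma_mt(double shape) {
  if (shape == 0.5) {            // Gamma(1/2) = chisq(1)/2 = N(0,1)^2 / 2
    const double z = norm_rand();
    return 0.5 * z * z;
  }
  if (shape < 1.0) {
    double u = unif_rand();
    return rgamma_mt(shape + 1.0) * std::pow(u, 1.0 / shape);
  }
  const double d = shape - 1.0 / 3.0;
  const double c = 1.0 / std::sqrt(9.0 * d);
  for (;;) {
    double x, v;
    do {
      x = norm_rand();
      v = 1.0 + c * x;
    } while (v <= 0.0);
    v = v * v * v;
    const double u = unif_rand();
    const double x2 = x * x;
    if (u < 1.0 - 0.0331 * x2 * x2) return d * v;
    if (std::log(u) < 0.5 * x2 + d * (1.0 - v + std::log(v))) return d * v;
  }
}

// Monte Carlo mean of n_draws Dirichlet(counts[, j] + offset) draws, one
// column per sample. Samples are processed in column order and draws use R's
// RNG stream, so a single set.seed() before the call fixes the whole table.
// [[Rcpp::export(name = ".dirichletMcMean")]]
NumericMatrix dirichlet_mc_mean(const NumericMatrix& counts, double offset,
                                int n_draws) {
  const int D = counts.nrow(), n = counts.ncol();
  NumericMatrix out(D, n);
  std::vector<double> g(D);
  for (int j = 0; j < n; ++j) {
    for (int t = 0; t < n_draws; ++t) {
      double s = 0.0;
      for (int i = 0; i < D; ++i) {
        g[i] = rgamma_mt(counts(i, j) + offset);
        s += g[i];
      }
      for (int i = 0; i < D; ++i) out(i, j) += g[i] / s;
    }
    for (int i = 0; i < D; ++i) out(i, j) /= n_draws;
  }
  return out;
}
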