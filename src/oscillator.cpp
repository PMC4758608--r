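#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration of two phase oscillators with a unidirectional
// Kuramoto-style sine coupling acting on the second (whisking) phase:
//   dphi_x = 2*pi*fx dt + sigma dW_x
//   dphi_y = 2*pi*fy dt + eps(t) * sin(phi_x - phi_y - lag) dt + sigma dW_y
// eps is supplied per sample so that coupling can change stepwise at episode
// boundaries. Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix integrate_coupled_phases(int n, double dt,
                                       double fx, double fy,
                                       NumericVector eps,
                                       double noise_sd, double lag,
                                       double phi_x0, double phi_y0) {
  NumericMatrix out(n, 2);
  double px = phi_x0, py = phi_y0;
  const double wx = 2.0 * M_PI * fx * dt;
  const double wy = 2.0 * M_PI * fy * dt;
  const double sq = noise_sd * std::sqrt(dt);
  out(0, 0) = px;
  out(0, 1) = py;
  for (int i = 1; i < n; i++) {
    double pull = eps[i - 1] * std::sin(px - py - lag) * dt;
    px += wx + sq * R::norm_rand();
    py += wy + pull + sq * R::norm_rand();
    out(i, 0) = px;
    out(i, 1) = py;
  }
  return out;
}
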