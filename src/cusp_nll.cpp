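// Negative log-likelihood and analytic gradient of the cusp regression
// model.  For parameters (a0, a1, b0, b1, w0, w1):
//   alpha_i = a0 + a1*x1_i, beta_i = b0 + b1*x2_i, z_i = w0 + w1*Y_i,
//   NLL = -sum_i [ U(z_i) - log psi_i + log|w1| ],
// with U(z) = alpha*z + beta*z^2/2 - z^4/4 and psi_i the row-wise
// normalizing constant, computed by composite Simpson quadrature on a
// shared equispaced grid wide enough for every row's equilibria
// (|root| <= max(1, sqrt(|beta|+|alpha|))) plus a tail margin grown
// until the kernel at both ends is at least `drop` log-units below
// each row's maximum.  The score needs only the first two moments of
// each row's stationary density, so value and gradient come out of a
// single pass over the grid.

#include <Rcpp.h>
#include <vector>
#include <cmath>

// [[Rcpp::export(name = ".cusp_nll_gr_cpp")]]
Rcpp::List cusp_nll_gr_cpp(Rcpp::NumericVector par,
                           Rcpp::NumericVector x1,
                           Rcpp::NumericVector x2,
                           Rcpp::NumericVector Y,
                           int n_grid = 401,
                           double drop = 40.0) {
  const int n = Y.size();
  const double a0 = par[0], a1 = par[1], b0 = par[2], b1 = par[3],
               w0 = par[4], w1 = par[5];
  Rcpp::NumericVector grad(6);
  if (w1 == 0.0 || !std::isfinite(w1))
    return Rcpp::List::create(Rcpp::Named("value") = 1e10,
                              Rcpp::Named("gradient") = grad);

  std::vector<double> al(n), be(n), z(n);
  double Bmax = 1.0;
  bool bad = false;
  for (int i = 0; i < n; ++i) {
    al[i] = a0 + a1 * x1[i];
    be[i] = b0 + b1 * x2[i];
    z[i] = w0 + w1 * Y[i];
    if (!std::isfinite(al[i]) || !std::isfinite(be[i]) || !std::isfinite(z[i]))
      bad = true;
    double b = std::sqrt(std::fabs(be[i]) + std::fabs(al[i]));
    if (b > Bmax) Bmax = b;
  }
  if (bad)
    return Rcpp::List::create(Rcpp::Named("value") = 1e10,
                              Rcpp::Named("gradient") = grad);

  std::vector<double> y(n_grid), y2(n_grid), y4(n_grid), w(n_grid);
  double margin = 2.0;
  double value = 0.0;
  for (int attempt = 0; attempt < 30; ++attempt) {
    double L = Bmax + margin;
    double h = 2.0 * L / (n_grid - 1);
    for (int j = 0; j < n_grid; ++j) {
      y[j] = -L + h * j;
      y2[j] = 0.5 * y[j] * y[j];
      y4[j] = 0.25 * y[j] * y[j] * y[j] * y[j];
      w[j] = (j == 0 || j == n_grid - 1) ? h / 3.0
             : ((j % 2 == 1) ? 4.0 * h / 3.0 : 2.0 * h / 3.0);
    }
    double worst_edge = -1e300;
    value = 0.0;
    double g0 = 0, g1 = 0, g2 = 0, g3 = 0, g4 = 0, g5 = 0;
    for (int i = 0; i < n; ++i) {
      const double a = al[i], b = be[i];
      double M = -1e300;
      for (int j = 0; j < n_grid; ++j) {
        double u = a * y[j] + b * y2[j] - y4[j];
        if (u > M) M = u;
      }
      double S0 = 0, S1 = 0, S2 = 0, u_lo = 0, u_hi = 0;
      for (int j = 0; j < n_grid; ++j) {
        double u = a * y[j] + b * y2[j] - y4[j];
        double e = std::exp(u - M);
        S0 += w[j] * e;
        S1 += w[j] * e * y[j];
        S2 += w[j] * e * y[j] * y[j];
        if (j == 0) u_lo = u - M;
        if (j == n_grid - 1) u_hi = u - M;
      }
      if (u_lo > worst_edge) worst_edge = u_lo;
      if (u_hi > worst_edge) worst_edge = u_hi;
      const double zi = z[i];
      const double U = a * zi + 0.5 * b * zi * zi - 0.25 * zi * zi * zi * zi;
      const double logpsi = M + std::log(S0);
      value -= U - logpsi + std::log(std::fabs(w1));
      const double E1 = S1 / S0, E2 = S2 / S0;
      const double r1 = zi - E1;
      const double r2 = 0.5 * (zi * zi - E2);
      const double r3 = a + b * zi - zi * zi * zi;
      g0 -= r1;
      g1 -= x1[i] * r1;
      g2 -= r2;
      g3 -= x2[i] * r2;
      g4 -= r3;
      g5 -= Y[i] * r3 + 1.0 / w1;
    }
    if (worst_edge < -drop) {
      grad[0] = g0; grad[1] = g1; grad[2] = g2;
      grad[3] = g3; grad[4] = g4; grad[5] = g5;
      break;
    }
    margin *= 1.6;
    if (attempt == 29) Rcpp::stop("could not bracket the cusp density support");
  }
  if (!std::isfinite(value)) {
    value = 1e10;
    for (int k = 0; k < 6; ++k) grad[k] = 0.0;
  } else {
    for (int k = 0; k < 6; ++k)
      if (!std::isfinite(grad[k])) { grad[k] = 0.0; }
  }
  return Rcpp::List::create(Rcpp::Named("value") = value,
                            Rcpp::Named("gradient") = grad);
}
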