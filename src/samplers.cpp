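// [[Rcpp::depends(RcppArmadillo)]]
#include "geometry.h"
#include <algorithm>
using namespace Rcpp;

// One-dimensional version of the modified GJF scheme (half-time stepping +
// Simpson's rule), used for scalar sampling problems. force codes:
// 0 = free (flat potential), 1 = harmonic (p1 = k), 2 = Morse (p1 = eps,
// p2 = a, p3 = r0, reflecting walls at [lo, hi]).
// [[Rcpp::export(name = ".cpp_gjf1d")]]
NumericVector cpp_gjf1d(long n_steps, double dt, double m, double gamma_, double kBT,
                        int force_code, double p1, double p2, double p3,
                        double lo, double hi, double x0, double v0, int stride,
                        int n_iter = 2) {
  auto F = [&](double x) -> double {
    if (force_code == 1) return -p1*x;
    if (force_code == 2) {
      const double ex = std::exp(-p2*(x - p3));
      return -2.0*p1*p2*ex*(1.0 - ex);
    }
    return 0.0;
  };
  const double S = 1.0/(m + 0.5*dt*gamma_);
  const double ncoef = std::sqrt(2.0*kBT*dt*gamma_);
  double x = x0, v = v0, f = F(x);
  const long nout = n_steps/stride;
  NumericVector out(nout);
  long j = 0;
  for (long s = 0; s < n_steps; ++s) {
    const double beta = (kBT > 0.0) ? ncoef*R::norm_rand() : 0.0;
    double fbar = f, w = 0.0, dx = 0.0, fn = 0.0;
    for (int it = 0; it < n_iter; ++it) {
      w = m*v + 0.5*dt*fbar + 0.5*beta;
      dx = dt*S*w;
      const double fh = F(x + 0.5*dx);
      fn = F(x + dx);
      if (it == n_iter - 1) break;
      fbar = (f + 4.0*fh + fn)/6.0;
    }
    const double Zdx = 2.0*(w - m*dx/dt);
    v += (dt*fbar - Zdx + beta)/m;
    x += dx;
    if (force_code == 2) {
      if (x < lo) { x = 2.0*lo - x; v = -v; }
      if (x > hi) { x = 2.0*hi - x; v = -v; }
    }
    f = F(x);
    if ((s + 1) % stride == 0) out[j++] = x;
  }
  return out;
}

// Kraskov-Stoegbauer-Grassberger mutual information (algorithm 1) with the
// Chebyshev metric, O(n^2); adequate for the per-node-pair map sizes used here.
// [[Rcpp::export(name = ".cpp_knn_mi")]]
double cpp_knn_mi(const arma::mat &X, const arma::mat &Y, int k) {
  const int n = X.n_rows;
  if (k >= n) stop("k must be smaller than the sample size");
  std::vector<double> dxv(n), dyv(n), dzv(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double dx = 0.0, dy = 0.0;
      for (arma::uword c = 0; c < X.n_cols; ++c)
        dx = std::max(dx, std::abs(X(i,c) - X(j,c)));
      for (arma::uword c = 0; c < Y.n_cols; ++c)
        dy = std::max(dy, std::abs(Y(i,c) - Y(j,c)));
      dxv[j] = dx; dyv[j] = dy; dzv[j] = std::max(dx, dy);
    }
    std::vector<double> dz = dzv;
    dz[i] = std::numeric_limits<double>::infinity();
    std::nth_element(dz.begin(), dz.begin() + (k - 1), dz.end());
    const double eps = dz[k - 1];
    int nx = 0, ny = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (dxv[j] < eps) ++nx;
      if (dyv[j] < eps) ++ny;
    }
    acc += R::digamma(nx + 1) + R::digamma(ny + 1);
  }
  double I = R::digamma(k) + R::digamma(n) - acc/n;
  return std::max(I, 0.0);
}
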