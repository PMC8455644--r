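#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fraction of the circle of radius t centred at (x, y) lying inside the
// rectangle [x0,x1] x [y0,y1] (Ripley isotropic edge correction).
// Exterior arc = sum over near edges of 2*acos(e/t), minus the corner
// overlaps acos(ei/t) + acos(ej/t) - pi/2 where ei^2 + ej^2 < t^2.
static double inside_frac(double x, double y, double t,
                          double x0, double x1, double y0, double y1) {
  double ex[2] = {x - x0, x1 - x};   // distances to vertical edges
  double ey[2] = {y - y0, y1 - y};   // distances to horizontal edges
  double ext = 0.0;
  for (int i = 0; i < 2; i++) {
    if (ex[i] < t) {
      double c = ex[i] / t; if (c < -1.0) c = -1.0;
      ext += 2.0 * std::acos(c);
    }
    if (ey[i] < t) {
      double c = ey[i] / t; if (c < -1.0) c = -1.0;
      ext += 2.0 * std::acos(c);
    }
  }
  for (int i = 0; i < 2; i++) {
    for (int j = 0; j < 2; j++) {
      if (ex[i] * ex[i] + ey[j] * ey[j] < t * t) {
        ext -= std::acos(ex[i] / t) + std::acos(ey[j] / t) - M_PI_2;
      }
    }
  }
  double frac = 1.0 - ext / (2.0 * M_PI);
  if (frac < 1e-3) frac = 1e-3;
  return frac;
}

// [[Rcpp::export]]
NumericVector ripley_weight_cpp(NumericVector x, NumericVector y,
                                NumericVector t,
                                double x0, double x1,
                                double y0, double y1) {
  int n = x.size();
  NumericVector w(n);
  for (int i = 0; i < n; i++)
    w[i] = 1.0 / inside_frac(x[i], y[i], t[i], x0, x1, y0, y1);
  return w;
}

// Kernel estimator of the inhomogeneous pair correlation function on a
// uniformly spaced r grid: Epanechnikov kernel of half-width h, Ripley
// isotropic edge-correction weights, divisor 2*pi*r*|W|, each ordered
// pair contributing 1/(lambda_i * lambda_j).
// [[Rcpp::export]]
NumericVector pcf_inhom_cpp(NumericVector x, NumericVector y,
                            NumericVector lambda,
                            double x0, double x1, double y0, double y1,
                            NumericVector r, double h) {
  int n = x.size();
  int m = r.size();
  NumericVector g(m);
  if (n < 2 || m < 1) return g;
  double r1 = r[0];
  double dr = (m > 1) ? (r[1] - r[0]) : 1.0;
  double rmax = r[m - 1];
  double area = (x1 - x0) * (y1 - y0);

  for (int i = 0; i < n - 1; i++) {
    for (int j = i + 1; j < n; j++) {
      double dx = x[i] - x[j];
      double dy = y[i] - y[j];
      double d = std::sqrt(dx * dx + dy * dy);
      if (d > rmax + h || d < 1e-12) continue;
      double wi = 1.0 / inside_frac(x[i], y[i], d, x0, x1, y0, y1);
      double wj = 1.0 / inside_frac(x[j], y[j], d, x0, x1, y0, y1);
      double contrib = (wi + wj) / (lambda[i] * lambda[j]);
      int kmin = (int)std::ceil((d - h - r1) / dr);
      int kmax = (int)std::floor((d + h - r1) / dr);
      if (kmin < 0) kmin = 0;
      if (kmax > m - 1) kmax = m - 1;
      for (int k = kmin; k <= kmax; k++) {
        double u = (r1 + k * dr - d) / h;
        if (u > -1.0 && u < 1.0)
          g[k] += contrib * 0.75 * (1.0 - u * u) / h;
      }
    }
  }
  for (int k = 0; k < m; k++)
    g[k] /= 2.0 * M_PI * r[k] * area;
  return g;
}
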