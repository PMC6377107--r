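#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Asymmetric least squares baseline estimation.
//
// Minimises  sum_i w_i (y_i - z_i)^2 + lambda * sum (d2 z)^2  with asymmetric
// weights w_i = p where y_i > z_i, else 1 - p, iterated until the weight
// vector stops changing. The system matrix W + lambda * D2'D2 is symmetric
// positive definite and pentadiagonal, so each iteration is a banded Cholesky
// factorisation and solve, O(n) per spectrum.

namespace {

// Bands of lambda * D2'D2 for length n (D2 = second-difference operator).
// p0 = diagonal, p1[i] = entry (i+1, i), p2[i] = entry (i+2, i).
void penalty_bands(int n, double lambda,
                   std::vector<double> &p0, std::vector<double> &p1,
                   std::vector<double> &p2) {
  p0.assign(n, 0.0);
  p1.assign(n, 0.0);
  p2.assign(n, 0.0);
  for (int k = 0; k + 2 < n; ++k) {
    // difference row has entries (1, -2, 1) at columns k, k+1, k+2
    p0[k]     += lambda;
    p0[k + 1] += lambda * 4.0;
    p0[k + 2] += lambda;
    p1[k]     -= lambda * 2.0;
    p1[k + 1] -= lambda * 2.0;
    p2[k]     += lambda;
  }
}

// One ALS fit; y and z have length n; w is the working weight buffer.
void als_fit(const double *y, int n, double lambda, double p, int max_iter,
             double tol, const std::vector<double> &p0,
             const std::vector<double> &p1, const std::vector<double> &p2,
             double *z, std::vector<double> &w) {
  // Cholesky bands: d[i] = L(i,i), e[i] = L(i,i-1), f[i] = L(i,i-2)
  std::vector<double> d(n), e(n, 0.0), f(n, 0.0), c(n);
  std::fill(w.begin(), w.end(), 1.0);
  for (int iter = 0; iter < max_iter; ++iter) {
    for (int i = 0; i < n; ++i) {
      f[i] = (i >= 2) ? p2[i - 2] / d[i - 2] : 0.0;
      e[i] = (i >= 1) ? (p1[i - 1] - (i >= 2 ? f[i] * e[i - 1] : 0.0)) / d[i - 1]
                      : 0.0;
      d[i] = std::sqrt(w[i] + p0[i] - e[i] * e[i] - f[i] * f[i]);
      // forward solve folded in: L c = W y
      c[i] = (w[i] * y[i] - e[i] * (i >= 1 ? c[i - 1] : 0.0)
              - f[i] * (i >= 2 ? c[i - 2] : 0.0)) / d[i];
    }
    for (int i = n - 1; i >= 0; --i) {
      z[i] = (c[i] - (i + 1 < n ? e[i + 1] * z[i + 1] : 0.0)
              - (i + 2 < n ? f[i + 2] * z[i + 2] : 0.0)) / d[i];
    }
    double max_change = 0.0;
    for (int i = 0; i < n; ++i) {
      double wn = (y[i] > z[i]) ? p : 1.0 - p;
      double ch = std::fabs(wn - w[i]);
      if (ch > max_change) max_change = ch;
      w[i] = wn;
    }
    if (iter > 0 && max_change < tol) break;
  }
}

}  // namespace

// [[Rcpp::export]]
NumericVector als_baseline_cpp(NumericVector y, double lambda, double p,
                               int max_iter, double tol) {
  int n = y.size();
  if (n < 3) stop("spectrum too short for a second-difference penalty");
  std::vector<double> p0, p1, p2, w(n);
  penalty_bands(n, lambda, p0, p1, p2);
  NumericVector z(n);
  als_fit(REAL(y), n, lambda, p, max_iter, tol, p0, p1, p2, REAL(z), w);
  return z;
}

// Row-wise ALS over a spectra matrix (rows = spectra).
// [[Rcpp::export]]
NumericMatrix als_baseline_mat_cpp(NumericMatrix Y, double lambda, double p,
                                   int max_iter, double tol) {
  int nr = Y.nrow(), n = Y.ncol();
  if (n < 3) stop("spectra too short for a second-difference penalty");
  std::vector<double> p0, p1, p2, w(n), yi(n), zi(n);
  penalty_bands(n, lambda, p0, p1, p2);
  NumericMatrix Z(nr, n);
  for (int r = 0; r < nr; ++r) {
    for (int j = 0; j < n; ++j) yi[j] = Y(r, j);
    als_fit(yi.data(), n, lambda, p, max_iter, tol, p0, p1, p2, zi.data(), w);
    for (int j = 0; j < n; ++j) Z(r, j) = zi[j];
  }
  return Z;
}
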