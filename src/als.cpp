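#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Asymmetric least squares (Eilers-style) baseline estimation.
// For each spectrum y, iterates z = argmin sum_i w_i (y_i - z_i)^2 +
// lam * sum (second difference of z)^2 with w_i = p for y_i > z_i and
// 1 - p otherwise. The normal matrix diag(w) + lam * D2'D2 is symmetric
// pentadiagonal, solved by a banded LDL^T factorisation in O(n).

// [[Rcpp::export]]
NumericMatrix als_baseline_cpp(NumericMatrix Y, double lam, double p,
                               int maxit) {
  const int nrow = Y.nrow();
  const int n = Y.ncol();
  NumericMatrix Z(nrow, n);
  if (n < 3) {
    // too short for a second-difference penalty; baseline = signal
    for (int r = 0; r < nrow; ++r)
      for (int j = 0; j < n; ++j) Z(r, j) = Y(r, j);
    return Z;
  }

  // diagonals of lam * D2'D2 (D2 = second-difference operator)
  std::vector<double> pen0(n, 0.0), pen1(n - 1, 0.0), pen2(n - 2, 0.0);
  for (int j = 0; j + 2 < n; ++j) {
    pen0[j] += lam;
    pen0[j + 1] += 4.0 * lam;
    pen0[j + 2] += lam;
    pen1[j] += -2.0 * lam;
    pen1[j + 1] += -2.0 * lam;
    pen2[j] += lam;
  }

  std::vector<double> w(n), d0(n), D(n), l1(n - 1), l2(n - 2), c(n), z(n);

  for (int r = 0; r < nrow; ++r) {
    for (int j = 0; j < n; ++j) w[j] = 1.0;
    for (int it = 0; it < maxit; ++it) {
      // assemble banded system
      for (int j = 0; j < n; ++j) d0[j] = w[j] + pen0[j];
      // LDL^T factorisation, bandwidth 2
      for (int i = 0; i < n; ++i) {
        double di = d0[i];
        if (i >= 1) di -= l1[i - 1] * l1[i - 1] * D[i - 1];
        if (i >= 2) di -= l2[i - 2] * l2[i - 2] * D[i - 2];
        D[i] = di;
        if (i + 1 < n) {
          double v = pen1[i];
          if (i >= 1) v -= l1[i - 1] * l2[i - 1] * D[i - 1];
          l1[i] = v / D[i];
        }
        if (i + 2 < n) l2[i] = pen2[i] / D[i];
      }
      // forward substitution L c = w*y
      for (int i = 0; i < n; ++i) {
        double v = w[i] * Y(r, i);
        if (i >= 1) v -= l1[i - 1] * c[i - 1];
        if (i >= 2) v -= l2[i - 2] * c[i - 2];
        c[i] = v;
      }
      for (int i = 0; i < n; ++i) c[i] /= D[i];
      // backward substitution L^T z = c
      for (int i = n - 1; i >= 0; --i) {
        double v = c[i];
        if (i + 1 < n) v -= l1[i] * z[i + 1];
        if (i + 2 < n) v -= l2[i] * z[i + 2];
        z[i] = v;
      }
      // asymmetric reweighting
      bool changed = false;
      for (int j = 0; j < n; ++j) {
        double wj = (Y(r, j) > z[j]) ? p : (1.0 - p);
        if (wj != w[j]) changed = true;
        w[j] = wj;
      }
      if (!changed && it > 0) break;
    }
    for (int j = 0; j < n; ++j) Z(r, j) = z[j];
  }
  return Z;
}
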