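#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Euclidean projection of every column of M onto the probability simplex.
// Uses Condat's O(m)-average algorithm to locate the support, then
// recomputes the threshold exactly over the detected support for numerical
// robustness. Hot loop of the archetypal solver.
// [[Rcpp::export(name = ".proj_simplex_cols")]]
NumericMatrix proj_simplex_cols(NumericMatrix M) {
  const int m = M.nrow(), n = M.ncol();
  NumericMatrix out(m, n);
  std::vector<double> v(m), vt(m);

  for (int j = 0; j < n; ++j) {
    const double* y = &M(0, j);
    int nv = 0, nvt = 0;
    v[nv++] = y[0];
    double rho = y[0] - 1.0;

    for (int i = 1; i < m; ++i) {
      const double yi = y[i];
      if (yi > rho) {
        rho += (yi - rho) / (nv + 1);
        if (rho > yi - 1.0) {
          v[nv++] = yi;
        } else {
          for (int t = 0; t < nv; ++t) vt[nvt++] = v[t];
          nv = 0;
          v[nv++] = yi;
          rho = yi - 1.0;
        }
      }
    }
    for (int t = 0; t < nvt; ++t) {
      const double w = vt[t];
      if (w > rho) {
        v[nv++] = w;
        rho += (w - rho) / nv;
      }
    }
    bool again = true;
    while (again) {
      again = false;
      for (int i = 0; i < nv;) {
        if (v[i] <= rho) {
          const double w = v[i];
          v[i] = v[--nv];
          rho += (rho - w) / nv;
          again = true;
        } else {
          ++i;
        }
      }
    }
    // exact threshold over the detected support
    double s = 0.0;
    int cnt = 0;
    for (int i = 0; i < m; ++i) {
      if (y[i] > rho) { s += y[i]; ++cnt; }
    }
    const double tau = (s - 1.0) / cnt;
    for (int i = 0; i < m; ++i) {
      const double x = y[i] - tau;
      out(i, j) = x > 0 ? x : 0.0;
    }
  }
  return out;
}
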