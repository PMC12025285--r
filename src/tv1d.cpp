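#include <Rcpp.h>
using namespace Rcpp;

// Direct O(n) solver for the 1-D total-variation proximity problem
//   min_x 0.5 * sum_i (x_i - y_i)^2 + lam * sum_{i<n} |x_{i+1} - x_i|
// (taut-string sweep with running bounds). Exact up to floating point;
// no iteration, no tolerance.
static void tv1d_condat(const double* y, double* x, const int n,
                        const double lam) {
  if (n <= 0) return;
  if (n == 1 || lam <= 0.0) {
    for (int i = 0; i < n; ++i) x[i] = y[i];
    return;
  }
  int k = 0, k0 = 0, kminus = 0, kplus = 0;
  double umin = lam, umax = -lam;
  double vmin = y[0] - lam, vmax = y[0] + lam;
  const double twolam = 2.0 * lam;
  const int last = n - 1;
  for (;;) {
    while (k == last) {
      if (umin < 0.0) {              // negative jump is forced
        do x[k0++] = vmin; while (k0 <= kminus);
        kminus = k = k0;
        vmin = y[k];
        umin = lam;
        umax = y[k] + lam - vmax;
      } else if (umax > 0.0) {       // positive jump is forced
        do x[k0++] = vmax; while (k0 <= kplus);
        kplus = k = k0;
        vmax = y[k];
        umax = -lam;
        umin = y[k] - lam - vmin;
      } else {                       // string is taut: flush and finish
        vmin += umin / (k - k0 + 1);
        do x[k0++] = vmin; while (k0 <= k);
        return;
      }
    }
    if (y[k + 1] + umin < vmin - lam) {          // negative jump
      do x[k0++] = vmin; while (k0 <= kminus);
      kplus = kminus = k = k0;
      vmin = y[k];
      vmax = y[k] + twolam;
      umin = lam;
      umax = -lam;
    } else if (y[k + 1] + umax > vmax + lam) {   // positive jump
      do x[k0++] = vmax; while (k0 <= kplus);
      kplus = kminus = k = k0;
      vmax = y[k];
      vmin = y[k] - twolam;
      umin = lam;
      umax = -lam;
    } else {                                     // no jump: extend segment
      ++k;
      umin += y[k] - vmin;
      umax += y[k] - vmax;
      if (umin >= lam) {
        vmin += (umin - lam) / (k - k0 + 1);
        umin = lam;
        kminus = k;
      }
      if (umax <= -lam) {
        vmax += (umax + lam) / (k - k0 + 1);
        umax = -lam;
        kplus = k;
      }
    }
  }
}

// [[Rcpp::export(name = ".tv1d")]]
NumericVector tv1d_cpp(NumericVector y, double lam) {
  const int n = y.size();
  NumericVector x(n);
  tv1d_condat(y.begin(), x.begin(), n, lam);
  return x;
}

// [[Rcpp::export(name = ".tv1d_rows")]]
NumericMatrix tv1d_rows_cpp(NumericMatrix V, double lam) {
  const int d = V.nrow(), T = V.ncol();
  NumericMatrix out(d, T);
  std::vector<double> row(T), res(T);
  for (int i = 0; i < d; ++i) {
    for (int t = 0; t < T; ++t) row[t] = V(i, t);
    tv1d_condat(row.data(), res.data(), T, lam);
    for (int t = 0; t < T; ++t) out(i, t) = res[t];
  }
  return out;
}
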