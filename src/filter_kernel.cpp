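#include <Rcpp.h>
using namespace Rcpp;

static void iir_pass(const std::vector<double>& x, std::vector<double>& y,
                     const NumericVector& b, const NumericVector& a) {
  const int n = x.size(), nb = b.size(), na = a.size();
  for (int t = 0; t < n; ++t) {
    double acc = 0.0;
    for (int j = 0; j < nb && j <= t; ++j) acc += b[j] * x[t - j];
    for (int j = 1; j < na && j <= t; ++j) acc -= a[j] * y[t - j];
    y[t] = acc;
  }
}

// Zero-phase (forward-backward) IIR filtering with edge reflection padding
// to suppress start-up transients. a is normalized (a[0] = 1).
// [[Rcpp::export]]
NumericVector zero_phase_kernel(NumericVector x, NumericVector b,
                                NumericVector a, int n_pad) {
  const int n = x.size();
  if (n < 2) return clone(x);
  const int np = std::min(n - 1, n_pad);
  const int m = n + 2 * np;
  std::vector<double> xp(m), tmp(m);
  for (int k = 0; k < np; ++k) xp[k] = 2.0 * x[0] - x[np - k];
  for (int t = 0; t < n; ++t) xp[np + t] = x[t];
  for (int k = 0; k < np; ++k) xp[np + n + k] = 2.0 * x[n - 1] - x[n - 2 - k];
  iir_pass(xp, tmp, b, a);
  std::reverse(tmp.begin(), tmp.end());
  iir_pass(tmp, xp, b, a);
  std::reverse(xp.begin(), xp.end());
  NumericVector out(n);
  for (int t = 0; t < n; ++t) out[t] = xp[np + t];
  return out;
}
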