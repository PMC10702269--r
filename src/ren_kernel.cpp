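#include <Rcpp.h>
using namespace Rcpp;

// Relative entropy (max directional KL, nats) for every unordered channel
// pair of a segment stack, on shared equal-width histogram bins spanning the
// pooled range of the two series.
//
// data: 4-d array [segment, channel, band, sample]; every series is expected
// to be finite (degenerate segments are excluded upstream).
// Pair order matches utils::combn(n_channels, 2): (1,2),(1,3),...,(2,3),...
//
// Probabilities are (count/n + eps) / (1 + n_bins*eps), mirroring the R-level
// amplitude_distribution().
// [[Rcpp::export]]
NumericVector ren_pairs_kernel(NumericVector data, int n_bins, double eps) {
  IntegerVector dim = data.attr("dim");
  if (dim.size() != 4) stop("data must be a 4-d array [segment, channel, band, sample]");
  const int ns = dim[0], nc = dim[1], nb = dim[2], nt = dim[3];
  if (n_bins < 2) stop("n_bins must be >= 2");
  if (nt < n_bins) stop("fewer samples than bins: cannot estimate distributions");
  const int np = nc * (nc - 1) / 2;

  NumericVector out(static_cast<R_xlen_t>(ns) * np * nb);
  out.attr("dim") = IntegerVector::create(ns, np, nb);

  // contiguous per-(segment, band) slice buffer: channel-major series, plus
  // per-channel ranges, so the pair loop reads sequential memory only
  std::vector<double> slice(static_cast<size_t>(nc) * nt);
  std::vector<double> ch_lo(nc), ch_hi(nc);
  std::vector<int> cx(n_bins), cy(n_bins);
  const double denom = 1.0 + n_bins * eps;
  const double inv_nt = 1.0 / nt;

  for (int b = 0; b < nb; ++b) {
    for (int s = 0; s < ns; ++s) {
      for (int c = 0; c < nc; ++c) {
        double lo = R_PosInf, hi = R_NegInf;
        double *dst = &slice[static_cast<size_t>(c) * nt];
        const R_xlen_t base = s + static_cast<R_xlen_t>(ns) * (c + static_cast<R_xlen_t>(nc) * b);
        const R_xlen_t stride = static_cast<R_xlen_t>(ns) * nc * nb;
        for (int t = 0; t < nt; ++t) {
          const double v = data[base + stride * t];
          dst[t] = v;
          if (v < lo) lo = v;
          if (v > hi) hi = v;
        }
        ch_lo[c] = lo;
        ch_hi[c] = hi;
      }
      int pidx = 0;
      for (int i = 0; i < nc; ++i) {
        for (int j = i + 1; j < nc; ++j, ++pidx) {
          const double lo = ch_lo[i] < ch_lo[j] ? ch_lo[i] : ch_lo[j];
          const double hi = ch_hi[i] > ch_hi[j] ? ch_hi[i] : ch_hi[j];
          double ren = 0.0;
          if (hi - lo > 0.0) {
            const double scale = n_bins / (hi - lo);
            std::fill(cx.begin(), cx.end(), 0);
            std::fill(cy.begin(), cy.end(), 0);
            const double *xi = &slice[static_cast<size_t>(i) * nt];
            const double *yj = &slice[static_cast<size_t>(j) * nt];
            for (int t = 0; t < nt; ++t) {
              int bx = static_cast<int>((xi[t] - lo) * scale);
              int by = static_cast<int>((yj[t] - lo) * scale);
              if (bx >= n_bins) bx = n_bins - 1;
              if (by >= n_bins) by = n_bins - 1;
              ++cx[bx]; ++cy[by];
            }
            double klpq = 0.0, klqp = 0.0;
            for (int k = 0; k < n_bins; ++k) {
              const double p = (cx[k] * inv_nt + eps) / denom;
              const double q = (cy[k] * inv_nt + eps) / denom;
              const double lr = std::log(p / q);
              klpq += p * lr;
              klqp -= q * lr;
            }
            ren = klpq > klqp ? klpq : klqp;
            if (ren < 0.0) ren = 0.0;  // guard against rounding just below zero
          }
          out[s + static_cast<R_xlen_t>(ns) * (pidx + static_cast<R_xlen_t>(np) * b)] = ren;
        }
      }
    }
  }
  return out;
}
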