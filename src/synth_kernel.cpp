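#include <Rcpp.h>
using namespace Rcpp;

// Synthesize one seizure window: every contact is a sum over bands of
// band-limited Gaussian noise (white noise through the band's IIR bandpass)
// modulated by per-block log-normal gains. Gain blocks tile backward from
// onset over the pre-ictal part and forward over the ictal part, so block
// boundaries align with the 2.5 s analysis segments anchored at onset.
//
// B, A: filter coefficient matrices (n_band x n_coef), A normalized (a0 = 1).
// amp: per-band amplitude. sd_pre, sd_ict: per-band log-sd of block gains.
// Uses R's RNG (deterministic under set.seed).
// [[Rcpp::export]]
NumericMatrix synth_window_kernel(int n_contacts, int n_pre, int n_ict,
                                  NumericMatrix B, NumericMatrix A,
                                  NumericVector amp, NumericVector sd_pre,
                                  NumericVector sd_ict, int block_samps) {
  const int n = n_pre + n_ict;
  const int n_band = B.nrow();
  const int nb = B.ncol(), na = A.ncol();
  NumericMatrix out(n_contacts, n);
  std::vector<double> x(n), y(n);
  const int nbp = n_pre > 0 ? (n_pre + block_samps - 1) / block_samps : 0;
  const int nbi = n_ict > 0 ? (n_ict + block_samps - 1) / block_samps : 0;
  // backward tiling: first pre block may be partial at the window start
  const int pre_head = nbp > 0 ? n_pre - (nbp - 1) * block_samps : 0;
  std::vector<double> g(std::max(nbp + nbi, 1));

  for (int ct = 0; ct < n_contacts; ++ct) {
    for (int b = 0; b < n_band; ++b) {
      for (int t = 0; t < n; ++t) x[t] = norm_rand();
      for (int t = 0; t < n; ++t) {
        double acc = 0.0;
        for (int j = 0; j < nb && j <= t; ++j) acc += B(b, j) * x[t - j];
        for (int j = 1; j < na && j <= t; ++j) acc -= A(b, j) * y[t - j];
        y[t] = acc;
      }
      for (int k = 0; k < nbp; ++k) g[k] = std::exp(sd_pre[b] * norm_rand());
      for (int k = 0; k < nbi; ++k) g[nbp + k] = std::exp(sd_ict[b] * norm_rand());
      for (int t = 0; t < n; ++t) {
        int blk;
        if (t < n_pre) {
          blk = t < pre_head ? 0 : 1 + (t - pre_head) / block_samps;
        } else {
          blk = nbp + (t - n_pre) / block_samps;
        }
        out(ct, t) += amp[b] * g[blk] * y[t];
      }
    }
  }
  return out;
}
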