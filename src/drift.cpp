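#include <Rcpp.h>
using namespace Rcpp;

// Neutral Wright-Fisher drift of population allele frequencies.
//
// Each site evolves independently: the allele count in the next generation is
// Binomial(2N, p_t). Sites absorbed at 0 or 1 stay there (no recurrent
// mutation), so the per-site loop exits early at absorption. For interior
// frequencies with np(1-p) > 30 the binomial draw is replaced by the
// standard rounded-normal approximation (continuity-corrected, clamped to
// [0, 2N]); near the boundaries the draw stays exact so absorption dynamics
// are untouched. Draws come from R's RNG stream, so results are reproducible
// under set.seed().
// [[Rcpp::export]]
NumericVector wf_drift_cpp(NumericVector p, int gens, int N) {
  const int n = p.size();
  const double twoN = 2.0 * N;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double x = p[i];
    for (int t = 0; t < gens; ++t) {
      if (x <= 0.0 || x >= 1.0) break;
      double np = twoN * x;
      double v = np * (1.0 - x);
      if (v > 30.0) {
        double k = std::floor(np + std::sqrt(v) * R::norm_rand() + 0.5);
        if (k < 0) k = 0;
        if (k > twoN) k = twoN;
        x = k / twoN;
      } else {
        x = R::rbinom(twoN, x) / twoN;
      }
    }
    out[i] = x;
  }
  return out;
}
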