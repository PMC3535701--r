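#include <Rcpp.h>
using namespace Rcpp;

// All-pairs mutual information over pre-discretized rows.
// disc: nodes x samples integer matrix with bin codes in 1..n_bins.
// Returns the symmetric MI matrix in natural-log units (diagonal = 0).
// [[Rcpp::export(name = ".mi_matrix_cpp")]]
NumericMatrix mi_matrix_cpp(IntegerMatrix disc, int n_bins) {
  const int n = disc.nrow(), s = disc.ncol();
  NumericMatrix out(n, n);
  if (s == 0) return out;
  // per-row marginal counts
  std::vector<std::vector<int> > marg(n, std::vector<int>(n_bins, 0));
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < s; ++k)
      marg[i][disc(i, k) - 1]++;
  std::vector<int> joint(n_bins * n_bins);
  const double inv_s = 1.0 / s;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      std::fill(joint.begin(), joint.end(), 0);
      for (int k = 0; k < s; ++k)
        joint[(disc(i, k) - 1) * n_bins + (disc(j, k) - 1)]++;
      double mi = 0.0;
      for (int a = 0; a < n_bins; ++a) {
        if (marg[i][a] == 0) continue;
        for (int b = 0; b < n_bins; ++b) {
          const int c = joint[a * n_bins + b];
          if (c == 0 || marg[j][b] == 0) continue;
          const double pxy = c * inv_s;
          mi += pxy * std::log(pxy / (marg[i][a] * inv_s * marg[j][b] * inv_s));
        }
      }
      if (mi < 0) mi = 0; // guard against round-off
      out(i, j) = mi;
      out(j, i) = mi;
    }
  }
  return out;
}
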