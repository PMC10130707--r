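#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Evaluate persistence-landscape layers at given abscissae:
// lambda_k(t) = k-th largest of max(0, min(t - b_i, d_i - t)).

// [[Rcpp::export]]
NumericMatrix landscape_eval_cpp(NumericMatrix bd, NumericVector ts,
                                 int max_layers) {
  const int m = bd.nrow(), M = ts.size();
  NumericMatrix out(max_layers, M);  // zero-initialized
  std::vector<double> vals(m);
  for (int s = 0; s < M; ++s) {
    const double t = ts[s];
    int cnt = 0;
    for (int i = 0; i < m; ++i) {
      double v = std::min(t - bd(i, 0), bd(i, 1) - t);
      if (v > 0) vals[cnt++] = v;
    }
    const int K = std::min(max_layers, cnt);
    std::partial_sort(vals.begin(), vals.begin() + K, vals.begin() + cnt,
                      std::greater<double>());
    for (int k = 0; k < K; ++k) out(k, s) = vals[k];
  }
  return out;
}
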