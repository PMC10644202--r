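#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Exhaustive best-split search for the regression-tree engine: maximizes
// sum_L^2/(n_L + lambda) + sum_R^2/(n_R + lambda) over features and
// thresholds. Returns the best feature (1-based), threshold and gain.

// [[Rcpp::export(name = ".best_split_cpp")]]
List best_split_cpp(NumericMatrix X, NumericVector r, IntegerVector idx,
                    IntegerVector features, int min_leaf, double lambda) {
  const int n = idx.size();
  double total = 0.0;
  for (int i = 0; i < n; ++i) total += r[idx[i] - 1];
  const double parent = total * total / (n + lambda);

  double best_gain = R_NegInf, best_thr = 0.0;
  int best_feat = -1;

  std::vector<int> ord(n);
  std::vector<double> xv(n), rv(n);

  for (int fi = 0; fi < features.size(); ++fi) {
    const int f = features[fi] - 1;
    const double *col = &X(0, f);
    for (int i = 0; i < n; ++i) {
      xv[i] = col[idx[i] - 1];
      rv[i] = r[idx[i] - 1];
      ord[i] = i;
    }
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return xv[a] < xv[b]; });
    double cs = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      cs += rv[ord[i]];
      const int nl = i + 1;
      if (nl < min_leaf || (n - nl) < min_leaf) continue;
      if (xv[ord[i]] >= xv[ord[i + 1]]) continue;
      const double score = cs * cs / (nl + lambda) +
        (total - cs) * (total - cs) / (n - nl + lambda);
      const double gain = score - parent;
      if (gain > best_gain) {
        best_gain = gain;
        best_feat = f + 1;
        best_thr = 0.5 * (xv[ord[i]] + xv[ord[i + 1]]);
      }
    }
  }
  return List::create(_["gain"] = best_gain, _["feature"] = best_feat,
                      _["threshold"] = best_thr);
}
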