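#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exhaustive CART split search with Gini impurity.
//
// For every feature, samples are sorted and candidate thresholds are the
// midpoints between consecutive distinct values; the split assigns
// x_j <= t to the left child. The score is the weighted child impurity
// G = (n_L * H_L + n_R * H_R) / N. Ties are broken deterministically:
// the first strictly better candidate wins, scanning features in index
// order and thresholds in ascending order.
//
// Returns feature = -1 when every sample is identical in every feature
// (no valid split).
// [[Rcpp::export(name = ".cart_best_split")]]
List cart_best_split(NumericMatrix X, IntegerVector y,
                     IntegerVector rows, int n_classes) {
  const int n = rows.size();
  const int p = X.ncol();
  double best_score = R_PosInf;
  int best_j = -1;
  double best_t = NA_REAL;

  std::vector<int> ord(n);
  std::vector<double> v(n);
  std::vector<int> lab(n);
  std::vector<double> left_cnt(n_classes);
  std::vector<double> total_cnt(n_classes);

  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) {
      v[i] = X(rows[i], j);
      lab[i] = y[rows[i]];
      ord[i] = i;
    }
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return v[a] < v[b]; });
    std::fill(left_cnt.begin(), left_cnt.end(), 0.0);
    std::fill(total_cnt.begin(), total_cnt.end(), 0.0);
    for (int i = 0; i < n; ++i) total_cnt[lab[i]] += 1.0;

    for (int i = 0; i < n - 1; ++i) {
      left_cnt[lab[ord[i]]] += 1.0;
      double lo = v[ord[i]], hi = v[ord[i + 1]];
      if (hi <= lo) continue; // not a distinct-value boundary
      double nl = i + 1, nr = n - nl;
      double gl = 1.0, gr = 1.0;
      for (int k = 0; k < n_classes; ++k) {
        double pl = left_cnt[k] / nl;
        double pr = (total_cnt[k] - left_cnt[k]) / nr;
        gl -= pl * pl;
        gr -= pr * pr;
      }
      double score = (nl * gl + nr * gr) / n;
      if (score < best_score) {
        best_score = score;
        best_j = j;
        best_t = lo + (hi - lo) / 2.0;
      }
    }
  }
  return List::create(_["feature"] = best_j + 1,
                      _["threshold"] = best_t,
                      _["score"] = best_score);
}
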