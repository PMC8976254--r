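// Gradient-boosted regression trees on a single predictor.
//
// With one input feature a depth-d regression tree partitions the real
// line into contiguous intervals, so each tree reduces to a sorted vector
// of thresholds plus one value per interval.  Squared-error boosting with
// shrinkage; split search is O(n) per node via prefix sums over the sorted
// training order.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Leaf { double upper; double value; };  // interval (-inf upto upper)

// Recursively split the sorted slice [lo, hi); append leaves in x-order.
void grow(const std::vector<double>& xs, const std::vector<double>& rs,
          int lo, int hi, int depth, int max_depth, int min_node,
          std::vector<Leaf>& leaves) {
  int n = hi - lo;
  double sum = 0.0;
  for (int i = lo; i < hi; ++i) sum += rs[i];
  bool can_split = depth < max_depth && n >= 2 * min_node &&
                   xs[hi - 1] > xs[lo];
  int best = -1;
  double best_gain = 1e-12, base = sum * sum / n;
  if (can_split) {
    double sl = 0.0;
    for (int i = lo; i < hi - 1; ++i) {
      sl += rs[i];
      int nl = i - lo + 1, nr = n - nl;
      if (nl < min_node || nr < min_node) continue;
      if (xs[i + 1] <= xs[i]) continue;  // no threshold between ties
      double sr = sum - sl;
      double gain = sl * sl / nl + sr * sr / nr - base;
      if (gain > best_gain) { best_gain = gain; best = i; }
    }
  }
  if (best < 0) {
    leaves.push_back({ (hi == (int)xs.size()) ? R_PosInf : xs[hi - 1],
                       sum / n });
    return;
  }
  grow(xs, rs, lo, best + 1, depth + 1, max_depth, min_node, leaves);
  grow(xs, rs, best + 1, hi, depth + 1, max_depth, min_node, leaves);
  // patch the boundary between the two subtrees to the midpoint threshold
  // (handled implicitly: left subtree's last leaf upper = xs[best], and
  // lookup uses x <= upper, so any x in (xs[best], xs[best+1]] goes right)
}

double tree_predict(const std::vector<Leaf>& leaves, double x) {
  for (size_t j = 0; j + 1 < leaves.size(); ++j)
    if (x <= leaves[j].upper) return leaves[j].value;
  return leaves.back().value;
}

}  // namespace

// [[Rcpp::export(name = ".boost_fit_predict")]]
List boost_fit_predict(NumericVector x_train, NumericVector y_train,
                       NumericVector x_test, int max_depth, int n_trees,
                       double shrinkage, int min_node) {
  int n = x_train.size(), m = x_test.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x_train[a] < x_train[b]; });
  std::vector<double> xs(n), f(n, 0.0), rs(n);
  for (int i = 0; i < n; ++i) xs[i] = x_train[ord[i]];
  double mean0 = Rcpp::mean(y_train);
  NumericVector pred_train(n, mean0), pred_test(m, mean0);
  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) rs[i] = y_train[ord[i]] - pred_train[ord[i]];
    std::vector<Leaf> leaves;
    grow(xs, rs, 0, n, 0, max_depth, min_node, leaves);
    if (leaves.size() == 1 && std::abs(leaves[0].value) < 1e-14) break;
    for (int i = 0; i < n; ++i)
      pred_train[ord[i]] += shrinkage * tree_predict(leaves, xs[i]);
    for (int j = 0; j < m; ++j)
      pred_test[j] += shrinkage * tree_predict(leaves, x_test[j]);
  }
  return List::create(_["train"] = pred_train, _["test"] = pred_test);
}
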