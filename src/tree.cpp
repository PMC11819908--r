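// Least-squares CART regression trees: the shared engine behind the
// random-forest (bootstrap + mtry) and gradient-boosting (shallow trees on
// residuals) families. Split search is exact: per candidate feature, node
// rows are sorted and the SSE-optimal threshold found by a prefix scan.
// Feature subsampling uses R's RNG, so results are reproducible under
// set.seed() on the R side.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

struct TreeBuf {
  std::vector<int> feature;      // -1 for leaves
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left, right;
  std::vector<double> value;     // node mean (prediction at leaves)
};

static void sample_features(int p, int mtry, std::vector<int> &out) {
  // partial Fisher-Yates with R's RNG
  std::vector<int> pool(p);
  for (int j = 0; j < p; ++j) pool[j] = j;
  out.clear();
  for (int k = 0; k < mtry; ++k) {
    int r = k + (int)(unif_rand() * (p - k));
    if (r >= p) r = p - 1;
    std::swap(pool[k], pool[r]);
    out.push_back(pool[k]);
  }
}

static int build_node(const NumericMatrix &X, const NumericVector &y,
                      std::vector<int> &rows, int lo, int hi, int depth,
                      int mtry, int max_depth, int min_node, TreeBuf &t) {
  const int n = hi - lo;
  double sum = 0.0, ss = 0.0;
  for (int i = lo; i < hi; ++i) {
    sum += y[rows[i]];
    ss += y[rows[i]] * y[rows[i]];
  }
  const double mean = sum / n;
  const double sse = ss - sum * sum / n;

  int node = (int)t.feature.size();
  t.feature.push_back(-1);
  t.threshold.push_back(0.0);
  t.left.push_back(-1);
  t.right.push_back(-1);
  t.value.push_back(mean);

  if (depth >= max_depth || n < 2 * min_node || sse <= 1e-12) return node;

  const int p = X.ncol();
  std::vector<int> feats;
  sample_features(p, std::min(mtry, p), feats);

  double best_gain = 1e-12;
  int best_f = -1;
  double best_thr = 0.0;

  std::vector<std::pair<double, double>> xy(n);
  for (size_t fi = 0; fi < feats.size(); ++fi) {
    const int f = feats[fi];
    for (int i = 0; i < n; ++i)
      xy[i] = std::make_pair(X(rows[lo + i], f), y[rows[lo + i]]);
    std::sort(xy.begin(), xy.end());
    if (xy.front().first == xy.back().first) continue;
    double lsum = 0.0;
    for (int i = 1; i < n; ++i) {
      lsum += xy[i - 1].second;
      if (xy[i - 1].first == xy[i].first) continue;
      if (i < min_node || n - i < min_node) continue;
      const double rsum = sum - lsum;
      // SSE reduction = lsum^2/nl + rsum^2/nr - sum^2/n
      const double gain =
          lsum * lsum / i + rsum * rsum / (n - i) - sum * sum / n;
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (xy[i - 1].first + xy[i].first);
      }
    }
  }
  if (best_f < 0) return node;

  // partition rows[lo..hi) in place
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(rows[i], best_f) <= best_thr) std::swap(rows[i], rows[mid++]);
  if (mid == lo || mid == hi) return node;  // numeric ties; keep as leaf

  t.feature[node] = best_f;
  t.threshold[node] = best_thr;
  int l = build_node(X, y, rows, lo, mid, depth + 1, mtry, max_depth,
                     min_node, t);
  t.left[node] = l;
  int r = build_node(X, y, rows, mid, hi, depth + 1, mtry, max_depth,
                     min_node, t);
  t.right[node] = r;
  return node;
}

// [[Rcpp::export]]
List cart_build(NumericMatrix X, NumericVector y, IntegerVector rows,
                int mtry, int max_depth, int min_node) {
  TreeBuf t;
  std::vector<int> rw(rows.begin(), rows.end());  // 0-based row indices
  build_node(X, y, rw, 0, (int)rw.size(), 0, mtry, max_depth, min_node, t);
  return List::create(_["feature"] = wrap(t.feature),
                      _["threshold"] = wrap(t.threshold),
                      _["left"] = wrap(t.left), _["right"] = wrap(t.right),
                      _["value"] = wrap(t.value));
}

// [[Rcpp::export]]
NumericVector cart_predict(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"];
  NumericVector value = tree["value"];
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
    }
    out[i] = value[node];
  }
  return out;
}
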