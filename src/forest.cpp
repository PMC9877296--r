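// Seeded random-forest classifier for small two-class expression matrices.
//
// The pipeline fits thousands of forests per run (one per disease group per
// Monte-Carlo repetition), each on a few dozen samples and at most a few
// hundred features, so the implementation favours exact reproducibility and
// low per-fit overhead over large-data tricks: a private xorshift64* RNG
// (identical streams on every platform, independent of R's RNG state),
// CART trees grown on bootstrap samples with gini splits over `mtry`
// randomly chosen features, and leaf class-frequency averaging across trees
// for probability output.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct Xorshift {
  uint64_t s;
  explicit Xorshift(uint64_t seed) {
    // splitmix64 scramble so small consecutive seeds give unrelated streams
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s = (z ^ (z >> 31)) | 1ULL;
  }
  uint64_t next() {
    s ^= s >> 12;
    s ^= s << 25;
    s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct Node {
  int feature = -1;      // -1 marks a leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  double prob = 0.0;     // leaf: fraction of positive training samples
};

struct Tree {
  std::vector<Node> nodes;

  double predict(const NumericMatrix& X, int row) const {
    int i = 0;
    while (nodes[i].feature >= 0)
      i = (X(row, nodes[i].feature) <= nodes[i].threshold) ? nodes[i].left
                                                           : nodes[i].right;
    return nodes[i].prob;
  }
};

class Builder {
public:
  Builder(const NumericMatrix& X, const IntegerVector& y, int mtry,
          int min_node, int max_depth, Xorshift& rng)
      : X_(X), y_(y), mtry_(mtry), min_node_(min_node),
        max_depth_(max_depth), rng_(rng), feat_pool_(X.ncol()) {
    for (int j = 0; j < X.ncol(); ++j) feat_pool_[j] = j;
  }

  Tree grow(std::vector<int>& sample_idx) {
    tree_.nodes.clear();
    build(sample_idx, 0, static_cast<int>(sample_idx.size()), 0);
    return tree_;
  }

private:
  int leaf(int lo, int hi, int n_pos, std::vector<int>& idx) {
    (void)idx;
    Node nd;
    nd.prob = static_cast<double>(n_pos) / (hi - lo);
    tree_.nodes.push_back(nd);
    return static_cast<int>(tree_.nodes.size()) - 1;
  }

  // Grow the subtree over idx[lo, hi); returns the node index.
  int build(std::vector<int>& idx, int lo, int hi, int depth) {
    int n = hi - lo;
    int n_pos = 0;
    for (int i = lo; i < hi; ++i) n_pos += y_[idx[i]];
    if (n_pos == 0 || n_pos == n || n < 2 * min_node_ || depth >= max_depth_)
      return leaf(lo, hi, n_pos, idx);

    // best gini split over mtry features drawn without replacement
    double best_gain = 0.0;
    int best_feat = -1;
    double best_thr = 0.0;
    const double parent = gini(n_pos, n);
    int pool = static_cast<int>(feat_pool_.size());
    for (int k = 0; k < mtry_ && pool > 0; ++k, --pool) {
      int pick = rng_.below(pool);
      std::swap(feat_pool_[pick], feat_pool_[pool - 1]);
      int j = feat_pool_[pool - 1];
      // sort node samples by feature value
      order_.assign(idx.begin() + lo, idx.begin() + hi);
      std::sort(order_.begin(), order_.end(), [&](int a, int b) {
        double va = X_(a, j), vb = X_(b, j);
        return va < vb || (va == vb && a < b);  // stable under ties
      });
      int left_n = 0, left_pos = 0;
      for (int i = 0; i + 1 < n; ++i) {
        ++left_n;
        left_pos += y_[order_[i]];
        double v = X_(order_[i], j), vn = X_(order_[i + 1], j);
        if (v == vn) continue;  // can only cut between distinct values
        if (left_n < min_node_ || n - left_n < min_node_) continue;
        double g = parent -
                   (left_n * gini(left_pos, left_n) +
                    (n - left_n) * gini(n_pos - left_pos, n - left_n)) / n;
        if (g > best_gain + 1e-12) {
          best_gain = g;
          best_feat = j;
          best_thr = v + (vn - v) / 2.0;
        }
      }
    }
    if (best_feat < 0) return leaf(lo, hi, n_pos, idx);

    int mid = static_cast<int>(
        std::partition(idx.begin() + lo, idx.begin() + hi,
                       [&](int a) { return X_(a, best_feat) <= best_thr; }) -
        idx.begin());
    if (mid == lo || mid == hi) return leaf(lo, hi, n_pos, idx);

    int self = static_cast<int>(tree_.nodes.size());
    tree_.nodes.push_back(Node());
    tree_.nodes[self].feature = best_feat;
    tree_.nodes[self].threshold = best_thr;
    int l = build(idx, lo, mid, depth + 1);
    int r = build(idx, mid, hi, depth + 1);
    tree_.nodes[self].left = l;
    tree_.nodes[self].right = r;
    return self;
  }

  static double gini(int n_pos, int n) {
    double p = static_cast<double>(n_pos) / n;
    return 2.0 * p * (1.0 - p);
  }

  const NumericMatrix& X_;
  const IntegerVector& y_;
  int mtry_, min_node_, max_depth_;
  Xorshift& rng_;
  std::vector<int> feat_pool_, order_;
  Tree tree_;
};

}  // namespace

// Fit a random forest on (X, y) and return positive-class probabilities for
// the rows of Xtest. y is 0/1 with 1 = "pos". mtry <= 0 requests the
// conventional floor(sqrt(p)) default.
// [[Rcpp::export(name = ".rf_fit_predict")]]
NumericVector rf_fit_predict(NumericMatrix X, IntegerVector y,
                             NumericMatrix Xtest, int ntree, int mtry,
                             int min_node, int max_depth, double seed) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length(y) != nrow(X)");
  if (Xtest.ncol() != p) stop("train and test feature counts differ");
  if (ntree < 1) stop("ntree must be >= 1");
  if (mtry <= 0) mtry = std::max(1, static_cast<int>(std::sqrt(static_cast<double>(p))));
  mtry = std::min(mtry, p);

  Xorshift rng(static_cast<uint64_t>(seed));
  Builder builder(X, y, mtry, min_node, max_depth, rng);

  NumericVector out(Xtest.nrow());
  std::vector<int> boot(n);
  for (int t = 0; t < ntree; ++t) {
    for (int i = 0; i < n; ++i) boot[i] = rng.below(n);
    Tree tree = builder.grow(boot);
    for (int r = 0; r < Xtest.nrow(); ++r) out[r] += tree.predict(Xtest, r);
  }
  return out / static_cast<double>(ntree);
}
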