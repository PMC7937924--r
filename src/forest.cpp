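// Compact CART forest used by the tree-based classifiers and the
// RF-importance selector.  Splits minimise node SSE, which for 0/1
// responses is proportional to the gini criterion, so one code path
// serves classification probabilities, regression on boosting
// gradients, and impurity importances.  All randomness flows through
// R's RNG so results are reproducible from set.seed().
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Tree {
  // parallel node arrays; feature == -1 marks a leaf
  std::vector<int> feature;
  std::vector<double> threshold;
  std::vector<int> left;
  std::vector<int> right;
  std::vector<double> value;
  std::vector<double> nnode;
};

struct BuildCtx {
  const NumericMatrix& X;
  const NumericVector& y;
  int mtry;
  int max_depth;      // <=0: unlimited
  int min_leaf;
  bool extra;         // random cutpoints instead of exhaustive scan
  std::vector<double>& importance; // accumulated SSE decrease
  double n_total;
  BuildCtx(const NumericMatrix& X_, const NumericVector& y_, int mtry_,
           int max_depth_, int min_leaf_, bool extra_,
           std::vector<double>& imp_, double ntot_)
      : X(X_), y(y_), mtry(mtry_), max_depth(max_depth_),
        min_leaf(min_leaf_), extra(extra_), importance(imp_),
        n_total(ntot_) {}
};

inline int rand_int(int n) { // uniform on 0..n-1 via R RNG
  int k = (int)std::floor(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

void sample_features(int p, int mtry, std::vector<int>& scratch,
                     std::vector<int>& out) {
  // partial Fisher-Yates on a persistent identity permutation
  for (int i = 0; i < mtry; ++i) {
    int j = i + rand_int(p - i);
    std::swap(scratch[i], scratch[j]);
    out[i] = scratch[i];
  }
  // restore identity so the next call starts clean
  std::sort(scratch.begin(), scratch.begin() + mtry);
  for (int i = 0; i < p; ++i) scratch[i] = i;
}

int build_node(BuildCtx& ctx, Tree& tree, std::vector<int>& idx,
               int begin, int end, int depth) {
  int n = end - begin;
  double sum = 0.0, sum2 = 0.0;
  for (int i = begin; i < end; ++i) {
    double v = ctx.y[idx[i]];
    sum += v; sum2 += v * v;
  }
  double mean = sum / n;
  double sse = sum2 - sum * sum / n;
  if (sse < 0) sse = 0;

  int node = (int)tree.feature.size();
  tree.feature.push_back(-1);
  tree.threshold.push_back(0.0);
  tree.left.push_back(-1);
  tree.right.push_back(-1);
  tree.value.push_back(mean);
  tree.nnode.push_back((double)n);

  bool stop = n < 2 * ctx.min_leaf || sse <= 1e-12 ||
              (ctx.max_depth > 0 && depth >= ctx.max_depth);
  if (stop) return node;

  int p = ctx.X.ncol();
  static thread_local std::vector<int> scratch, feats;
  if ((int)scratch.size() != p) {
    scratch.resize(p);
    for (int i = 0; i < p; ++i) scratch[i] = i;
  }
  feats.resize(ctx.mtry);
  sample_features(p, ctx.mtry, scratch, feats);

  double best_gain = 0.0, best_thr = 0.0;
  int best_f = -1;
  std::vector<double> vals(n);
  std::vector<int> ord(n);

  const double* xbase = ctx.X.begin();
  const int nrowX = ctx.X.nrow();
  for (int fi = 0; fi < ctx.mtry; ++fi) {
    int f = feats[fi];
    const double* col = xbase + (size_t)f * nrowX;
    for (int i = 0; i < n; ++i) vals[i] = col[idx[begin + i]];
    if (ctx.extra) {
      double lo = *std::min_element(vals.begin(), vals.end());
      double hi = *std::max_element(vals.begin(), vals.end());
      if (hi <= lo) continue;
      double thr = lo + unif_rand() * (hi - lo);
      double ls = 0, ls2 = 0; int ln = 0;
      for (int i = 0; i < n; ++i) {
        if (vals[i] <= thr) {
          double v = ctx.y[idx[begin + i]];
          ls += v; ls2 += v * v; ++ln;
        }
      }
      int rn = n - ln;
      if (ln < ctx.min_leaf || rn < ctx.min_leaf) continue;
      double rs = sum - ls, rs2 = sum2 - ls2;
      double child = (ls2 - ls * ls / ln) + (rs2 - rs * rs / rn);
      double gain = sse - child;
      if (gain > best_gain + 1e-12) {
        best_gain = gain; best_f = f; best_thr = thr;
      }
    } else {
      for (int i = 0; i < n; ++i) ord[i] = i;
      std::sort(ord.begin(), ord.end(),
                [&](int a, int b) { return vals[a] < vals[b]; });
      double ls = 0, ls2 = 0;
      for (int i = 0; i < n - 1; ++i) {
        double v = ctx.y[idx[begin + ord[i]]];
        ls += v; ls2 += v * v;
        double xv = vals[ord[i]], xnext = vals[ord[i + 1]];
        if (xnext <= xv) continue; // not a boundary between distinct values
        int ln = i + 1, rn = n - ln;
        if (ln < ctx.min_leaf || rn < ctx.min_leaf) continue;
        double rs = sum - ls, rs2 = sum2 - ls2;
        double child = (ls2 - ls * ls / ln) + (rs2 - rs * rs / rn);
        double gain = sse - child;
        if (gain > best_gain + 1e-12) {
          best_gain = gain; best_f = f;
          best_thr = xv + (xnext - xv) / 2.0;
        }
      }
    }
  }

  if (best_f < 0) return node; // no admissible split

  ctx.importance[best_f] += best_gain / ctx.n_total;

  // partition idx[begin, end) in place
  const double* bcol = xbase + (size_t)best_f * nrowX;
  int mid = begin;
  for (int i = begin; i < end; ++i)
    if (bcol[idx[i]] <= best_thr) std::swap(idx[i], idx[mid++]);

  tree.feature[node] = best_f;
  tree.threshold[node] = best_thr;
  int l = build_node(ctx, tree, idx, begin, mid, depth + 1);
  int r = build_node(ctx, tree, idx, mid, end, depth + 1);
  tree.left[node] = l;
  tree.right[node] = r;
  return node;
}

NumericMatrix tree_to_matrix(const Tree& t) {
  int m = (int)t.feature.size();
  NumericMatrix out(m, 6);
  for (int i = 0; i < m; ++i) {
    out(i, 0) = t.feature[i];
    out(i, 1) = t.threshold[i];
    out(i, 2) = t.left[i];
    out(i, 3) = t.right[i];
    out(i, 4) = t.value[i];
    out(i, 5) = t.nnode[i];
  }
  colnames(out) = CharacterVector::create("feature", "threshold", "left",
                                          "right", "value", "n");
  return out;
}

int descend(const NumericMatrix& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while ((int)tree(node, 0) >= 0) {
    int f = (int)tree(node, 0);
    node = X(row, f) <= tree(node, 1) ? (int)tree(node, 2)
                                      : (int)tree(node, 3);
  }
  return node;
}

} // namespace

// [[Rcpp::export]]
List cpp_forest_fit(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                    int max_depth, int min_leaf, bool balanced,
                    bool bootstrap, double sample_frac, bool extra) {
  int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  std::vector<double> importance(p, 0.0);
  List trees(n_trees);
  IntegerMatrix bag_counts(n_trees, 2);

  // class index lists for balanced bootstrap (y assumed 0/1 there)
  std::vector<int> cls0, cls1;
  if (balanced) {
    for (int i = 0; i < n; ++i) (y[i] > 0.5 ? cls1 : cls0).push_back(i);
    if (cls0.empty() || cls1.empty())
      stop("balanced forest requires both classes present");
  }

  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx;
    if (balanced) {
      // undersample each bootstrap to the minority size, per class
      int m = (int)std::min(cls0.size(), cls1.size());
      idx.reserve(2 * m);
      for (int i = 0; i < m; ++i) idx.push_back(cls0[rand_int((int)cls0.size())]);
      for (int i = 0; i < m; ++i) idx.push_back(cls1[rand_int((int)cls1.size())]);
    } else if (bootstrap) {
      idx.reserve(n);
      for (int i = 0; i < n; ++i) idx.push_back(rand_int(n));
    } else {
      int m = (int)std::floor(sample_frac * n + 0.5);
      if (m < 2) m = n < 2 ? n : 2;
      if (m >= n) {
        idx.resize(n);
        for (int i = 0; i < n; ++i) idx[i] = i;
      } else { // without replacement
        std::vector<int> all(n);
        for (int i = 0; i < n; ++i) all[i] = i;
        for (int i = 0; i < m; ++i) std::swap(all[i], all[i + rand_int(n - i)]);
        idx.assign(all.begin(), all.begin() + m);
      }
    }
    int c1 = 0;
    for (size_t i = 0; i < idx.size(); ++i) if (y[idx[i]] > 0.5) ++c1;
    bag_counts(t, 0) = (int)idx.size() - c1;
    bag_counts(t, 1) = c1;

    Tree tree;
    BuildCtx ctx(X, y, mtry, max_depth, min_leaf, extra, importance,
                 (double)idx.size() * n_trees);
    build_node(ctx, tree, idx, 0, (int)idx.size(), 0);
    trees[t] = tree_to_matrix(tree);
  }

  return List::create(_["trees"] = trees,
                      _["importance"] = NumericVector(importance.begin(),
                                                      importance.end()),
                      _["bag_counts"] = bag_counts);
}

// [[Rcpp::export]]
NumericVector cpp_forest_predict(List trees, NumericMatrix X) {
  int n = X.nrow(), nt = trees.size();
  NumericVector out(n);
  for (int t = 0; t < nt; ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) out[i] += tree(descend(tree, X, i), 4);
  }
  for (int i = 0; i < n; ++i) out[i] /= nt;
  return out;
}

// Single regression tree for gradient boosting: returns the tree and the
// leaf node index of every training row so terminal-node updates can be
// computed in R from the loss's hessian.
// [[Rcpp::export]]
List cpp_tree_fit(NumericMatrix X, NumericVector y, int mtry, int max_depth,
                  int min_leaf) {
  int n = X.nrow(), p = X.ncol();
  if (mtry < 1 || mtry > p) mtry = p;
  std::vector<double> importance(p, 0.0);
  Tree tree;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  BuildCtx ctx(X, y, mtry, max_depth, min_leaf, false, importance, (double)n);
  build_node(ctx, tree, idx, 0, n, 0);
  NumericMatrix tm = tree_to_matrix(tree);
  int m = tm.nrow();
  IntegerVector leaf(n);
  for (int i = 0; i < n; ++i) leaf[i] = descend(tm, X, i);
  (void)m;
  return List::create(_["tree"] = tm, _["leaf"] = leaf,
                      _["importance"] = NumericVector(importance.begin(),
                                                      importance.end()));
}

// [[Rcpp::export]]
IntegerVector cpp_tree_leaf(NumericMatrix tree, NumericMatrix X) {
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = descend(tree, X, i);
  return out;
}
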