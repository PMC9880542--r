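// Exact-greedy CART regression trees with an L2 leaf penalty, shared by the
// random-forest (bagging, feature subsampling, lambda = 0, leaf = mean) and
// gradient-boosting (residual fitting, shrinkage, lambda > 0, split-count
// F-scores) learners. n and p are small here (hundreds x 13), so exact
// per-node sorting is the right trade-off.
#include <Rcpp.h>
#include <algorithm>
#include <random>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;   // -1 for leaf
  std::vector<double> thresh;
  std::vector<int> left, right;
  std::vector<double> value;
};

struct Builder {
  const NumericMatrix& X;
  const std::vector<double>& y;   // targets (or residuals)
  double lambda;
  int max_depth;                  // 0 = unlimited
  int min_node;
  int mtry;
  std::mt19937& rng;
  std::vector<int>* split_count;  // optional, length p

  Tree tree;

  int build(std::vector<int>& idx, int depth) {
    const int n = (int)idx.size();
    double G = 0.0;
    for (int i : idx) G += y[i];
    const int node = (int)tree.feature.size();
    tree.feature.push_back(-1);
    tree.thresh.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.value.push_back(G / (n + lambda));

    if (n < 2 * min_node || (max_depth > 0 && depth >= max_depth)) return node;

    const int p = X.ncol();
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    if (mtry < p) {
      for (int j = 0; j < mtry; ++j) {
        std::uniform_int_distribution<int> pick(j, p - 1);
        std::swap(feats[j], feats[pick(rng)]);
      }
      feats.resize(mtry);
    }

    double base = G * G / (n + lambda);
    double best_gain = 1e-12;
    int best_feat = -1, best_pos = -1;
    double best_thresh = 0.0;
    std::vector<std::pair<double, double>> xv(n);

    for (int f : feats) {
      for (int i = 0; i < n; ++i) xv[i] = {X(idx[i], f), y[idx[i]]};
      std::sort(xv.begin(), xv.end());
      if (xv.front().first == xv.back().first) continue;
      double GL = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        GL += xv[i].second;
        if (xv[i + 1].first == xv[i].first) continue;
        int nL = i + 1, nR = n - nL;
        if (nL < min_node || nR < min_node) continue;
        double GR = G - GL;
        double gain = GL * GL / (nL + lambda) + GR * GR / (nR + lambda) - base;
        if (gain > best_gain) {
          best_gain = gain;
          best_feat = f;
          best_thresh = (xv[i].first + xv[i + 1].first) / 2.0;
          best_pos = nL;
        }
      }
    }
    if (best_feat < 0) return node;

    std::vector<int> lidx, ridx;
    lidx.reserve(best_pos);
    ridx.reserve(n - best_pos);
    for (int i : idx) {
      if (X(i, best_feat) <= best_thresh) lidx.push_back(i);
      else ridx.push_back(i);
    }
    if (lidx.empty() || ridx.empty()) return node; // ties collapsed a side

    tree.feature[node] = best_feat;
    tree.thresh[node] = best_thresh;
    if (split_count) (*split_count)[best_feat] += 1;
    tree.left[node] = build(lidx, depth + 1);
    tree.right[node] = build(ridx, depth + 1);
    return node;
  }
};

List tree_to_list(const Tree& t) {
  return List::create(_["feature"] = wrap(t.feature),
                      _["thresh"] = wrap(t.thresh),
                      _["left"] = wrap(t.left),
                      _["right"] = wrap(t.right),
                      _["value"] = wrap(t.value));
}

double tree_predict_row(const IntegerVector& feature,
                        const NumericVector& thresh,
                        const IntegerVector& left, const IntegerVector& right,
                        const NumericVector& value,
                        const NumericMatrix& X, int row) {
  int node = 0;
  while (feature[node] >= 0) {
    node = (X(row, feature[node]) <= thresh[node]) ? left[node] : right[node];
  }
  return value[node];
}

} // namespace

// [[Rcpp::export(name = ".rf_fit")]]
List rf_fit(NumericMatrix X, NumericVector y, int ntree, int mtry,
            int max_depth, int min_node, int seed) {
  const int n = X.nrow();
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> boot(0, n - 1);
  List trees(ntree);
  std::vector<double> yb(n);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    NumericMatrix Xb(n, X.ncol());
    for (int i = 0; i < n; ++i) {
      int b = boot(rng);
      yb[i] = y[b];
      for (int j = 0; j < X.ncol(); ++j) Xb(i, j) = X(b, j);
      idx[i] = i;
    }
    Builder bld{Xb, yb, 0.0, max_depth, min_node, mtry, rng, nullptr, {}};
    bld.build(idx, 0);
    trees[t] = tree_to_list(bld.tree);
  }
  return List::create(_["trees"] = trees);
}

// [[Rcpp::export(name = ".forest_predict")]]
NumericVector forest_predict(List trees, NumericMatrix X, double init,
                             double scale) {
  const int n = X.nrow(), ntree = trees.size();
  NumericVector out(n, init);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector thresh = tr["thresh"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericVector value = tr["value"];
    for (int i = 0; i < n; ++i) {
      out[i] += scale * tree_predict_row(feature, thresh, left, right, value,
                                         X, i);
    }
  }
  return out;
}

// Second-order gradient boosting for squared loss (unit hessians): each tree
// fits current residuals with leaf values sum(res) / (n_leaf + lambda),
// scaled by the learning rate. Split counts per feature are the F-scores.
// [[Rcpp::export(name = ".gbt_fit")]]
List gbt_fit(NumericMatrix X, NumericVector y, int ntree, int max_depth,
             double learning_rate, double lambda, int min_node, int seed) {
  const int n = X.nrow(), p = X.ncol();
  std::mt19937 rng((unsigned)seed);
  double init = 0.0;
  for (int i = 0; i < n; ++i) init += y[i];
  init /= n;
  std::vector<double> pred(n, init), res(n);
  std::vector<int> fcount(p, 0);
  List trees(ntree);
  for (int t = 0; t < ntree; ++t) {
    for (int i = 0; i < n; ++i) res[i] = y[i] - pred[i];
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    Builder bld{X, res, lambda, max_depth, min_node, p, rng, &fcount, {}};
    bld.build(idx, 0);
    IntegerVector fv = wrap(bld.tree.feature);
    NumericVector tv = wrap(bld.tree.thresh);
    IntegerVector lv = wrap(bld.tree.left), rv = wrap(bld.tree.right);
    NumericVector vv = wrap(bld.tree.value);
    for (int i = 0; i < n; ++i) {
      pred[i] += learning_rate * tree_predict_row(fv, tv, lv, rv, vv, X, i);
    }
    trees[t] = tree_to_list(bld.tree);
  }
  return List::create(_["trees"] = trees, _["init"] = init,
                      _["f_score"] = wrap(fcount));
}
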