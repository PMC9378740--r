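#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Flat-array decision trees used by all tree-based learners.
//
// Two modes share one builder:
//  * classification: weighted Gini impurity, leaf stores class weight shares
//  * regression ("newton"): gradient/hessian boosting split gain
//      gain = 0.5 * (GL^2/(HL+lambda) + GR^2/(HR+lambda) - G^2/(H+lambda))
//    and leaf weight -G/(H+lambda)  (lambda = 0 recovers plain Newton/GBDT)
//
// Randomness (mtry feature subsets, extra-trees thresholds) is drawn from R's
// RNG so that set.seed() on the R side makes training deterministic.

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold; // go left if x <= threshold
  int left, right;
  std::vector<double> value; // K class shares, or single regression weight
};

struct Builder {
  const NumericMatrix &X;
  const IntegerVector &y;     // classification: 0..K-1 (unused in regression)
  const NumericVector &w;     // classification sample weights
  const NumericVector &g;     // regression gradients
  const NumericVector &h;     // regression hessians
  int K;
  bool regression;
  double lambda;
  int mtry, max_depth, min_leaf;
  bool random_split;
  std::vector<Node> nodes;

  Builder(const NumericMatrix &X_, const IntegerVector &y_,
          const NumericVector &w_, const NumericVector &g_,
          const NumericVector &h_, int K_, bool reg_, double lambda_,
          int mtry_, int max_depth_, int min_leaf_, bool random_split_)
      : X(X_), y(y_), w(w_), g(g_), h(h_), K(K_), regression(reg_),
        lambda(lambda_), mtry(mtry_), max_depth(max_depth_),
        min_leaf(min_leaf_), random_split(random_split_) {}

  // Fisher-Yates prefix over feature indices via R RNG
  std::vector<int> sample_features(int p) {
    std::vector<int> idx(p);
    for (int j = 0; j < p; ++j) idx[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      int k = j + (int)std::floor(unif_rand() * (p - j));
      if (k >= p) k = p - 1;
      std::swap(idx[j], idx[k]);
    }
    idx.resize(m);
    return idx;
  }

  int make_leaf(const std::vector<int> &rows) {
    Node nd;
    nd.feature = -1;
    nd.threshold = 0.0;
    nd.left = nd.right = -1;
    if (regression) {
      double G = 0, H = 0;
      for (int i : rows) { G += g[i]; H += h[i]; }
      nd.value.assign(1, (H + lambda) > 0 ? -G / (H + lambda) : 0.0);
    } else {
      std::vector<double> cw(K, 0.0);
      double tot = 0;
      for (int i : rows) { cw[y[i]] += w[i]; tot += w[i]; }
      if (tot <= 0) tot = 1;
      for (int k = 0; k < K; ++k) cw[k] /= tot;
      nd.value = cw;
    }
    nodes.push_back(nd);
    return (int)nodes.size() - 1;
  }

  // returns node index
  int build(std::vector<int> &rows, int depth) {
    int n = (int)rows.size();
    bool pure = true;
    if (!regression) {
      for (int i = 1; i < n; ++i)
        if (y[rows[i]] != y[rows[0]]) { pure = false; break; }
    } else {
      pure = false;
    }
    if (n < 2 * min_leaf || depth >= max_depth || (!regression && pure))
      return make_leaf(rows);

    int p = X.ncol();
    std::vector<int> feats = sample_features(p);

    double best_gain = 0.0;
    int best_f = -1;
    double best_thr = 0.0;

    // node totals
    double G = 0, H = 0, W = 0;
    std::vector<double> cw(K, 0.0);
    if (regression) {
      for (int i : rows) { G += g[i]; H += h[i]; }
    } else {
      for (int i : rows) { cw[y[i]] += w[i]; W += w[i]; }
    }
    double parent_score;
    if (regression) {
      parent_score = G * G / (H + lambda);
    } else {
      double s = 0;
      for (int k = 0; k < K; ++k) s += cw[k] * cw[k];
      parent_score = W > 0 ? (1.0 - s / (W * W)) : 0.0; // gini
    }

    std::vector<double> xv(n);
    std::vector<int> ord(n);
    for (int fi : feats) {
      for (int i = 0; i < n; ++i) xv[i] = X(rows[i], fi);
      if (random_split) {
        double lo = xv[0], hi = xv[0];
        for (int i = 1; i < n; ++i) {
          lo = std::min(lo, xv[i]);
          hi = std::max(hi, xv[i]);
        }
        if (hi <= lo) continue;
        double thr = lo + unif_rand() * (hi - lo);
        if (thr >= hi) thr = std::nextafter(hi, lo);
        double gain = split_gain(rows, xv, thr, G, H, W, cw, parent_score);
        if (gain > best_gain) { best_gain = gain; best_f = fi; best_thr = thr; }
      } else {
        for (int i = 0; i < n; ++i) ord[i] = i;
        std::sort(ord.begin(), ord.end(),
                  [&](int a, int b) { return xv[a] < xv[b]; });
        // sweep sorted values, split between distinct neighbours
        double GL = 0, HL = 0, WL = 0;
        std::vector<double> cwl(K, 0.0);
        for (int i = 0; i < n - 1; ++i) {
          int r = rows[ord[i]];
          if (regression) { GL += g[r]; HL += h[r]; }
          else { cwl[y[r]] += w[r]; WL += w[r]; }
          if (xv[ord[i + 1]] <= xv[ord[i]]) continue;
          int nl = i + 1, nr = n - nl;
          if (nl < min_leaf || nr < min_leaf) continue;
          double gain;
          if (regression) {
            double GR = G - GL, HR = H - HL;
            gain = 0.5 * (GL * GL / (HL + lambda) + GR * GR / (HR + lambda) -
                          parent_score);
          } else {
            double WR = W - WL;
            double sl = 0, sr = 0;
            for (int k = 0; k < K; ++k) {
              sl += cwl[k] * cwl[k];
              double cr = cw[k] - cwl[k];
              sr += cr * cr;
            }
            double gl = WL > 0 ? 1.0 - sl / (WL * WL) : 0.0;
            double gr = WR > 0 ? 1.0 - sr / (WR * WR) : 0.0;
            gain = parent_score - (WL * gl + WR * gr) / W;
          }
          if (gain > best_gain) {
            best_gain = gain;
            best_f = fi;
            best_thr = 0.5 * (xv[ord[i]] + xv[ord[i + 1]]);
          }
        }
      }
    }

    if (best_f < 0 || best_gain <= 1e-12) return make_leaf(rows);

    std::vector<int> lrows, rrows;
    for (int i : rows) {
      if (X(i, best_f) <= best_thr) lrows.push_back(i);
      else rrows.push_back(i);
    }
    if ((int)lrows.size() < min_leaf || (int)rrows.size() < min_leaf)
      return make_leaf(rows);

    Node nd;
    nd.feature = best_f;
    nd.threshold = best_thr;
    nd.value.assign(regression ? 1 : K, 0.0);
    nodes.push_back(nd);
    int self = (int)nodes.size() - 1;
    int li = build(lrows, depth + 1);
    int ri = build(rrows, depth + 1);
    nodes[self].left = li;
    nodes[self].right = ri;
    return self;
  }

  double split_gain(const std::vector<int> &rows, const std::vector<double> &xv,
                    double thr, double G, double H, double W,
                    const std::vector<double> &cw, double parent_score) {
    int n = (int)rows.size(), nl = 0;
    if (regression) {
      double GL = 0, HL = 0;
      for (int i = 0; i < n; ++i)
        if (xv[i] <= thr) { GL += g[rows[i]]; HL += h[rows[i]]; ++nl; }
      if (nl < min_leaf || n - nl < min_leaf) return 0.0;
      double GR = G - GL, HR = H - HL;
      return 0.5 * (GL * GL / (HL + lambda) + GR * GR / (HR + lambda) -
                    parent_score);
    }
    std::vector<double> cwl(K, 0.0);
    double WL = 0;
    for (int i = 0; i < n; ++i)
      if (xv[i] <= thr) { cwl[y[rows[i]]] += w[rows[i]]; WL += w[rows[i]]; ++nl; }
    if (nl < min_leaf || n - nl < min_leaf) return 0.0;
    double WR = W - WL, sl = 0, sr = 0;
    for (int k = 0; k < K; ++k) {
      sl += cwl[k] * cwl[k];
      double cr = cw[k] - cwl[k];
      sr += cr * cr;
    }
    double gl = WL > 0 ? 1.0 - sl / (WL * WL) : 0.0;
    double gr = WR > 0 ? 1.0 - sr / (WR * WR) : 0.0;
    return parent_score - (WL * gl + WR * gr) / W;
  }
};

List pack(const Builder &b, int root) {
  int nn = (int)b.nodes.size();
  int vdim = b.regression ? 1 : b.K;
  IntegerVector feature(nn), left(nn), right(nn);
  NumericVector threshold(nn);
  NumericMatrix value(nn, vdim);
  for (int i = 0; i < nn; ++i) {
    feature[i] = b.nodes[i].feature;
    threshold[i] = b.nodes[i].threshold;
    left[i] = b.nodes[i].left;
    right[i] = b.nodes[i].right;
    for (int k = 0; k < vdim; ++k) value(i, k) = b.nodes[i].value[k];
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right,
                      _["value"] = value, _["root"] = root);
}

} // namespace

// [[Rcpp::export]]
List cpp_build_class_tree(NumericMatrix X, IntegerVector y, NumericVector w,
                          int K, int mtry, int max_depth, int min_leaf,
                          bool random_split, IntegerVector rows) {
  NumericVector dummy(0);
  Builder b(X, y, w, dummy, dummy, K, false, 0.0, mtry, max_depth, min_leaf,
            random_split);
  std::vector<int> rr(rows.begin(), rows.end());
  int root = b.build(rr, 0);
  return pack(b, root);
}

// [[Rcpp::export]]
List cpp_build_reg_tree(NumericMatrix X, NumericVector g, NumericVector h,
                        double lambda, int mtry, int max_depth, int min_leaf,
                        bool random_split, IntegerVector rows) {
  IntegerVector dummy_y(0);
  NumericVector dummy_w(0);
  Builder b(X, dummy_y, dummy_w, g, h, 1, true, lambda, mtry, max_depth,
            min_leaf, random_split);
  std::vector<int> rr(rows.begin(), rows.end());
  int root = b.build(rr, 0);
  return pack(b, root);
}

// [[Rcpp::export]]
NumericMatrix cpp_predict_tree(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"];
  NumericMatrix value = tree["value"];
  int root = as<int>(tree["root"]);
  int n = X.nrow(), vdim = value.ncol();
  NumericMatrix out(n, vdim);
  for (int i = 0; i < n; ++i) {
    int nd = root;
    while (feature[nd] >= 0)
      nd = (X(i, feature[nd]) <= threshold[nd]) ? left[nd] : right[nd];
    for (int k = 0; k < vdim; ++k) out(i, k) = value(nd, k);
  }
  return out;
}
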