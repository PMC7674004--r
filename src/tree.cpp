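#include <Rcpp.h>
using namespace Rcpp;

// Greedy binary CART builder used by both the random forest (classification
// mode: gini/entropy impurity, leaf = class frequencies) and the gradient
// boosting machine (regression mode: second-order gain with L2 penalty
// lambda and split penalty gamma, leaf = -G/(H+lambda)).
//
// Feature subsampling (mtry) draws through R's RNG, so tree growth is
// reproducible under set.seed().

struct Node {
  int feature;       // -1 for leaf
  double threshold;
  int left, right;   // child node ids, -1 for leaf
  std::vector<double> value;
};

struct Builder {
  const NumericMatrix& X;
  const IntegerVector& y;   // classification labels 0..K-1 (ignored in reg mode)
  const NumericVector& g;   // gradients (reg mode)
  const NumericVector& h;   // hessians (reg mode)
  int n_classes, mode, criterion, max_depth, min_split, min_leaf, mtry;
  double min_child_weight, lambda, gamma;
  std::vector<Node> nodes;

  Builder(const NumericMatrix& X_, const IntegerVector& y_,
          const NumericVector& g_, const NumericVector& h_)
    : X(X_), y(y_), g(g_), h(h_) {}

  double impurity(const std::vector<double>& cnt, double n) const {
    if (n <= 0) return 0.0;
    double imp = 0.0;
    for (double c : cnt) {
      if (c <= 0) continue;
      double p = c / n;
      imp += (criterion == 0) ? p * (1.0 - p) : -p * std::log2(p);
    }
    return imp;
  }

  std::vector<double> leaf_value(const std::vector<int>& idx) const {
    if (mode == 0) {
      std::vector<double> cnt(n_classes, 0.0);
      for (int i : idx) cnt[y[i]] += 1.0;
      double n = (double)idx.size();
      for (double& c : cnt) c /= n;
      return cnt;
    }
    double G = 0.0, H = 0.0;
    for (int i : idx) { G += g[i]; H += h[i]; }
    return std::vector<double>(1, -G / (H + lambda));
  }

  int build(const std::vector<int>& idx, int depth) {
    const int node_id = (int)nodes.size();
    nodes.push_back(Node());
    nodes[node_id].feature = -1;
    nodes[node_id].left = nodes[node_id].right = -1;
    nodes[node_id].value = leaf_value(idx);

    const int n = (int)idx.size();
    bool stop = (max_depth > 0 && depth >= max_depth) || n < min_split ||
                n < 2 * min_leaf;
    if (mode == 0 && !stop) {  // purity check
      int first = y[idx[0]];
      bool pure = true;
      for (int i : idx) if (y[i] != first) { pure = false; break; }
      stop = pure;
    }
    if (stop) return node_id;

    const int p = X.ncol();
    IntegerVector feats;
    if (mtry > 0 && mtry < p) {
      feats = Rcpp::sample(p, mtry);  // 1-based, R RNG
    } else {
      feats = IntegerVector(p);
      for (int j = 0; j < p; ++j) feats[j] = j + 1;
    }

    // parent statistics
    std::vector<double> cnt;
    double Gp = 0.0, Hp = 0.0, parent_imp = 0.0, parent_score = 0.0;
    if (mode == 0) {
      cnt.assign(n_classes, 0.0);
      for (int i : idx) cnt[y[i]] += 1.0;
      parent_imp = impurity(cnt, (double)n);
    } else {
      for (int i : idx) { Gp += g[i]; Hp += h[i]; }
      parent_score = Gp * Gp / (Hp + lambda);
    }

    double best_gain = 0.0, best_thr = 0.0;
    int best_feat = -1;
    std::vector<std::pair<double, int> > vals(n);

    for (int jj = 0; jj < feats.size(); ++jj) {
      const int j = feats[jj] - 1;
      for (int i = 0; i < n; ++i) vals[i] = std::make_pair(X(idx[i], j), idx[i]);
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;

      if (mode == 0) {
        std::vector<double> lcnt(n_classes, 0.0);
        for (int i = 0; i < n - 1; ++i) {
          lcnt[y[vals[i].second]] += 1.0;
          if (vals[i].first == vals[i + 1].first) continue;
          const int nl = i + 1, nrr = n - nl;
          if (nl < min_leaf || nrr < min_leaf) continue;
          std::vector<double> rcnt(n_classes);
          for (int k = 0; k < n_classes; ++k) rcnt[k] = cnt[k] - lcnt[k];
          double gain = parent_imp -
            (nl * impurity(lcnt, nl) + nrr * impurity(rcnt, nrr)) / n;
          if (gain > best_gain + 1e-12) {
            best_gain = gain;
            best_feat = j;
            best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
          }
        }
      } else {
        double GL = 0.0, HL = 0.0;
        for (int i = 0; i < n - 1; ++i) {
          GL += g[vals[i].second];
          HL += h[vals[i].second];
          if (vals[i].first == vals[i + 1].first) continue;
          const int nl = i + 1, nrr = n - nl;
          if (nl < min_leaf || nrr < min_leaf) continue;
          const double GR = Gp - GL, HR = Hp - HL;
          if (HL < min_child_weight || HR < min_child_weight) continue;
          double gain = 0.5 * (GL * GL / (HL + lambda) + GR * GR / (HR + lambda) -
                               parent_score) - gamma;
          if (gain > best_gain + 1e-12) {
            best_gain = gain;
            best_feat = j;
            best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
          }
        }
      }
    }

    if (best_feat < 0) return node_id;

    std::vector<int> lidx, ridx;
    for (int i : idx) {
      if (X(i, best_feat) <= best_thr) lidx.push_back(i); else ridx.push_back(i);
    }
    if (lidx.empty() || ridx.empty()) return node_id;

    nodes[node_id].feature = best_feat;
    nodes[node_id].threshold = best_thr;
    int l = build(lidx, depth + 1);
    int r = build(ridx, depth + 1);
    nodes[node_id].left = l;
    nodes[node_id].right = r;
    return node_id;
  }
};

// [[Rcpp::export(name = ".build_tree_cpp")]]
List build_tree_cpp(NumericMatrix X, IntegerVector y, NumericVector g,
                    NumericVector h, IntegerVector idx, int n_classes,
                    int mode, int criterion, int max_depth, int min_split,
                    int min_leaf, int mtry, double min_child_weight,
                    double lambda, double gamma) {
  Builder b(X, y, g, h);
  b.n_classes = n_classes;
  b.mode = mode;
  b.criterion = criterion;
  b.max_depth = max_depth;
  b.min_split = std::max(min_split, 2);
  b.min_leaf = std::max(min_leaf, 1);
  b.mtry = mtry;
  b.min_child_weight = min_child_weight;
  b.lambda = lambda;
  b.gamma = gamma;
  std::vector<int> samples(idx.begin(), idx.end());
  b.build(samples, 0);

  const int nn = (int)b.nodes.size();
  const int vd = (mode == 0) ? n_classes : 1;
  IntegerVector feature(nn), left(nn), right(nn);
  NumericVector threshold(nn);
  NumericMatrix value(nn, vd);
  for (int i = 0; i < nn; ++i) {
    feature[i] = b.nodes[i].feature;
    threshold[i] = (b.nodes[i].feature >= 0) ? b.nodes[i].threshold : NA_REAL;
    left[i] = b.nodes[i].left;
    right[i] = b.nodes[i].right;
    for (int k = 0; k < vd; ++k) value(i, k) = b.nodes[i].value[k];
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right, _["value"] = value);
}

// [[Rcpp::export(name = ".predict_tree_cpp")]]
NumericMatrix predict_tree_cpp(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"];
  NumericMatrix value = tree["value"];
  const int n = X.nrow(), vd = value.ncol();
  NumericMatrix out(n, vd);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
    }
    for (int k = 0; k < vd; ++k) out(i, k) = value(node, k);
  }
  return out;
}
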