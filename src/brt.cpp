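// Stochastic gradient-boosted regression trees with Friedman relative
// influence. Squared-error loss for continuous responses, Bernoulli deviance
// (Newton leaf updates) for binary ones. Subsampling uses R's RNG so callers
// control reproducibility with set.seed().
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct Node {
  int feature = -1;      // -1 marks a leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  double value = 0.0;    // leaf prediction (pre-shrinkage)
};

struct SplitResult {
  int feature = -1;
  double threshold = 0.0, gain = 0.0;
};

static SplitResult best_split(const NumericMatrix& X,
                              const std::vector<double>& g,
                              const std::vector<double>& h,
                              const std::vector<int>& rows,
                              int min_node) {
  SplitResult best;
  const int p = X.ncol(), m = (int)rows.size();
  if (m < 2 * min_node) return best;
  double G = 0.0, H = 0.0;
  for (int r : rows) { G += g[r]; H += h[r]; }
  if (H <= 0.0) return best;
  double parent = G * G / H;
  std::vector<int> ord(rows);
  std::vector<double> xv(m);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < m; ++i) xv[i] = X(rows[i], j);
    std::iota(ord.begin(), ord.end(), 0);
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return xv[a] < xv[b]; });
    double GL = 0.0, HL = 0.0;
    int nl = 0;
    for (int i = 0; i < m - 1; ++i) {
      int r = rows[ord[i]];
      GL += g[r]; HL += h[r]; ++nl;
      double xa = xv[ord[i]], xb = xv[ord[i + 1]];
      if (xa == xb) continue;
      if (nl < min_node || m - nl < min_node) continue;
      double GR = G - GL, HR = H - HL;
      if (HL <= 0.0 || HR <= 0.0) continue;
      double gain = GL * GL / HL + GR * GR / HR - parent;
      if (gain > best.gain) {
        best.gain = gain;
        best.feature = j;
        best.threshold = 0.5 * (xa + xb);
      }
    }
  }
  return best;
}

static void grow(const NumericMatrix& X, const std::vector<double>& g,
                 const std::vector<double>& h, std::vector<int> rows,
                 int depth, int max_depth, int min_node,
                 std::vector<Node>& nodes, int node_id,
                 std::vector<double>& feat_gain) {
  double G = 0.0, H = 0.0;
  for (int r : rows) { G += g[r]; H += h[r]; }
  nodes[node_id].value = (H > 0.0) ? -G / H : 0.0;
  if (depth >= max_depth) return;
  SplitResult s = best_split(X, g, h, rows, min_node);
  if (s.feature < 0 || s.gain <= 1e-12) return;
  feat_gain[s.feature] += s.gain;
  std::vector<int> lrows, rrows;
  for (int r : rows)
    (X(r, s.feature) <= s.threshold ? lrows : rrows).push_back(r);
  nodes[node_id].feature = s.feature;
  nodes[node_id].threshold = s.threshold;
  nodes[node_id].left = (int)nodes.size();
  nodes.push_back(Node());
  nodes[node_id].right = (int)nodes.size();
  nodes.push_back(Node());
  grow(X, g, h, lrows, depth + 1, max_depth, min_node, nodes,
       nodes[node_id].left, feat_gain);
  grow(X, g, h, rrows, depth + 1, max_depth, min_node, nodes,
       nodes[node_id].right, feat_gain);
}

static double tree_predict(const std::vector<Node>& nodes,
                           const NumericMatrix& X, int row) {
  int id = 0;
  while (nodes[id].feature >= 0)
    id = (X(row, nodes[id].feature) <= nodes[id].threshold)
             ? nodes[id].left : nodes[id].right;
  return nodes[id].value;
}

static NumericMatrix pack_tree(const std::vector<Node>& nodes) {
  NumericMatrix M((int)nodes.size(), 5);
  for (int i = 0; i < (int)nodes.size(); ++i) {
    M(i, 0) = nodes[i].feature;
    M(i, 1) = nodes[i].threshold;
    M(i, 2) = nodes[i].left;
    M(i, 3) = nodes[i].right;
    M(i, 4) = nodes[i].value;
  }
  return M;
}

// [[Rcpp::export(name = ".brt_fit_cpp")]]
List brt_fit_cpp(NumericMatrix X, NumericVector y, std::string loss,
                 int n_trees, double learning_rate, int max_depth,
                 double bag_fraction, int min_node, int patience) {
  const int n = X.nrow(), p = X.ncol();
  const bool bern = (loss == "bernoulli");
  double init;
  if (bern) {
    double ybar = mean(y);
    ybar = std::min(std::max(ybar, 1e-12), 1.0 - 1e-12);
    init = std::log(ybar / (1.0 - ybar));
  } else {
    init = mean(y);
  }
  std::vector<double> F(n, init), g(n), h(n);
  std::vector<std::vector<double>> tree_gains;
  std::vector<std::vector<Node>> trees;
  std::vector<double> train_dev, oob_dev;
  std::vector<int> idx(n);
  std::iota(idx.begin(), idx.end(), 0);
  const int bag_n = std::max(2 * min_node,
                             (int)std::floor(bag_fraction * n + 0.5));
  const bool bagging = bag_n < n;
  double best_oob = R_PosInf;
  int best_iter = 0;

  auto deviance = [&](const std::vector<int>& rows) {
    if (rows.empty()) return NA_REAL;
    double d = 0.0;
    for (int r : rows) {
      if (bern) {
        // -2 log-likelihood per observation, numerically safe
        double z = F[r];
        d += 2.0 * (std::log1p(std::exp(-std::fabs(z))) +
                    std::max(z, 0.0) - y[r] * z);
      } else {
        double e = y[r] - F[r];
        d += e * e;
      }
    }
    return d / rows.size();
  };

  for (int t = 0; t < n_trees; ++t) {
    // partial Fisher-Yates draw of bag_n rows
    for (int i = 0; i < bag_n; ++i) {
      int j = i + (int)std::floor(R::unif_rand() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(idx[i], idx[j]);
    }
    std::vector<int> bag(idx.begin(), idx.begin() + bag_n);
    std::vector<int> oob(idx.begin() + bag_n, idx.end());
    for (int r = 0; r < n; ++r) {
      if (bern) {
        double pr = 1.0 / (1.0 + std::exp(-F[r]));
        g[r] = pr - y[r];
        h[r] = std::max(pr * (1.0 - pr), 1e-12);
      } else {
        g[r] = F[r] - y[r];
        h[r] = 1.0;
      }
    }
    std::vector<Node> nodes(1);
    std::vector<double> tree_gain(p, 0.0);
    grow(X, g, h, bag, 0, max_depth, min_node, nodes, 0, tree_gain);
    tree_gains.push_back(tree_gain);
    trees.push_back(nodes);
    for (int r = 0; r < n; ++r)
      F[r] += learning_rate * tree_predict(nodes, X, r);
    train_dev.push_back(deviance(bag));
    double od = bagging ? deviance(oob) : deviance(bag);
    oob_dev.push_back(od);
    if (!ISNA(od) && od < best_oob - 1e-12) {
      best_oob = od;
      best_iter = t + 1;
    }
    if (patience > 0 && (t + 1) - best_iter >= patience) break;
  }
  // influence accounting restricted to the kept (early-stopped) ensemble
  const int kept = (patience > 0 && best_iter > 0) ? best_iter
                                                   : (int)trees.size();
  List tree_list(kept);
  NumericVector feat_gain(p);
  for (int t = 0; t < kept; ++t) {
    tree_list[t] = pack_tree(trees[t]);
    for (int j = 0; j < p; ++j) feat_gain[j] += tree_gains[t][j];
  }
  return List::create(
      _["trees"] = tree_list, _["init"] = init,
      _["n_trees"] = kept, _["feature_gain"] = feat_gain,
      _["train_deviance"] = NumericVector(train_dev.begin(),
                                          train_dev.begin() + kept),
      _["oob_deviance"] = NumericVector(oob_dev.begin(),
                                        oob_dev.begin() + kept));
}

// [[Rcpp::export(name = ".brt_predict_cpp")]]
NumericVector brt_predict_cpp(List trees, double init, double learning_rate,
                              NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n, init);
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix M = trees[t];
    const int nn = M.nrow();
    std::vector<Node> nodes(nn);
    for (int i = 0; i < nn; ++i) {
      nodes[i].feature = (int)M(i, 0);
      nodes[i].threshold = M(i, 1);
      nodes[i].left = (int)M(i, 2);
      nodes[i].right = (int)M(i, 3);
      nodes[i].value = M(i, 4);
    }
    for (int r = 0; r < n; ++r)
      out[r] += learning_rate * tree_predict(nodes, X, r);
  }
  return out;
}
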