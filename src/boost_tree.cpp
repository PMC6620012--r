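// Exact greedy builder for second-order gradient-boosted regression trees.
// Every split retains its summed gradient/Hessian statistics (G, H on the
// node and both children) so the regularised feature-gain formula can be
// evaluated literally from the stored model.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline double soft_thr(double x, double alpha) {
  if (x > alpha) return x - alpha;
  if (x < -alpha) return x + alpha;
  return 0.0;
}

static inline double leaf_score(double G, double H, double lambda,
                                double alpha) {
  double s = soft_thr(G, alpha);
  return s * s / (H + lambda);
}

struct Node {
  int feature;      // 0-based; -1 for leaf
  double threshold;
  double weight;    // leaf output
  int left, right;  // 0-based node ids; -1 for leaf
  double gain;
  double G, H, GL, HL, GR, HR;
};

struct BuildCtx {
  const NumericMatrix& X;
  const NumericVector& g;
  const NumericVector& h;
  double lambda, alpha, gamma;
  int max_features, min_leaf, max_depth;  // max_depth < 0: unbounded
  std::vector<Node> nodes;
  BuildCtx(const NumericMatrix& X_, const NumericVector& g_,
           const NumericVector& h_, double l, double a, double gm,
           int mf, int ml, int md)
    : X(X_), g(g_), h(h_), lambda(l), alpha(a), gamma(gm),
      max_features(mf), min_leaf(ml), max_depth(md) {}
};

// sample k of d feature indices without replacement using the R RNG,
// returned sorted ascending so the tie-break on feature index is stable
static std::vector<int> sample_features(int d, int k) {
  std::vector<int> idx(d);
  for (int i = 0; i < d; ++i) idx[i] = i;
  for (int i = 0; i < k; ++i) {
    int j = i + (int)std::floor(unif_rand() * (d - i));
    if (j >= d) j = d - 1;
    std::swap(idx[i], idx[j]);
  }
  idx.resize(k);
  std::sort(idx.begin(), idx.end());
  return idx;
}

static int build_node(BuildCtx& ctx, std::vector<int>& rows, int depth) {
  double G = 0.0, H = 0.0;
  for (int r : rows) { G += ctx.g[r]; H += ctx.h[r]; }
  int id = (int)ctx.nodes.size();
  Node nd;
  nd.feature = -1; nd.threshold = NA_REAL;
  nd.weight = -soft_thr(G, ctx.alpha) / (H + ctx.lambda);
  nd.left = nd.right = -1;
  nd.gain = NA_REAL;
  nd.G = G; nd.H = H;
  nd.GL = nd.HL = nd.GR = nd.HR = NA_REAL;
  ctx.nodes.push_back(nd);

  int n = (int)rows.size();
  if (n < 2 * ctx.min_leaf || n < 2) return id;
  if (ctx.max_depth >= 0 && depth >= ctx.max_depth) return id;

  std::vector<int> feats = sample_features(ctx.X.ncol(), ctx.max_features);
  double parent_score = leaf_score(G, H, ctx.lambda, ctx.alpha);

  double best_gain = 0.0, best_thr = 0.0;
  double best_GL = 0, best_HL = 0;
  int best_feat = -1, best_nleft = 0;
  std::vector<int> order(rows);

  for (int f : feats) {
    std::sort(order.begin(), order.end(), [&](int a, int b) {
      double xa = ctx.X(a, f), xb = ctx.X(b, f);
      if (xa != xb) return xa < xb;
      return a < b;
    });
    double GL = 0.0, HL = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      int r = order[i];
      GL += ctx.g[r]; HL += ctx.h[r];
      double x0 = ctx.X(r, f), x1 = ctx.X(order[i + 1], f);
      if (x1 <= x0) continue;
      int nleft = i + 1, nright = n - nleft;
      if (nleft < ctx.min_leaf || nright < ctx.min_leaf) continue;
      double GR = G - GL, HR = H - HL;
      double gain = 0.5 * (leaf_score(GL, HL, ctx.lambda, ctx.alpha) +
                           leaf_score(GR, HR, ctx.lambda, ctx.alpha) -
                           parent_score) - ctx.gamma;
      // strict improvement keeps the lowest feature index / threshold on ties
      if (gain > best_gain) {
        best_gain = gain;
        best_feat = f;
        best_thr = 0.5 * (x0 + x1);
        best_GL = GL; best_HL = HL;
        best_nleft = nleft;
      }
    }
  }

  if (best_feat < 0 || best_gain <= 0.0) return id;

  std::vector<int> left_rows, right_rows;
  left_rows.reserve(best_nleft);
  right_rows.reserve(n - best_nleft);
  for (int r : rows) {
    if (ctx.X(r, best_feat) < best_thr) left_rows.push_back(r);
    else right_rows.push_back(r);
  }
  ctx.nodes[id].feature = best_feat;
  ctx.nodes[id].threshold = best_thr;
  ctx.nodes[id].gain = best_gain;
  ctx.nodes[id].GL = best_GL; ctx.nodes[id].HL = best_HL;
  ctx.nodes[id].GR = G - best_GL; ctx.nodes[id].HR = H - best_HL;
  int lid = build_node(ctx, left_rows, depth + 1);
  int rid = build_node(ctx, right_rows, depth + 1);
  ctx.nodes[id].left = lid;
  ctx.nodes[id].right = rid;
  return id;
}

// [[Rcpp::export(name = ".build_tree_cpp")]]
DataFrame build_tree_cpp(NumericMatrix X, NumericVector g, NumericVector h,
                         double lambda, double alpha, double gamma,
                         int max_features, int min_samples_leaf,
                         int max_depth) {
  BuildCtx ctx(X, g, h, lambda, alpha, gamma, max_features,
               min_samples_leaf, max_depth);
  std::vector<int> rows(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) rows[i] = i;
  build_node(ctx, rows, 0);
  int m = (int)ctx.nodes.size();
  IntegerVector feature(m), left(m), right(m);
  NumericVector threshold(m), weight(m), gain(m);
  NumericVector G(m), H(m), GL(m), HL(m), GR(m), HR(m);
  for (int i = 0; i < m; ++i) {
    const Node& nd = ctx.nodes[i];
    feature[i] = nd.feature < 0 ? NA_INTEGER : nd.feature + 1;
    threshold[i] = nd.threshold;
    weight[i] = nd.weight;
    left[i] = nd.left < 0 ? NA_INTEGER : nd.left + 1;
    right[i] = nd.right < 0 ? NA_INTEGER : nd.right + 1;
    gain[i] = nd.gain;
    G[i] = nd.G; H[i] = nd.H;
    GL[i] = nd.GL; HL[i] = nd.HL; GR[i] = nd.GR; HR[i] = nd.HR;
  }
  return DataFrame::create(
    Named("feature") = feature, Named("threshold") = threshold,
    Named("weight") = weight, Named("left") = left, Named("right") = right,
    Named("gain") = gain, Named("G") = G, Named("H") = H,
    Named("G_L") = GL, Named("H_L") = HL,
    Named("G_R") = GR, Named("H_R") = HR);
}

// [[Rcpp::export(name = ".predict_tree_cpp")]]
NumericVector predict_tree_cpp(DataFrame tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], weight = tree["weight"];
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] != NA_INTEGER) {
      int f = feature[node] - 1;
      node = (X(i, f) < threshold[node] ? left[node] : right[node]) - 1;
    }
    out[i] = weight[node];
  }
  return out;
}
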