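// Gradient-boosted decision trees, binary logistic loss, histogram-based
// split finding (LightGBM-style): features are pre-binned into at most
// 255 quantile bins once per fit; each node accumulates per-feature
// gradient/hessian histograms over its rows, so a tree costs
// O(depth * n_rows * n_features) sequential additions. Deterministic
// unless row/column subsampling < 1.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>

using namespace Rcpp;

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

static const int MAX_BINS = 255;

struct Tree {
  std::vector<int> feature;      // -1 at leaves
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left, right;
  std::vector<double> value;     // leaf value (already scaled by learning rate)
};

struct Binned {
  std::vector<unsigned char> B;        // row-major n x m bin codes
  std::vector<std::vector<double>> ub; // per feature: upper edge per bin
  int n, m;
};

// quantile binning; ub[k] is the largest data value in bin k, so the
// split "bin <= k" is exactly "x <= ub[k]" for any future x
static Binned bin_features(const NumericMatrix& X) {
  Binned bn;
  bn.n = X.nrow(); bn.m = X.ncol();
  bn.B.assign((size_t)bn.n * bn.m, 0);
  bn.ub.resize(bn.m);
  std::vector<double> col(bn.n);
  for (int j = 0; j < bn.m; ++j) {
    const double* xp = &X(0, j);
    std::copy(xp, xp + bn.n, col.begin());
    std::sort(col.begin(), col.end());
    std::vector<double> edges;
    edges.reserve(MAX_BINS);
    for (int k = 1; k <= MAX_BINS; ++k) {
      size_t pos = (size_t)((double)k * bn.n / MAX_BINS) - 1;
      if (pos >= (size_t)bn.n) pos = bn.n - 1;
      double v = col[pos];
      if (edges.empty() || v > edges.back()) edges.push_back(v);
    }
    edges.back() = col[bn.n - 1];
    bn.ub[j] = edges;
    const std::vector<double>& e = bn.ub[j];
    for (int r = 0; r < bn.n; ++r) {
      int b = (int)(std::lower_bound(e.begin(), e.end(), xp[r]) - e.begin());
      if (b >= (int)e.size()) b = (int)e.size() - 1;
      bn.B[(size_t)r * bn.m + j] = (unsigned char)b;
    }
  }
  return bn;
}

static Tree grow_tree(const Binned& bn,
                      const std::vector<double>& g,
                      const std::vector<double>& h,
                      std::vector<int>& rows, // in-bag row ids, repartitioned in place
                      const std::vector<char>& use_col,
                      int max_depth, int min_child, double lambda,
                      double min_gain, double lr) {
  const int m = bn.m;
  Tree tr;
  struct NodeJob { int id, lo, hi, depth; double G, H; };
  tr.feature.push_back(-1); tr.threshold.push_back(0);
  tr.left.push_back(-1); tr.right.push_back(-1); tr.value.push_back(0);

  double G0 = 0, H0 = 0;
  for (int r : rows) { G0 += g[r]; H0 += h[r]; }
  std::vector<NodeJob> stack = {{0, 0, (int)rows.size(), 0, G0, H0}};
  std::vector<double> hg((size_t)m * MAX_BINS), hh((size_t)m * MAX_BINS);
  std::vector<int> hc((size_t)m * MAX_BINS);

  while (!stack.empty()) {
    NodeJob nd = stack.back(); stack.pop_back();
    int cnt = nd.hi - nd.lo;
    if (nd.depth >= max_depth || cnt < 2 * min_child) {
      tr.value[nd.id] = -lr * nd.G / (nd.H + lambda);
      continue;
    }
    std::fill(hg.begin(), hg.end(), 0.0);
    std::fill(hh.begin(), hh.end(), 0.0);
    std::fill(hc.begin(), hc.end(), 0);
    for (int ii = nd.lo; ii < nd.hi; ++ii) {
      int r = rows[ii];
      const unsigned char* br = &bn.B[(size_t)r * m];
      double gr = g[r], hr = h[r];
      for (int j = 0; j < m; ++j) {
        size_t o = (size_t)j * MAX_BINS + br[j];
        hg[o] += gr; hh[o] += hr; hc[o]++;
      }
    }
    double best_gain = min_gain;
    int best_feat = -1, best_bin = -1;
    double parent_score = nd.G * nd.G / (nd.H + lambda);
    for (int j = 0; j < m; ++j) {
      if (!use_col[j]) continue;
      int nb = (int)bn.ub[j].size();
      double GL = 0, HL = 0; int NL = 0;
      for (int b = 0; b + 1 < nb; ++b) {
        size_t o = (size_t)j * MAX_BINS + b;
        GL += hg[o]; HL += hh[o]; NL += hc[o];
        int NR = cnt - NL;
        if (NL < min_child) continue;
        if (NR < min_child) break;
        double GR = nd.G - GL, HR = nd.H - HL;
        double gain = GL * GL / (HL + lambda) + GR * GR / (HR + lambda)
                      - parent_score;
        if (gain > best_gain) { best_gain = gain; best_feat = j; best_bin = b; }
      }
    }
    if (best_feat < 0) {
      tr.value[nd.id] = -lr * nd.G / (nd.H + lambda);
      continue;
    }
    // partition rows[lo:hi) in place: bin <= best_bin goes left
    int i = nd.lo, jx = nd.hi - 1;
    double GL = 0, HL = 0;
    while (i <= jx) {
      int r = rows[i];
      if (bn.B[(size_t)r * m + best_feat] <= best_bin) {
        GL += g[r]; HL += h[r]; ++i;
      } else {
        std::swap(rows[i], rows[jx]); --jx;
      }
    }
    int L = (int)tr.feature.size(), R = L + 1;
    for (int t = 0; t < 2; ++t) {
      tr.feature.push_back(-1); tr.threshold.push_back(0);
      tr.left.push_back(-1); tr.right.push_back(-1); tr.value.push_back(0);
    }
    tr.feature[nd.id] = best_feat;
    tr.threshold[nd.id] = bn.ub[best_feat][best_bin];
    tr.left[nd.id] = L; tr.right[nd.id] = R;
    stack.push_back({L, nd.lo, i, nd.depth + 1, GL, HL});
    stack.push_back({R, i, nd.hi, nd.depth + 1, nd.G - GL, nd.H - HL});
  }
  return tr;
}

static inline double tree_predict_row(const Tree& tr, const double* Xp,
                                      int n, int r) {
  int node = 0;
  while (tr.feature[node] >= 0) {
    double v = Xp[(size_t)tr.feature[node] * n + r];
    node = (v <= tr.threshold[node]) ? tr.left[node] : tr.right[node];
  }
  return tr.value[node];
}

// [[Rcpp::export(name = ".gbt_fit_cpp")]]
List gbt_fit_cpp(NumericMatrix X, NumericVector y, NumericVector w,
                 int nrounds, double learning_rate, int max_depth,
                 int min_child, double lambda, double min_gain,
                 double subsample, double colsample, int rng_seed,
                 Nullable<NumericMatrix> Xvalid, Nullable<NumericVector> yvalid,
                 int early_stopping_rounds) {
  const int n = X.nrow(), m = X.ncol();
  if (y.size() != n || w.size() != n) stop("length mismatch");

  double sw1 = 0, sw0 = 0;
  for (int r = 0; r < n; ++r) { if (y[r] > 0.5) sw1 += w[r]; else sw0 += w[r]; }
  if (sw1 <= 0 || sw0 <= 0) {
    // degenerate: single-class training data -> constant model
    double base = (sw1 <= 0) ? -10.0 : 10.0;
    return List::create(_["base_score"] = base, _["trees"] = List::create(),
                        _["best_iter"] = 0, _["n_features"] = m);
  }
  double base = std::log(sw1 / sw0);

  Binned bn = bin_features(X);
  const double* Xp = &X(0, 0);

  std::vector<double> F(n, base), g(n), h(n);
  std::mt19937 rng((unsigned)rng_seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  bool has_valid = Xvalid.isNotNull() && yvalid.isNotNull();
  NumericMatrix Xv;
  NumericVector yv;
  int nv = 0;
  std::vector<double> Fv;
  if (has_valid) {
    Xv = Xvalid.get(); yv = yvalid.get(); nv = Xv.nrow();
    Fv.assign(nv, base);
  }
  double best_loss = std::numeric_limits<double>::infinity();
  int best_iter = 0, since_best = 0;

  std::vector<Tree> trees;
  trees.reserve(nrounds);
  std::vector<char> use_col(m, 1);
  std::vector<int> rows;
  rows.reserve(n);

  for (int it = 0; it < nrounds; ++it) {
    for (int r = 0; r < n; ++r) {
      double p = sigmoid(F[r]);
      g[r] = w[r] * (p - y[r]);
      h[r] = std::max(w[r] * p * (1.0 - p), 1e-16);
    }
    rows.clear();
    if (subsample < 1.0) {
      for (int r = 0; r < n; ++r) if (unif(rng) < subsample) rows.push_back(r);
      if (rows.empty()) for (int r = 0; r < n; ++r) rows.push_back(r);
    } else {
      for (int r = 0; r < n; ++r) rows.push_back(r);
    }
    if (colsample < 1.0) {
      bool any = false;
      for (int j = 0; j < m; ++j) { use_col[j] = unif(rng) < colsample; any |= use_col[j]; }
      if (!any) std::fill(use_col.begin(), use_col.end(), 1);
    }

    Tree tr = grow_tree(bn, g, h, rows, use_col, max_depth, min_child,
                        lambda, min_gain, learning_rate);
    trees.push_back(tr);
    for (int r = 0; r < n; ++r) F[r] += tree_predict_row(tr, Xp, n, r);

    if (has_valid) {
      const double* Xvp = &Xv(0, 0);
      for (int r = 0; r < nv; ++r) Fv[r] += tree_predict_row(tr, Xvp, nv, r);
      double loss = 0;
      for (int r = 0; r < nv; ++r) {
        double p = sigmoid(Fv[r]);
        p = std::min(std::max(p, 1e-15), 1.0 - 1e-15);
        loss += (yv[r] > 0.5) ? -std::log(p) : -std::log(1.0 - p);
      }
      loss /= std::max(nv, 1);
      if (loss < best_loss - 1e-12) {
        best_loss = loss; best_iter = it + 1; since_best = 0;
      } else if (early_stopping_rounds > 0 && ++since_best >= early_stopping_rounds) {
        break;
      }
    } else {
      best_iter = it + 1;
    }
  }
  if (!has_valid || best_iter == 0) best_iter = (int)trees.size();

  List tlist(best_iter);
  for (int t = 0; t < best_iter; ++t) {
    tlist[t] = List::create(_["feature"] = wrap(trees[t].feature),
                            _["threshold"] = wrap(trees[t].threshold),
                            _["left"] = wrap(trees[t].left),
                            _["right"] = wrap(trees[t].right),
                            _["value"] = wrap(trees[t].value));
  }
  return List::create(_["base_score"] = base, _["trees"] = tlist,
                      _["best_iter"] = best_iter, _["n_features"] = m);
}

// [[Rcpp::export(name = ".gbt_predict_cpp")]]
NumericVector gbt_predict_cpp(List model, NumericMatrix X) {
  const int n = X.nrow();
  double base = as<double>(model["base_score"]);
  List tlist = model["trees"];
  NumericVector out(n, base);
  for (int t = 0; t < tlist.size(); ++t) {
    List tl = tlist[t];
    IntegerVector feature = tl["feature"];
    NumericVector threshold = tl["threshold"];
    IntegerVector left = tl["left"], right = tl["right"];
    NumericVector value = tl["value"];
    for (int r = 0; r < n; ++r) {
      int node = 0;
      while (feature[node] >= 0) {
        double v = X(r, feature[node]);
        node = (v <= threshold[node]) ? left[node] : right[node];
      }
      out[r] += value[node];
    }
  }
  return out;
}
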