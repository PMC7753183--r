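// Constrained regression forest for multivariate connectivity.
//
// Trees are grown best-first (the pending leaf with the largest achievable
// SSE decrease is split next) up to a cap on terminal nodes; m_try
// predictors are sampled per split (or per tree); split quality is the
// weighted SSE decrease on the bootstrap sample. All randomness comes from
// a self-contained splitmix64 stream seeded per fit, so outputs are
// bit-identical across runs and platforms. Ties between equal-gain splits
// resolve to the lowest predictor index, then the lowest threshold.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  // deterministic integer in [0, n); modulo bias is irrelevant here
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct Node {
  bool leaf = true;
  int feature = -1;
  double threshold = 0.0;
  int left = -1, right = -1;
  double value = 0.0;          // weighted mean of y in node
  // training-sample stats (bootstrap weighted)
  double n = 0.0, sum = 0.0;
  // cached best split for this leaf
  double best_gain = -1.0;
  int best_feature = -1;
  double best_threshold = 0.0;
};

// sample m indices without replacement from 0..q-1, returned ascending;
// if m >= q all indices are used and the stream is untouched
void sample_features(SplitMix64& rng, int q, int m, std::vector<int>& idx,
                     std::vector<int>& out) {
  out.clear();
  if (m >= q) {
    for (int j = 0; j < q; ++j) out.push_back(j);
    return;
  }
  for (int j = 0; j < q; ++j) idx[j] = j;
  for (int k = 0; k < m; ++k) {
    int r = k + rng.below(q - k);
    std::swap(idx[k], idx[r]);
    out.push_back(idx[k]);
  }
  std::sort(out.begin(), out.end());
}

}  // namespace

// [[Rcpp::export(name = ".forest_fit_cpp")]]
List forest_fit_cpp(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                    int max_leaf_nodes, bool bootstrap, double seed,
                    bool per_tree_sampling, bool want_oob) {
  const int p = X.nrow(), q = X.ncol();
  SplitMix64 rng(static_cast<uint64_t>(seed));

  // presort each column once; node scans then run in value order with no
  // per-node sorting
  std::vector<std::vector<int>> order(q, std::vector<int>(p));
  for (int j = 0; j < q; ++j) {
    const double* col = &X(0, j);
    std::vector<int>& oj = order[j];
    for (int r = 0; r < p; ++r) oj[r] = r;
    std::stable_sort(oj.begin(), oj.end(),
                     [col](int a, int b) { return col[a] < col[b]; });
  }

  std::vector<double> pred_sum(p, 0.0), oob_sum(p, 0.0), imp(q, 0.0);
  std::vector<int> oob_cnt(p, 0);
  std::vector<double> w(p);
  std::vector<int> node_of(p), scratch_idx(q), feats;
  std::vector<int> tree_feats;

  for (int t = 0; t < n_trees; ++t) {
    // bootstrap weights (multinomial counts over original rows)
    std::fill(w.begin(), w.end(), 0.0);
    if (bootstrap) {
      for (int d = 0; d < p; ++d) w[rng.below(p)] += 1.0;
    } else {
      std::fill(w.begin(), w.end(), 1.0);
    }
    if (per_tree_sampling)
      sample_features(rng, q, mtry, scratch_idx, tree_feats);

    std::vector<Node> nodes(1);
    {
      Node& root = nodes[0];
      for (int r = 0; r < p; ++r) {
        node_of[r] = (w[r] > 0.0) ? 0 : -1;
        root.n += w[r];
        root.sum += w[r] * y[r];
      }
      root.value = root.sum / root.n;
    }

    // evaluate the best split available to a leaf node
    auto eval_leaf = [&](int id) {
      Node& nd = nodes[id];
      nd.best_gain = -1.0;
      if (nd.n < 2.0) return;
      if (per_tree_sampling) feats = tree_feats;
      else sample_features(rng, q, mtry, scratch_idx, feats);
      const double parent = nd.sum * nd.sum / nd.n;
      for (size_t f = 0; f < feats.size(); ++f) {
        const int j = feats[f];
        const double* col = &X(0, j);
        const std::vector<int>& oj = order[j];
        double nl = 0.0, sl = 0.0;
        double prev_x = 0.0;
        bool have_prev = false;
        for (int k = 0; k < p; ++k) {
          const int r = oj[k];
          if (node_of[r] != id) continue;
          if (have_prev && col[r] > prev_x && nl > 0.0 && nd.n - nl > 0.0) {
            const double nr = nd.n - nl, sr = nd.sum - sl;
            const double gain = sl * sl / nl + sr * sr / nr - parent;
            // strict > keeps the first (lowest feature, lowest threshold)
            if (gain > nd.best_gain) {
              nd.best_gain = gain;
              nd.best_feature = j;
              nd.best_threshold = 0.5 * (prev_x + col[r]);
            }
          }
          nl += w[r];
          sl += w[r] * y[r];
          prev_x = col[r];
          have_prev = true;
        }
      }
    };

    eval_leaf(0);
    int n_leaves = 1;
    while (n_leaves < max_leaf_nodes) {
      // best-first: split the pending leaf with the largest gain
      int best = -1;
      for (size_t id = 0; id < nodes.size(); ++id)
        if (nodes[id].leaf && nodes[id].best_gain > 0.0 &&
            (best < 0 || nodes[id].best_gain > nodes[best].best_gain))
          best = static_cast<int>(id);
      if (best < 0) break;

      Node& nd = nodes[best];
      const int j = nd.best_feature;
      const double thr = nd.best_threshold;
      const int li = static_cast<int>(nodes.size());
      const int ri = li + 1;
      imp[j] += nd.best_gain;
      nd.leaf = false;
      nd.feature = j;
      nd.threshold = thr;
      nd.left = li;
      nd.right = ri;
      nodes.push_back(Node());
      nodes.push_back(Node());
      Node& L = nodes[li];
      Node& R = nodes[ri];
      for (int r = 0; r < p; ++r) {
        if (node_of[r] != best) continue;
        const int child = (X(r, j) <= thr) ? li : ri;
        node_of[r] = child;
        nodes[child].n += w[r];
        nodes[child].sum += w[r] * y[r];
      }
      L.value = L.sum / L.n;
      R.value = R.sum / R.n;
      eval_leaf(li);
      eval_leaf(ri);
      ++n_leaves;
    }

    // route every original row (bootstrap or not) for prediction
    for (int r = 0; r < p; ++r) {
      int id = 0;
      while (!nodes[id].leaf)
        id = (X(r, nodes[id].feature) <= nodes[id].threshold)
                 ? nodes[id].left : nodes[id].right;
      pred_sum[r] += nodes[id].value;
      if (want_oob && w[r] == 0.0) {
        oob_sum[r] += nodes[id].value;
        ++oob_cnt[r];
      }
    }
  }

  NumericVector fitted(p), importances(q);
  for (int r = 0; r < p; ++r) fitted[r] = pred_sum[r] / n_trees;
  for (int j = 0; j < q; ++j) importances[j] = imp[j] / n_trees;
  List out = List::create(_["fitted"] = fitted, _["importances"] = importances);
  if (want_oob) {
    NumericVector oob(p);
    for (int r = 0; r < p; ++r)
      oob[r] = oob_cnt[r] > 0 ? oob_sum[r] / oob_cnt[r] : NA_REAL;
    out["oob"] = oob;
  }
  return out;
}
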