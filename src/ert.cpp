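#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Extremely randomized trees (classification, probability output).
// Per node: mtry candidate features drawn without replacement; one uniform
// random threshold per candidate between the node's min and max; candidates
// scored by Gini impurity decrease; best split taken. Trees are grown on the
// full sample (no bootstrap) until nodes are pure or at/below min_node_size.
// Features are held in single precision; node sample indices are kept in
// ascending order (stable partitions) so per-candidate column scans stay
// prefetch-friendly. Uses R's RNG: reproducible under set.seed().

struct Node { int feat; double thr; int left, right; double value; };

// [[Rcpp::export]]
List ert_fit_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                 int min_node_size) {
  const int n = X.nrow(), d = X.ncol();
  if (mtry > d) mtry = d;
  std::vector<float> xf((size_t)n * d);
  {
    const double* xp = REAL(X);
    for (size_t i = 0; i < (size_t)n * d; ++i) xf[i] = (float)xp[i];
  }
  std::vector<Node> nodes;
  nodes.reserve((size_t)n_trees * 64);
  std::vector<int> roots(n_trees);
  std::vector<int> idx(n), featbuf(d), ybuf(n), scratch(n);
  std::vector<float> valbuf(n), bestval(n);
  struct Work { int lo, hi, node; };
  std::vector<Work> stack;

  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) idx[i] = i;
    roots[t] = (int)nodes.size();
    nodes.push_back(Node{-1, 0.0, -1, -1, 0.0});
    stack.push_back(Work{0, n, roots[t]});
    while (!stack.empty()) {
      Work w = stack.back(); stack.pop_back();
      const int m = w.hi - w.lo;
      int pos = 0;
      for (int i = w.lo; i < w.hi; ++i) pos += y[idx[i]];
      nodes[w.node].value = (double)pos / m;
      if (m < 2 || m <= min_node_size || pos == 0 || pos == m) continue;

      for (int i = 0; i < m; ++i) ybuf[i] = y[idx[w.lo + i]];
      int best_f = -1;
      float best_thr = 0.0f;
      double best_score = -1.0;
      for (int j = 0; j < d; ++j) featbuf[j] = j;
      int avail = d;
      for (int k = 0; k < mtry && avail > 0; ++k) {
        int pick = (int)(unif_rand() * avail);
        if (pick >= avail) pick = avail - 1;
        const int f = featbuf[pick];
        featbuf[pick] = featbuf[--avail];
        const float* col = &xf[(size_t)f * n];
        float lo = col[idx[w.lo]], hi = lo;
        for (int i = 0; i < m; ++i) {
          const float v = col[idx[w.lo + i]];
          valbuf[i] = v;
          if (v < lo) lo = v;
          if (v > hi) hi = v;
        }
        if (hi <= lo) continue;
        const float thr = lo + (float)unif_rand() * (hi - lo);
        int nl = 0, posl = 0;
        for (int i = 0; i < m; ++i) {        // branchless, vectorizable
          const int c = valbuf[i] < thr;
          nl += c;
          posl += c & ybuf[i];
        }
        if (nl == 0 || nl == m) continue;  // degenerate draw at boundary
        const int nr = m - nl, posr = pos - posl;
        // Gini decrease up to constants: maximize -sum_child n_c*gini_c
        const double score =
          ((double)posl * posl + (double)(nl - posl) * (nl - posl)) / nl +
          ((double)posr * posr + (double)(nr - posr) * (nr - posr)) / nr;
        if (score > best_score) {
          best_score = score; best_f = f; best_thr = thr;
          std::copy(valbuf.begin(), valbuf.begin() + m, bestval.begin());
        }
      }
      if (best_f < 0) continue;  // all candidates constant: leaf
      // stable partition: children keep ascending sample order
      int a = 0, b = 0;
      for (int i = 0; i < m; ++i) {
        const int id = idx[w.lo + i];
        if (bestval[i] < best_thr) idx[w.lo + a++] = id;
        else scratch[b++] = id;
      }
      for (int i = 0; i < b; ++i) idx[w.lo + a + i] = scratch[i];
      const int l = (int)nodes.size();
      nodes.push_back(Node{-1, 0.0, -1, -1, 0.0});
      nodes.push_back(Node{-1, 0.0, -1, -1, 0.0});
      nodes[w.node].feat = best_f;
      nodes[w.node].thr = (double)best_thr;
      nodes[w.node].left = l;
      nodes[w.node].right = l + 1;
      stack.push_back(Work{w.lo, w.lo + a, l});
      stack.push_back(Work{w.lo + a, w.hi, l + 1});
    }
  }

  const int nn = (int)nodes.size();
  IntegerVector feat(nn), left(nn), right(nn);
  NumericVector thr(nn), value(nn);
  for (int i = 0; i < nn; ++i) {
    feat[i] = nodes[i].feat; thr[i] = nodes[i].thr;
    left[i] = nodes[i].left; right[i] = nodes[i].right;
    value[i] = nodes[i].value;
  }
  return List::create(_["feature"] = feat, _["threshold"] = thr,
                      _["left"] = left, _["right"] = right,
                      _["value"] = value,
                      _["roots"] = IntegerVector(roots.begin(), roots.end()),
                      _["n_features"] = d);
}

// [[Rcpp::export]]
NumericVector ert_predict_cpp(List forest, NumericMatrix X) {
  IntegerVector feat = forest["feature"], left = forest["left"],
                right = forest["right"], roots = forest["roots"];
  NumericVector thr = forest["threshold"], value = forest["value"];
  const int n = X.nrow(), T = roots.size();
  const double* xp = REAL(X);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int t = 0; t < T; ++t) {
      int node = roots[t];
      while (feat[node] >= 0)
        node = ((float)xp[(size_t)feat[node] * n + i] < (float)thr[node])
                 ? left[node] : right[node];
      s += value[node];
    }
    out[i] = s / T;
  }
  return out;
}
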