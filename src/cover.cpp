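#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Exact maximum-weight laminar family over all 2^n sample subsets.
//
// The independent sets of the evolutionary conflict graph under full
// pattern enumeration are exactly the laminar families (any two patterns
// nested or disjoint), so the weighted minimum vertex cover is the
// complement of the maximum-weight laminar family.  All weights are
// non-negative, hence a pattern compatible with the whole family is always
// kept (ties broken towards keeping more patterns).
//
// Because all weights are non-negative, a set is always worth keeping when
// it is compatible with the rest of the family, so the best family over
// ground set U always contains U itself:
//   D[U] = w(U) + max( D[U \ {x}],                        x uncovered
//                      max_{V: x in V, V proper subset U} D[V] + D[U \ V] )
// where x is U's lowest element.  Submask enumeration gives O(3^n).
// Ties are broken towards keeping more patterns (removing fewer nodes).
// [[Rcpp::export(name = ".laminar_cover_dp")]]
List laminar_cover_dp(NumericVector weights, int n) {
  const int full = (1 << n) - 1;
  if ((int)weights.size() != full + 1)
    stop("weights must have length 2^n");
  const double eps = 1e-12;
  std::vector<double> D(full + 1);
  std::vector<int> Dcnt(full + 1), Dch(full + 1);

  D[0] = 0.0; Dcnt[0] = 0; Dch[0] = 0;  // empty mask handled separately
  for (int U = 1; U <= full; ++U) {
    const int low = U & (-U);
    const int rest = U ^ low;
    double bw = D[rest];                 // leave the lowest element uncovered
    int bc = Dcnt[rest], bch = 0;
    for (int T = rest; ; T = (T - 1) & rest) {
      const int V = T | low;             // every subset of U containing low
      if (V != U) {
        const double w = D[V] + D[U ^ V];
        const int c = Dcnt[V] + Dcnt[U ^ V];
        if (w > bw + eps || (w > bw - eps && c > bc)) {
          bw = w; bc = c; bch = V;
        }
      }
      if (T == 0) break;
    }
    D[U] = weights[U] + bw;
    Dcnt[U] = bc + 1;
    Dch[U] = bch;
  }

  // backtrack: kept = {0} plus the decomposition rooted at the full mask
  std::vector<char> kept(full + 1, 0);
  kept[0] = 1;
  std::vector<int> stack;
  stack.push_back(full);
  while (!stack.empty()) {
    int U = stack.back(); stack.pop_back();
    if (U == 0) continue;
    kept[U] = 1;
    const int ch = Dch[U];
    if (ch == 0) stack.push_back(U ^ (U & (-U)));
    else { stack.push_back(ch); stack.push_back(U ^ ch); }
  }
  IntegerVector kept_masks;
  double kept_weight = 0.0;
  std::vector<int> km;
  for (int U = 0; U <= full; ++U)
    if (kept[U]) { km.push_back(U); kept_weight += weights[U]; }
  return List::create(_["kept"] = wrap(km),
                      _["kept_weight"] = kept_weight);
}

// Exact maximum-weight independent set by branch and bound, for arbitrary
// graphs (restricted pattern sets, benchmark random graphs).  Vertices are
// explored by decreasing weight; the bound is the weight of all still-free
// vertices.  Deterministic by construction.
namespace {
struct BB {
  int n;
  std::vector<double> w;
  std::vector<std::vector<int>> adj;
  std::vector<int> order;       // vertices sorted by decreasing weight
  std::vector<char> state;      // 0 free, 1 excluded, 2 included
  double best_w;
  int best_cnt;
  std::vector<char> best_set;

  void search(double cur_w, int cur_cnt, double free_w, int next) {
    // advance to the first free vertex in the static order
    int v = -1;
    for (int k = next; k < n; ++k) {
      if (state[order[k]] == 0) { v = order[k]; next = k; break; }
    }
    if (v < 0) {
      if (cur_w > best_w + 1e-12 ||
          (cur_w > best_w - 1e-12 && cur_cnt > best_cnt)) {
        best_w = cur_w; best_cnt = cur_cnt;
        for (int i = 0; i < n; ++i) best_set[i] = (state[i] == 2);
      }
      return;
    }
    if (cur_w + free_w < best_w - 1e-12) return;  // bound

    // include v: exclude all free neighbours
    std::vector<int> newly;
    state[v] = 2;
    double fw = free_w - w[v];
    for (int u : adj[v]) if (state[u] == 0) {
      state[u] = 1; newly.push_back(u); fw -= w[u];
    }
    search(cur_w + w[v], cur_cnt + 1, fw, next + 1);
    for (int u : newly) state[u] = 0;
    // exclude v
    state[v] = 1;
    search(cur_w, cur_cnt, free_w - w[v], next + 1);
    state[v] = 0;
  }
};
}  // namespace

// [[Rcpp::export(name = ".mwis_branch_bound")]]
List mwis_branch_bound(NumericVector weights, IntegerMatrix edges) {
  BB bb;
  bb.n = weights.size();
  bb.w.assign(weights.begin(), weights.end());
  bb.adj.assign(bb.n, {});
  for (int r = 0; r < edges.nrow(); ++r) {
    int i = edges(r, 0) - 1, j = edges(r, 1) - 1;
    if (i == j) continue;
    bb.adj[i].push_back(j);
    bb.adj[j].push_back(i);
  }
  bb.order.resize(bb.n);
  for (int i = 0; i < bb.n; ++i) bb.order[i] = i;
  std::stable_sort(bb.order.begin(), bb.order.end(),
                   [&](int a, int b) { return bb.w[a] > bb.w[b]; });
  bb.state.assign(bb.n, 0);
  bb.best_w = -1.0; bb.best_cnt = -1;
  bb.best_set.assign(bb.n, 0);
  double total = 0.0;
  for (double x : bb.w) total += x;

  // isolated vertices are always independent: pre-include
  std::vector<int> iso;
  double iso_w = 0.0;
  for (int i = 0; i < bb.n; ++i) if (bb.adj[i].empty()) {
    bb.state[i] = 2; iso.push_back(i); iso_w += bb.w[i];
  }
  bb.search(iso_w, (int)iso.size(), total - iso_w, 0);

  std::vector<int> kept;
  for (int i = 0; i < bb.n; ++i) if (bb.best_set[i]) kept.push_back(i + 1);
  return List::create(_["kept"] = wrap(kept),
                      _["kept_weight"] = bb.best_w);
}
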