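// Topology weighting by iterative subtree sampling (Twisst-style).
// One leaf per taxon is drawn (exhaustively or by Monte-Carlo), the induced
// rooted subtree is classified by repeatedly agglomerating the pair of
// clusters with the deepest MRCA, and counts per canonical topology are
// returned.  Classification is purely topological (integer depth from the
// root), so non-ultrametric NJ trees and simulated genealogies are handled
// alike; ties (polytomies from zero-length branches) resolve to the first
// pair in scan order, which is deterministic.
//
// Combinations are classified to an integer code (the bitmasks of the
// merge steps); canonical labels are built once per distinct code.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <map>
#include <unordered_map>
#include <algorithm>
#include <climits>
#include <cstdint>

using namespace Rcpp;

static inline uint64_t splitmix64w(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

struct WRng {
  uint64_t s[2];
  explicit WRng(uint64_t seed) {
    s[0] = splitmix64w(seed);
    s[1] = splitmix64w(s[0] ^ 0xABCDEF1234567890ULL);
  }
  inline uint64_t next() {
    uint64_t s0 = s[0], s1 = s[1];
    uint64_t r = s0 + s1;
    s1 ^= s0;
    s[0] = ((s0 << 55) | (s0 >> 9)) ^ s1 ^ (s1 << 14);
    s[1] = (s1 << 36) | (s1 >> 28);
    return r;
  }
  inline int unif_int(int n) { return (int)(next() % (uint64_t)n); }
};

// depth of the MRCA of two leaves (edges from the root)
static int mrca_depth(int a, int b, const std::vector<int>& parent,
                      const std::vector<int>& depth) {
  while (a != b) {
    if (depth[a] > depth[b]) a = parent[a];
    else if (depth[b] > depth[a]) b = parent[b];
    else { a = parent[a]; b = parent[b]; }
  }
  return depth[a];
}

// classify one combination; returns an integer code built from the taxon
// bitmasks of the successive merges (the final all-taxa merge is implicit)
static int classify_combo(const int* combo, int T,
                          const std::vector<int>& D, int na) {
  int mask[4], memb[4][4], msize[4];
  int nc = T;
  for (int t = 0; t < T; ++t) {
    mask[t] = 1 << t;
    memb[t][0] = combo[t];
    msize[t] = 1;
  }
  int code = 0, shift = 0;
  while (nc > 2) {
    int bi = 0, bj = 1, bd = -1;
    for (int i = 0; i < nc; ++i)
      for (int j = i + 1; j < nc; ++j) {
        // MRCA depth of the union: shallowest pairwise depth
        int d = INT_MAX;
        for (int a = 0; a < msize[i]; ++a)
          for (int b = 0; b < msize[j]; ++b) {
            int dd = D[(size_t)memb[i][a] * na + memb[j][b]];
            if (dd < d) d = dd;
          }
        if (d > bd) { bd = d; bi = i; bj = j; }
      }
    // merge bj into bi, drop bj
    for (int b = 0; b < msize[bj]; ++b) memb[bi][msize[bi] + b] = memb[bj][b];
    msize[bi] += msize[bj];
    mask[bi] |= mask[bj];
    code |= mask[bi] << shift;
    shift += 5;
    --nc;
    if (bj != nc) {
      mask[bj] = mask[nc];
      msize[bj] = msize[nc];
      for (int b = 0; b < msize[nc]; ++b) memb[bj][b] = memb[nc][b];
    }
  }
  return code;
}

// canonical label for a merge-code: children of every internal node ordered
// by the smallest contained taxon index
static std::string code_label(int code, int T) {
  std::vector<int> masks, mins;
  std::vector<std::string> labels;
  for (int t = 0; t < T; ++t) {
    masks.push_back(1 << t);
    mins.push_back(t);
    labels.push_back(std::to_string(t));
  }
  std::vector<int> steps;
  int shift = 0;
  for (int k = 0; k < T - 2; ++k) {
    steps.push_back((code >> shift) & 31);
    shift += 5;
  }
  steps.push_back((1 << T) - 1);  // implicit root merge
  for (size_t s = 0; s < steps.size(); ++s) {
    int mm = steps[s];
    int i1 = -1, i2 = -1;
    for (size_t i = 0; i < masks.size() && i2 < 0; ++i)
      for (size_t j = i + 1; j < masks.size(); ++j)
        if ((masks[i] | masks[j]) == mm) { i1 = (int)i; i2 = (int)j; break; }
    if (i1 < 0) return "?";  // malformed code (cannot happen)
    int a = i1, b = i2;
    if (mins[b] < mins[a]) std::swap(a, b);
    std::string lab = "(" + labels[a] + "," + labels[b] + ")";
    masks[i1] = mm;
    mins[i1] = std::min(mins[i1], mins[i2]);
    labels[i1] = lab;
    masks.erase(masks.begin() + i2);
    mins.erase(mins.begin() + i2);
    labels.erase(labels.begin() + i2);
  }
  return labels[0];
}

// [[Rcpp::export]]
List cpp_topo_weights(IntegerVector parent_, List taxon_leaves, bool exact,
                      int n_iter, double cap, double seed) {
  int nn = parent_.size();
  std::vector<int> parent(nn);
  int root = -1;
  for (int v = 0; v < nn; ++v) {
    parent[v] = parent_[v];
    if (parent[v] < 0) root = v;
  }
  if (root < 0) stop("tree has no root");
  std::vector<int> depth(nn, -1);
  depth[root] = 0;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int v = 0; v < nn; ++v)
      if (depth[v] < 0 && parent[v] >= 0 && depth[parent[v]] >= 0) {
        depth[v] = depth[parent[v]] + 1;
        changed = true;
      }
  }
  int T = taxon_leaves.size();
  if (T < 3 || T > 4) stop("3 or 4 taxa are supported");
  std::vector<std::vector<int> > leaves(T);
  std::vector<int> all;
  for (int t = 0; t < T; ++t) {
    leaves[t] = as<std::vector<int> >(taxon_leaves[t]);  // 0-based node ids
    if (leaves[t].empty()) stop("taxon %d has no leaves", t + 1);
    for (size_t k = 0; k < leaves[t].size(); ++k) all.push_back(leaves[t][k]);
  }
  // pairwise MRCA depth over involved leaves, indexed by position in `all`
  std::vector<int> leaf_index(nn, -1);
  int na = (int)all.size();
  for (int k = 0; k < na; ++k) leaf_index[all[k]] = k;
  std::vector<int> D((size_t)na * na, 0);
  for (int i = 0; i < na; ++i)
    for (int j = i + 1; j < na; ++j)
      D[(size_t)i * na + j] = D[(size_t)j * na + i] =
        mrca_depth(all[i], all[j], parent, depth);
  // taxon leaf lists in `all`-index space
  std::vector<std::vector<int> > lv(T);
  for (int t = 0; t < T; ++t)
    for (size_t k = 0; k < leaves[t].size(); ++k)
      lv[t].push_back(leaf_index[leaves[t][k]]);

  std::unordered_map<int, double> counts;
  double n_comb = 1.0;
  for (int t = 0; t < T; ++t) n_comb *= (double)lv[t].size();
  int combo[4];
  if (exact) {
    if (n_comb > cap)
      stop("combination count %.0f exceeds the exact-mode cap (%.0f); "
           "use sampled mode", n_comb, cap);
    std::vector<int> idx(T, 0);
    while (true) {
      for (int t = 0; t < T; ++t) combo[t] = lv[t][idx[t]];
      counts[classify_combo(combo, T, D, na)] += 1.0;
      int t = T - 1;
      while (t >= 0 && ++idx[t] == (int)lv[t].size()) { idx[t] = 0; --t; }
      if (t < 0) break;
    }
  } else {
    WRng rng((uint64_t)seed);
    for (int it = 0; it < n_iter; ++it) {
      for (int t = 0; t < T; ++t)
        combo[t] = lv[t][rng.unif_int((int)lv[t].size())];
      counts[classify_combo(combo, T, D, na)] += 1.0;
    }
  }
  std::map<std::string, double> named;
  for (std::unordered_map<int, double>::iterator it = counts.begin();
       it != counts.end(); ++it)
    named[code_label(it->first, T)] += it->second;
  CharacterVector labels(named.size());
  NumericVector vals(named.size());
  int k = 0;
  for (std::map<std::string, double>::iterator it = named.begin();
       it != named.end(); ++it) {
    labels[k] = it->first;
    vals[k] = it->second;
    ++k;
  }
  return List::create(_["topology"] = labels, _["count"] = vals,
                      _["n_combinations"] = exact ? n_comb : (double)n_iter);
}
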