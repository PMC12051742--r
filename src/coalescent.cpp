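// Structured-coalescent core: genealogies for independent non-recombining
// loci under a piecewise demographic history (splits, migration epochs,
// exponential growth), plus infinite-sites / HKY mutation layers and
// branch-length joint-SFS accumulation.
//
// Time is backward, in generations, 0 = present.  Within a segment the
// per-pop size is N(t) = N_seg * exp(-g * (t - t_seg)) so the pairwise
// coalescence rate grows exponentially backward; waiting times are drawn
// exactly by inversion of the integrated rate.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <string>
#include <map>
#include <algorithm>
#include <unordered_set>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: counter-based per-locus seeding so locus i is reproducible
// independently of how many loci are requested.

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

struct Rng {
  uint64_t s[2];
  explicit Rng(uint64_t seed) {
    s[0] = splitmix64(seed);
    s[1] = splitmix64(s[0] ^ 0xDEADBEEFCAFEBABEULL);
  }
  // xoroshiro128+
  inline uint64_t next() {
    uint64_t s0 = s[0], s1 = s[1];
    uint64_t r = s0 + s1;
    s1 ^= s0;
    s[0] = ((s0 << 55) | (s0 >> 9)) ^ s1 ^ (s1 << 14);
    s[1] = (s1 << 36) | (s1 >> 28);
    return r;
  }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double expo() { return -std::log(unif()); }
  inline int unif_int(int n) { return (int)(next() % (uint64_t)n); }
  int poisson(double lambda) {
    if (lambda <= 0.0) return 0;
    if (lambda < 30.0) {
      double L = std::exp(-lambda), p = 1.0;
      int k = 0;
      do { ++k; p *= unif(); } while (p > L);
      return k - 1;
    }
    // Normal approximation with continuity correction for large means.
    double u1 = unif(), u2 = unif();
    double z = std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
    double v = lambda + std::sqrt(lambda) * z;
    return v < 0.0 ? 0 : (int)(v + 0.5);
  }
};

static inline uint64_t locus_seed(uint64_t master, uint64_t idx) {
  return splitmix64(master * 0x9E3779B97F4A7C15ULL + idx + 1ULL);
}

// ---------------------------------------------------------------------------
// Engine specification compiled on the R side (times already in generations).

struct EngineSpec {
  int n_pop;
  std::vector<int> samples;                 // haploid per pop
  std::vector<double> breaks;               // segment start times
  std::vector<std::vector<double> > N;      // [seg][pop] size at segment start
  std::vector<std::vector<double> > g;      // [seg][pop] backward decline rate
  std::vector<std::vector<bool> > active;   // [seg][pop]
  std::vector<std::vector<double> > mig;    // [seg][j*n_pop+i] rate j -> i
  std::vector<std::vector<double> > migrow; // [seg][j] row sums
  std::vector<std::vector<std::pair<int,int> > > merges; // on entering seg
};

static EngineSpec parse_spec(const List& spec) {
  EngineSpec es;
  es.n_pop = as<int>(spec["n_pop"]);
  es.samples = as<std::vector<int> >(spec["samples"]);
  es.breaks = as<std::vector<double> >(spec["breaks"]);
  int nseg = (int)es.breaks.size();
  NumericMatrix N = spec["N"], g = spec["g"];
  LogicalMatrix act = spec["active"];
  List mig = spec["mig"], mg = spec["merges"];
  es.N.resize(nseg); es.g.resize(nseg); es.active.resize(nseg);
  es.mig.resize(nseg); es.migrow.resize(nseg); es.merges.resize(nseg);
  for (int s = 0; s < nseg; ++s) {
    es.N[s].resize(es.n_pop); es.g[s].resize(es.n_pop);
    es.active[s].resize(es.n_pop);
    for (int p = 0; p < es.n_pop; ++p) {
      es.N[s][p] = N(s, p); es.g[s][p] = g(s, p);
      es.active[s][p] = act(s, p);
    }
    NumericMatrix M = mig[s];
    es.mig[s].assign(es.n_pop * es.n_pop, 0.0);
    es.migrow[s].assign(es.n_pop, 0.0);
    for (int j = 0; j < es.n_pop; ++j)
      for (int i = 0; i < es.n_pop; ++i) {
        es.mig[s][j * es.n_pop + i] = M(j, i);
        es.migrow[s][j] += M(j, i);
      }
    IntegerMatrix mm = mg[s];
    for (int k = 0; k < mm.ncol(); ++k)
      es.merges[s].push_back(std::make_pair(mm(0, k), mm(1, k)));
  }
  return es;
}

// ---------------------------------------------------------------------------

struct Genealogy {
  int n_leaves;
  std::vector<int> parent;     // -1 at root
  std::vector<double> time;
  std::vector<int> child1, child2;
  std::vector<int> leaf_pop;
};

static Genealogy sim_genealogy(const EngineSpec& es, Rng& rng) {
  int np = es.n_pop;
  int n_leaves = 0;
  for (int p = 0; p < np; ++p) n_leaves += es.samples[p];
  Genealogy G;
  G.n_leaves = n_leaves;
  int n_nodes_max = 2 * n_leaves - 1;
  G.parent.assign(n_nodes_max, -1);
  G.time.assign(n_nodes_max, 0.0);
  G.child1.assign(n_nodes_max, -1);
  G.child2.assign(n_nodes_max, -1);
  G.leaf_pop.resize(n_leaves);

  std::vector<std::vector<int> > lin(np);
  int id = 0;
  for (int p = 0; p < np; ++p)
    for (int k = 0; k < es.samples[p]; ++k) {
      lin[p].push_back(id);
      G.leaf_pop[id] = p;
      ++id;
    }
  int next_node = n_leaves;
  int total = n_leaves;
  int nseg = (int)es.breaks.size();
  int seg = 0;
  double t = 0.0;
  long long guard = 0;

  while (total > 1) {
    if (++guard > 200000000LL) stop("coalescent engine: event cap exceeded");
    double seg_start = es.breaks[seg];
    double seg_end = (seg + 1 < nseg) ? es.breaks[seg + 1] : R_PosInf;

    // candidate coalescence per population (exact inversion under growth)
    double best = R_PosInf;
    int ev_pop = -1;  // >=0 coalescence in pop, -2 migration
    for (int p = 0; p < np; ++p) {
      int n = (int)lin[p].size();
      if (n < 2 || !es.active[seg][p]) continue;
      double Ncur = es.N[seg][p];
      double gg = es.g[seg][p];
      if (gg != 0.0) Ncur *= std::exp(-gg * (t - seg_start));
      double lam0 = 0.25 * n * (n - 1) / Ncur;  // C(n,2) / (2N)
      double E = rng.expo();
      double s = (gg != 0.0) ? std::log1p(gg * E / lam0) / gg : E / lam0;
      if (s < best) { best = s; ev_pop = p; }
    }
    // candidate migration (rates constant within a segment)
    double R = 0.0;
    for (int p = 0; p < np; ++p)
      if (!lin[p].empty()) R += lin[p].size() * es.migrow[seg][p];
    if (R > 0.0) {
      double s = rng.expo() / R;
      if (s < best) { best = s; ev_pop = -2; }
    }

    if (t + best >= seg_end) {
      if (seg + 1 >= nseg)
        stop("coalescent engine: lineages cannot find a common ancestor "
             "(final segment has isolated occupied populations)");
      t = seg_end;
      ++seg;
      for (size_t k = 0; k < es.merges[seg].size(); ++k) {
        int from = es.merges[seg][k].first, to = es.merges[seg][k].second;
        for (size_t i = 0; i < lin[from].size(); ++i)
          lin[to].push_back(lin[from][i]);
        lin[from].clear();
      }
      continue;
    }
    t += best;
    if (ev_pop >= 0) {
      std::vector<int>& L = lin[ev_pop];
      int n = (int)L.size();
      int a = rng.unif_int(n);
      int b = rng.unif_int(n - 1);
      if (b >= a) ++b;
      if (a > b) std::swap(a, b);
      int node = next_node++;
      G.time[node] = t;
      G.child1[node] = L[a]; G.child2[node] = L[b];
      G.parent[L[a]] = node; G.parent[L[b]] = node;
      L[a] = node;
      L[b] = L[n - 1];
      L.pop_back();
      --total;
    } else {
      // migration: pick source pop weighted by n_j * rowsum_j
      double u = rng.unif() * R, acc = 0.0;
      int j = -1;
      for (int p = 0; p < np; ++p) {
        if (lin[p].empty()) continue;
        acc += lin[p].size() * es.migrow[seg][p];
        if (u <= acc) { j = p; break; }
      }
      if (j < 0) j = np - 1;
      int li = rng.unif_int((int)lin[j].size());
      double u2 = rng.unif() * es.migrow[seg][j], acc2 = 0.0;
      int dest = -1;
      for (int i = 0; i < np; ++i) {
        acc2 += es.mig[seg][j * np + i];
        if (u2 <= acc2) { dest = i; break; }
      }
      if (dest < 0) continue;
      lin[dest].push_back(lin[j][li]);
      lin[j][li] = lin[j].back();
      lin[j].pop_back();
    }
  }
  return G;
}

// per-node descendant leaf counts per population
static void leaf_counts(const Genealogy& G, int np, std::vector<int>& cnt) {
  int nn = 2 * G.n_leaves - 1;
  cnt.assign((size_t)nn * np, 0);
  for (int l = 0; l < G.n_leaves; ++l) cnt[(size_t)l * np + G.leaf_pop[l]] = 1;
  for (int v = G.n_leaves; v < nn; ++v) {
    int c1 = G.child1[v], c2 = G.child2[v];
    for (int p = 0; p < np; ++p)
      cnt[(size_t)v * np + p] =
        cnt[(size_t)c1 * np + p] + cnt[(size_t)c2 * np + p];
  }
}

// ---------------------------------------------------------------------------
// Joint-SFS accumulation over loci.  mode 0: expected branch lengths,
// mode 1: Poisson mutation counts (observed-like).

// [[Rcpp::export]]
List cpp_sim_jsfs(List spec, int n_loci, double locus_length, double mu,
                  IntegerMatrix pairs, double seed, bool poisson) {
  EngineSpec es = parse_spec(spec);
  int np = es.n_pop, npair = pairs.nrow();
  std::vector<NumericMatrix> out;
  for (int k = 0; k < npair; ++k) {
    int a = pairs(k, 0), b = pairs(k, 1);
    out.push_back(NumericMatrix(es.samples[a] + 1, es.samples[b] + 1));
  }
  std::vector<int> cnt;
  for (int l = 0; l < n_loci; ++l) {
    Rng rng(locus_seed((uint64_t)seed, (uint64_t)l));
    Genealogy G = sim_genealogy(es, rng);
    leaf_counts(G, np, cnt);
    int nn = 2 * G.n_leaves - 1;
    for (int v = 0; v < nn; ++v) {
      if (G.parent[v] < 0) continue;
      double blen = G.time[G.parent[v]] - G.time[v];
      double w = blen;
      if (poisson) {
        int m = rng.poisson(mu * locus_length * blen);
        if (m == 0) continue;
        w = (double)m;
      }
      for (int k = 0; k < npair; ++k) {
        int a = pairs(k, 0), b = pairs(k, 1);
        out[k](cnt[(size_t)v * np + a], cnt[(size_t)v * np + b]) += w;
      }
    }
    if ((l & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  List res(npair);
  for (int k = 0; k < npair; ++k) res[k] = out[k];
  return res;
}

// ---------------------------------------------------------------------------
// Per-locus summary statistics: TMRCA, total branch length, S ~ Poisson.

// [[Rcpp::export]]
NumericMatrix cpp_sim_stats(List spec, int n_loci, double locus_length,
                            double mu, double seed) {
  EngineSpec es = parse_spec(spec);
  NumericMatrix out(n_loci, 3);
  colnames(out) = CharacterVector::create("tmrca", "total_length", "n_mut");
  for (int l = 0; l < n_loci; ++l) {
    Rng rng(locus_seed((uint64_t)seed, (uint64_t)l));
    Genealogy G = sim_genealogy(es, rng);
    int nn = 2 * G.n_leaves - 1;
    double tot = 0.0;
    for (int v = 0; v < nn; ++v)
      if (G.parent[v] >= 0) tot += G.time[G.parent[v]] - G.time[v];
    out(l, 0) = G.time[nn - 1];
    out(l, 1) = tot;
    out(l, 2) = rng.poisson(mu * locus_length * tot);
    if ((l & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// ---------------------------------------------------------------------------
// Infinite-sites SNP loci: 0/1 haplotype matrices with distinct positions.

static List one_snp_locus(const EngineSpec& es, Rng& rng, double locus_length,
                          double mu) {
  int np = es.n_pop;
  Genealogy G = sim_genealogy(es, rng);
  int nn = 2 * G.n_leaves - 1;
  std::vector<double> cum(nn, 0.0);
  double tot = 0.0;
  for (int v = 0; v < nn; ++v) {
    if (G.parent[v] >= 0) tot += G.time[G.parent[v]] - G.time[v];
    cum[v] = tot;
  }
  int L = (int)locus_length;
  int m = rng.poisson(mu * locus_length * tot);
  if (m > L) m = L;  // infinite-sites on a finite grid: at most L sites
  // distinct positions
  std::unordered_set<int> used;
  std::vector<int> pos(m);
  for (int k = 0; k < m; ++k) {
    int p;
    do { p = 1 + rng.unif_int(L); } while (used.count(p));
    used.insert(p);
    pos[k] = p;
  }
  // branch per mutation, then carriers
  std::vector<int> branch(m);
  for (int k = 0; k < m; ++k) {
    double u = rng.unif() * tot;
    branch[k] = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
  }
  std::vector<int> ord(m);
  for (int k = 0; k < m; ++k) ord[k] = k;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return pos[a] < pos[b]; });
  IntegerMatrix geno(G.n_leaves, m);
  IntegerVector position(m);
  std::vector<int> stack;
  for (int k = 0; k < m; ++k) {
    int mk = ord[k];
    position[k] = pos[mk];
    stack.clear();
    stack.push_back(branch[mk]);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      if (v < G.n_leaves) geno(v, k) = 1;
      else { stack.push_back(G.child1[v]); stack.push_back(G.child2[v]); }
    }
  }
  (void)np;
  return List::create(_["positions"] = position, _["geno"] = geno);
}

// [[Rcpp::export]]
List cpp_sim_snp_loci(List spec, int n_loci, double locus_length, double mu,
                      double seed) {
  EngineSpec es = parse_spec(spec);
  List out(n_loci);
  for (int l = 0; l < n_loci; ++l) {
    Rng rng(locus_seed((uint64_t)seed, (uint64_t)l));
    out[l] = one_snp_locus(es, rng, locus_length, mu);
    if ((l & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// ---------------------------------------------------------------------------
// Genealogies as parent/time arrays (for trees and downstream weighting).

// [[Rcpp::export]]
List cpp_sim_genealogies(List spec, int n_loci, double seed) {
  EngineSpec es = parse_spec(spec);
  List out(n_loci);
  for (int l = 0; l < n_loci; ++l) {
    Rng rng(locus_seed((uint64_t)seed, (uint64_t)l));
    Genealogy G = sim_genealogy(es, rng);
    int nn = 2 * G.n_leaves - 1;
    IntegerVector par(nn);
    NumericVector tm(nn);
    for (int v = 0; v < nn; ++v) { par[v] = G.parent[v]; tm[v] = G.time[v]; }
    out[l] = List::create(_["parent"] = par, _["time"] = tm,
                          _["n_leaves"] = G.n_leaves,
                          _["leaf_pop"] = IntegerVector(G.leaf_pop.begin(),
                                                        G.leaf_pop.end()));
    if ((l & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// ---------------------------------------------------------------------------
// Finite-sites HKY mutation layer on a fixed genealogy.  Equal base
// frequencies; a mutation is a transition with probability ts_fraction,
// otherwise one of the two transversions equiprobably.  Recurrent hits and
// back-mutation are possible.  Bases: 0=A, 1=C, 2=G, 3=T; transition
// partner is b XOR 2.

// [[Rcpp::export]]
List cpp_mutate_hky(IntegerVector parent, NumericVector time, int n_leaves,
                    double locus_length, double mu, double ts_fraction,
                    double seed) {
  int nn = parent.size();
  Rng rng((uint64_t)seed);
  std::vector<std::vector<int> > children(nn);
  int root = -1;
  double tot = 0.0;
  std::vector<double> cum(nn, 0.0);
  for (int v = 0; v < nn; ++v) {
    if (parent[v] >= 0) {
      children[parent[v]].push_back(v);
      tot += time[parent[v]] - time[v];
    } else root = v;
    cum[v] = tot;
  }
  int L = (int)locus_length;
  int M = rng.poisson(mu * locus_length * tot);
  // mutations: site, branch (child node), age within branch, type draws
  std::vector<int> m_site(M), m_branch(M);
  std::vector<double> m_age(M), m_u1(M), m_u2(M);
  for (int k = 0; k < M; ++k) {
    m_site[k] = rng.unif_int(L);
    double u = rng.unif() * tot;
    int v = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    m_branch[k] = v;
    double lo = time[v], hi = time[parent[v]];
    m_age[k] = lo + rng.unif() * (hi - lo);
    m_u1[k] = rng.unif(); m_u2[k] = rng.unif();
  }
  // group mutations by site
  std::map<int, std::vector<int> > by_site;
  for (int k = 0; k < M; ++k) by_site[m_site[k]].push_back(k);

  int n_ts = 0;
  std::vector<int> keep_pos;
  std::vector<int> keep_anc;
  std::vector<std::vector<int> > keep_cols;
  std::vector<int> base(nn);
  std::vector<int> order;
  for (std::map<int, std::vector<int> >::iterator it = by_site.begin();
       it != by_site.end(); ++it) {
    const std::vector<int>& muts = it->second;
    int anc = rng.unif_int(4);
    // evaluate bases down the tree
    std::vector<std::pair<int,int> > stack;  // node
    base[root] = anc;
    std::vector<int> dfs;
    dfs.push_back(root);
    while (!dfs.empty()) {
      int v = dfs.back(); dfs.pop_back();
      if (v != root) {
        int b = base[parent[v]];
        // apply this branch's mutations from oldest to youngest
        order.clear();
        for (size_t k = 0; k < muts.size(); ++k)
          if (m_branch[muts[k]] == v) order.push_back(muts[k]);
        std::sort(order.begin(), order.end(),
                  [&](int a, int c) { return m_age[a] > m_age[c]; });
        for (size_t k = 0; k < order.size(); ++k) {
          int mk = order[k];
          if (m_u1[mk] < ts_fraction) { b ^= 2; ++n_ts; }
          else {
            // transversion: flip purine/pyrimidine class
            int tv1 = (b ^ 1), tv2 = (b ^ 3);
            b = (m_u2[mk] < 0.5) ? tv1 : tv2;
          }
        }
        base[v] = b;
      }
      for (size_t c = 0; c < children[v].size(); ++c)
        dfs.push_back(children[v][c]);
    }
    // polymorphic among leaves?
    bool poly = false;
    for (int l = 1; l < n_leaves; ++l)
      if (base[l] != base[0]) { poly = true; break; }
    if (poly) {
      keep_pos.push_back(it->first + 1);
      keep_anc.push_back(anc);
      std::vector<int> col(n_leaves);
      for (int l = 0; l < n_leaves; ++l) col[l] = base[l];
      keep_cols.push_back(col);
    }
  }
  int S = (int)keep_pos.size();
  IntegerMatrix alle(n_leaves, S);
  for (int s = 0; s < S; ++s)
    for (int l = 0; l < n_leaves; ++l) alle(l, s) = keep_cols[s][l];
  return List::create(_["positions"] = IntegerVector(keep_pos.begin(), keep_pos.end()),
                      _["alleles"] = alle,
                      _["ancestral"] = IntegerVector(keep_anc.begin(), keep_anc.end()),
                      _["n_mutations"] = M,
                      _["n_transitions"] = n_ts);
}
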