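#include <Rcpp.h>
#include <vector>
#include <array>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Skeletonization: sequential topology-preserving thinning.
//
// A pixel is deleted iff it is an 8-simple point (its occupied neighbours
// form exactly one 8-connected set within the 3x3 ring, and its background
// 4-neighbours belong to exactly one 4-connected background set of the
// ring) and it has at least two occupied neighbours (endpoints are
// preserved). Deleting a simple point changes neither the number of
// foreground components nor the number of background components, so
// iterating immediate (sequential) deletions to convergence yields a
// one-pixel-wide skeleton with the same topology as the input. A cleanup
// pass removes simple pixels from any residual fully-occupied 2x2 block.
//
// Simplicity is precomputed for all 256 neighbourhood configurations; bit
// order N,NE,E,SE,S,SW,W,NW.
// ---------------------------------------------------------------------------

static const int NBR_DR[8] = { -1, -1, 0, 1, 1, 1, 0, -1 };
static const int NBR_DC[8] = { 0, 1, 1, 1, 0, -1, -1, -1 };

static void build_simple_lut(std::vector<uint8_t> &lut) {
  lut.assign(256, 0);
  for (int cfg = 0; cfg < 256; ++cfg) {
    int b = 0;
    for (int i = 0; i < 8; ++i) if (cfg & (1 << i)) ++b;
    if (b < 2) continue; // isolated pixel or endpoint: keep

    // foreground components within the ring (8-adjacency between cells)
    int comp[8];
    for (int i = 0; i < 8; ++i) comp[i] = -1;
    int nfg = 0;
    for (int i = 0; i < 8; ++i) {
      if (!(cfg & (1 << i)) || comp[i] >= 0) continue;
      // BFS
      int stack[8], sp = 0;
      stack[sp++] = i; comp[i] = nfg;
      while (sp) {
        int u = stack[--sp];
        for (int v = 0; v < 8; ++v) {
          if (!(cfg & (1 << v)) || comp[v] >= 0) continue;
          if (std::abs(NBR_DR[u] - NBR_DR[v]) <= 1 &&
              std::abs(NBR_DC[u] - NBR_DC[v]) <= 1) {
            comp[v] = nfg; stack[sp++] = v;
          }
        }
      }
      ++nfg;
    }
    if (nfg != 1) continue;

    // background components (4-adjacency) containing a 4-neighbour of p
    int bcomp[8];
    for (int i = 0; i < 8; ++i) bcomp[i] = -1;
    int nbg = 0;
    for (int i = 0; i < 8; ++i) {
      if ((cfg & (1 << i)) || bcomp[i] >= 0) continue;
      int stack[8], sp = 0;
      stack[sp++] = i; bcomp[i] = nbg;
      bool touches4 = (i % 2 == 0); // even indices are the 4-neighbours
      while (sp) {
        int u = stack[--sp];
        for (int v = 0; v < 8; ++v) {
          if ((cfg & (1 << v)) || bcomp[v] >= 0) continue;
          if (std::abs(NBR_DR[u] - NBR_DR[v]) +
              std::abs(NBR_DC[u] - NBR_DC[v]) == 1) {
            bcomp[v] = nbg; stack[sp++] = v;
            if (v % 2 == 0) touches4 = true;
          }
        }
      }
      if (touches4) ++nbg; else { // not adjacent to p: irrelevant cavity
        for (int j = 0; j < 8; ++j) if (bcomp[j] == nbg) bcomp[j] = 100;
      }
    }
    if (nbg == 1) lut[cfg] = 1;
  }
}

// classic two-subiteration parallel-thinning marking rules (neighbour
// count 2..6, single 0->1 crossing, directional corner products zero)
static void build_zs_luts(std::vector<uint8_t> &zs0, std::vector<uint8_t> &zs1) {
  zs0.assign(256, 0);
  zs1.assign(256, 0);
  for (int cfg = 0; cfg < 256; ++cfg) {
    int p[8];
    int b = 0;
    for (int i = 0; i < 8; ++i) { p[i] = (cfg >> i) & 1; b += p[i]; }
    if (b < 2 || b > 6) continue;
    int a = 0;
    for (int i = 0; i < 8; ++i)
      if (p[i] == 0 && p[(i + 1) % 8] == 1) ++a;
    if (a != 1) continue;
    // p[0]=N, p[2]=E, p[4]=S, p[6]=W
    if (!(p[0] && p[2] && p[4]) && !(p[2] && p[4] && p[6])) zs0[cfg] = 1;
    if (!(p[0] && p[2] && p[6]) && !(p[0] && p[4] && p[6])) zs1[cfg] = 1;
  }
}

static inline int nbr_config(const std::vector<uint8_t> &g, int w, int idx) {
  int cfg = 0;
  for (int i = 0; i < 8; ++i)
    if (g[idx + NBR_DR[i] * w + NBR_DC[i]]) cfg |= (1 << i);
  return cfg;
}

static inline int nbr_sum(const std::vector<uint8_t> &g, int w, int idx) {
  return g[idx - w] + g[idx - w + 1] + g[idx + 1] + g[idx + w + 1] +
         g[idx + w] + g[idx + w - 1] + g[idx - 1] + g[idx - w - 1];
}

// [[Rcpp::export]]
LogicalMatrix thin_skeleton_cpp(LogicalMatrix bw) {
  int nr = bw.nrow(), nc = bw.ncol();
  int w = nc + 2;
  std::vector<uint8_t> g((nr + 2) * (size_t)w, 0);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      g[(r + 1) * (size_t)w + (c + 1)] = bw(r, c) ? 1 : 0;

  static std::vector<uint8_t> lut, zs0, zs1;
  if (lut.empty()) {
    build_simple_lut(lut);
    build_zs_luts(zs0, zs1);
  }

  // Zhang-Suen-style directional subiterations: candidates are marked on a
  // snapshot (so erosion is transverse and curve length is preserved), but
  // each deletion is re-verified as 8-simple in the current grid, which
  // keeps components and endpoints intact where the parallel rule alone
  // would not.
  std::vector<size_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      const std::vector<uint8_t> &zs = sub == 0 ? zs0 : zs1;
      cand.clear();
      for (int r = 1; r <= nr; ++r)
        for (int c = 1; c <= nc; ++c) {
          size_t idx = r * (size_t)w + c;
          if (g[idx] && zs[nbr_config(g, w, idx)]) cand.push_back(idx);
        }
      for (size_t i = 0; i < cand.size(); ++i) {
        if (lut[nbr_config(g, w, cand[i])]) {
          g[cand[i]] = 0;
          changed = true;
        }
      }
    }
  }

  // redundancy pass: on a one-pixel-wide structure a simple pixel with
  // >= 2 neighbours is necessarily a corner or junction surplus (a curve
  // pixel whose two neighbours are not mutually adjacent is not simple),
  // so this dissolves residual staircases without shortening curves
  changed = true;
  while (changed) {
    changed = false;
    for (int r = 1; r <= nr; ++r) {
      for (int c = 1; c <= nc; ++c) {
        size_t idx = r * (size_t)w + c;
        if (!g[idx]) continue;
        if (lut[nbr_config(g, w, idx)]) {
          g[idx] = 0;
          changed = true;
        }
      }
    }
  }

  // remove residual 2x2 blocks (rare; only pixels that are still simple)
  changed = true;
  while (changed) {
    changed = false;
    for (int r = 1; r < nr; ++r) {
      for (int c = 1; c < nc; ++c) {
        size_t idx = r * (size_t)w + c;
        if (g[idx] && g[idx + 1] && g[idx + w] && g[idx + w + 1]) {
          size_t cand[4] = { idx, idx + 1, idx + (size_t)w, idx + (size_t)w + 1 };
          for (int i = 0; i < 4; ++i) {
            if (lut[nbr_config(g, w, cand[i])]) {
              g[cand[i]] = 0;
              changed = true;
              break;
            }
          }
        }
      }
    }
  }

  LogicalMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      out(r, c) = g[(r + 1) * (size_t)w + (c + 1)] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// 8-connected component labelling (iterative flood fill).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix label_components8_cpp(LogicalMatrix bw) {
  int nr = bw.nrow(), nc = bw.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!bw(r0, c0) || lab(r0, c0)) continue;
      ++next;
      lab(r0, c0) = next;
      stack.push_back(r0 + c0 * nr);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int r = p % nr, c = p / nr;
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (bw(rr, cc) && !lab(rr, cc)) {
              lab(rr, cc) = next;
              stack.push_back(rr + cc * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Lempel-Ziv (1976) production complexity c(n) of a symbol sequence,
// exhaustive-history parsing with self-referential matches.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
int lz76_cpp(IntegerVector s) {
  int n = s.size();
  if (n == 0) return 0;
  int c = 1, l = 1, i = 0, k = 1, kmax = 1;
  while (true) {
    if (s[i + k - 1] != s[l + k - 1]) {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    } else {
      ++k;
      if (l + k > n) { ++c; break; }
    }
  }
  return c;
}

// ---------------------------------------------------------------------------
// Agent-based fission/fusion dynamics over L dimers (Gillespie algorithm).
//
// Tips of dimers merge into nodes of degree 1, 2 or 3. Reaction channels and
// mass-action propensities (a_i = c_i * b_i):
//   tip-to-tip fusion   2 X1 -> X2       A1 = a1 * n1 (n1 - 1) / 2
//   tip-to-tip fission  X2 -> 2 X1       B1 = b1 * n2
//   tip-to-side fusion  X1 + X2 -> X3    A2 = a2 * n1 * n2
//   tip-to-side fission X3 -> X1 + X2    B2 = b2 * n3
// Participants are drawn uniformly from the list of nodes with the matching
// degree; for 3 -> 1 + 2 the departing tip is uniform among the node's three
// tips. Randomness comes from R's RNG so set.seed() governs the simulation.
// ---------------------------------------------------------------------------

struct FFState {
  int L;
  std::vector<int> node_of_tip;            // 2L tips
  std::vector<std::array<int, 3>> tips;    // tips per node id
  std::vector<int> deg;                    // 0 = free id
  std::vector<int> free_ids;
  std::vector<int> lst[4];                 // node ids by degree 1..3
  std::vector<int> pos;                    // position in its degree list

  explicit FFState(int L_) : L(L_) {
    int n = 2 * L;
    node_of_tip.resize(n);
    tips.resize(n);
    deg.assign(n, 0);
    pos.assign(n, -1);
    for (int t = 0; t < n; ++t) {
      node_of_tip[t] = t;
      tips[t][0] = t;
      deg[t] = 1;
      pos[t] = (int)lst[1].size();
      lst[1].push_back(t);
    }
  }

  void list_remove(int node) {
    std::vector<int> &v = lst[deg[node]];
    int p = pos[node];
    int last = v.back();
    v[p] = last;
    pos[last] = p;
    v.pop_back();
    pos[node] = -1;
  }
  void list_add(int node, int d) {
    deg[node] = d;
    pos[node] = (int)lst[d].size();
    lst[d].push_back(node);
  }
  int sample_from(int d) {
    int sz = (int)lst[d].size();
    int i = (int)(unif_rand() * sz);
    if (i >= sz) i = sz - 1;
    return lst[d][i];
  }
};

static void uf_init(std::vector<int> &par, int n) {
  par.resize(n);
  for (int i = 0; i < n; ++i) par[i] = i;
}
static int uf_find(std::vector<int> &par, int x) {
  while (par[x] != x) { par[x] = par[par[x]]; x = par[x]; }
  return x;
}

// [[Rcpp::export]]
List simulate_ff_cpp(int L, double c1, double c2, double b1, double b2,
                     int n_events, bool record_trace = false,
                     bool return_edges = false) {
  if (L < 1) stop("L must be >= 1");
  FFState st(L);
  double a1 = c1 * b1, a2 = c2 * b2;

  IntegerMatrix trace;
  if (record_trace) trace = IntegerMatrix(n_events, 3);

  bool absorbed = false;
  int events_done = 0;

  for (int e = 0; e < n_events; ++e) {
    double n1 = (double)st.lst[1].size();
    double n2 = (double)st.lst[2].size();
    double n3 = (double)st.lst[3].size();
    double A1 = a1 * n1 * (n1 - 1.0) / 2.0;
    double B1 = b1 * n2;
    double A2 = a2 * n1 * n2;
    double B2 = b2 * n3;
    double tot = A1 + B1 + A2 + B2;
    if (tot <= 0.0) { absorbed = true; break; }

    double u = unif_rand() * tot;
    if (u < A1) {
      // tip-to-tip fusion: two distinct degree-1 nodes merge
      int sz = (int)st.lst[1].size();
      int i1 = (int)(unif_rand() * sz); if (i1 >= sz) i1 = sz - 1;
      int i2 = (int)(unif_rand() * (sz - 1)); if (i2 >= sz - 1) i2 = sz - 2;
      if (i2 >= i1) ++i2;
      int u1 = st.lst[1][i1], u2 = st.lst[1][i2];
      st.list_remove(u1);
      st.list_remove(u2);
      st.tips[u1][1] = st.tips[u2][0];
      st.node_of_tip[st.tips[u2][0]] = u1;
      st.deg[u2] = 0;
      st.free_ids.push_back(u2);
      st.list_add(u1, 2);
    } else if (u < A1 + B1) {
      // tip-to-tip fission: degree-2 node splits into two tips
      int v = st.sample_from(2);
      st.list_remove(v);
      int t1 = st.tips[v][1];
      int id = st.free_ids.back(); st.free_ids.pop_back();
      st.tips[id][0] = t1;
      st.node_of_tip[t1] = id;
      st.list_add(id, 1);
      st.list_add(v, 1);
    } else if (u < A1 + B1 + A2) {
      // tip-to-side fusion: degree-1 joins degree-2
      int v1 = st.sample_from(1);
      int v2 = st.sample_from(2);
      st.list_remove(v1);
      st.list_remove(v2);
      st.tips[v2][2] = st.tips[v1][0];
      st.node_of_tip[st.tips[v1][0]] = v2;
      st.deg[v1] = 0;
      st.free_ids.push_back(v1);
      st.list_add(v2, 3);
    } else {
      // tip-to-side fission: one of the three tips departs
      int v = st.sample_from(3);
      st.list_remove(v);
      int j = (int)(unif_rand() * 3.0); if (j > 2) j = 2;
      int t_out = st.tips[v][j];
      st.tips[v][j] = st.tips[v][2]; // keep remaining two in slots 0,1
      int id = st.free_ids.back(); st.free_ids.pop_back();
      st.tips[id][0] = t_out;
      st.node_of_tip[t_out] = id;
      st.list_add(id, 1);
      st.list_add(v, 2);
    }
    ++events_done;
    if (record_trace) {
      trace(e, 0) = (int)st.lst[1].size();
      trace(e, 1) = (int)st.lst[2].size();
      trace(e, 2) = (int)st.lst[3].size();
    }
  }

  int n1 = (int)st.lst[1].size();
  int n2 = (int)st.lst[2].size();
  int n3 = (int)st.lst[3].size();
  int N = n1 + n2 + n3;
  if (n1 + 2 * n2 + 3 * n3 != 2 * L)
    stop("internal error: tip conservation violated"); // # nocov

  // connected components of the node graph (edges = dimers)
  std::vector<int> par;
  uf_init(par, 2 * L);
  for (int d = 0; d < L; ++d) {
    int ra = uf_find(par, st.node_of_tip[2 * d]);
    int rb = uf_find(par, st.node_of_tip[2 * d + 1]);
    if (ra != rb) par[ra] = rb;
  }
  std::vector<int> size_of(2 * L, 0);
  for (int id = 0; id < 2 * L; ++id)
    if (st.deg[id] > 0) ++size_of[uf_find(par, id)];
  std::vector<int> sizes;
  for (int id = 0; id < 2 * L; ++id)
    if (size_of[id] > 0) sizes.push_back(size_of[id]);

  int ng = 0;
  long stot = 0;
  for (size_t i = 0; i < sizes.size(); ++i) {
    stot += sizes[i];
    if (sizes[i] > ng) ng = sizes[i];
  }
  double mean_s_excl = (sizes.size() > 1)
      ? (double)(stot - ng) / (double)(sizes.size() - 1)
      : NA_REAL;

  List out = List::create(
    _["n1"] = n1, _["n2"] = n2, _["n3"] = n3, _["n_nodes"] = N,
    _["n_components"] = (int)sizes.size(),
    _["cluster_sizes"] = wrap(sizes),
    _["mean_k"] = (double)(2 * L) / (double)N,
    _["ng_over_n"] = (double)ng / (double)N,
    _["mean_s_excl_giant"] = mean_s_excl,
    _["absorbed"] = absorbed,
    _["events_done"] = events_done);
  if (record_trace) out["trace"] = trace;
  if (return_edges) {
    IntegerMatrix ed(L, 2);
    for (int d = 0; d < L; ++d) {
      ed(d, 0) = st.node_of_tip[2 * d] + 1;
      ed(d, 1) = st.node_of_tip[2 * d + 1] + 1;
    }
    out["edges"] = ed;
  }
  return out;
}
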