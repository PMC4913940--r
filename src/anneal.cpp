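// Simulated-annealing maximisation of modularity.
//
// One routine serves both forms: for a bipartite incidence matrix W (nr x nc)
// the node set is rows followed by columns and Q is the Barber bipartite
// modularity; for a directed adjacency matrix the node set is the shared
// row/column index and Q is the Leicht-Newman directed modularity.  In both
// cases Q(g) = (1/m) * sum_ij (W_ij - a_i b_j / m) [g_row(i) == g_col(j)]
// with a = row sums, b = column sums, m = sum(W).

#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Rng {
  std::mt19937 eng;
  explicit Rng(uint32_t seed) : eng(seed) {}
  // uniform in (0, 1); explicit arithmetic keeps streams identical across
  // standard-library implementations
  double unif() { return (eng() + 0.5) * (1.0 / 4294967296.0); }
  int unif_int(int n) { return (int)(unif() * n); }
};

struct Problem {
  NumericMatrix W;
  bool directed;
  int nr, nc, nnode;
  std::vector<double> a, b;
  double m;

  Problem(NumericMatrix W_, bool directed_) : W(W_), directed(directed_) {
    nr = W.nrow();
    nc = W.ncol();
    nnode = directed ? nr : nr + nc;
    a.assign(nr, 0.0);
    b.assign(nc, 0.0);
    m = 0.0;
    for (int i = 0; i < nr; ++i)
      for (int j = 0; j < nc; ++j) {
        double w = W(i, j);
        a[i] += w;
        b[j] += w;
        m += w;
      }
  }

  inline int col_node(int j) const { return directed ? j : nr + j; }

  double fullQ(const std::vector<int>& g) const {
    double q = 0.0;
    for (int i = 0; i < nr; ++i) {
      int gi = g[i];
      for (int j = 0; j < nc; ++j)
        if (gi == g[col_node(j)]) q += W(i, j) - a[i] * b[j] / m;
    }
    return q / m;
  }

  // change in Q when node v moves from module x to module y
  double delta_single(const std::vector<int>& g, int v, int x, int y) const {
    double d = 0.0;
    if (!directed) {
      if (v < nr) {
        for (int j = 0; j < nc; ++j) {
          int gj = g[nr + j];
          if (gj == y) d += W(v, j) - a[v] * b[j] / m;
          else if (gj == x) d -= W(v, j) - a[v] * b[j] / m;
        }
      } else {
        int cj = v - nr;
        for (int i = 0; i < nr; ++i) {
          int gi = g[i];
          if (gi == y) d += W(i, cj) - a[i] * b[cj] / m;
          else if (gi == x) d -= W(i, cj) - a[i] * b[cj] / m;
        }
      }
    } else {
      for (int j = 0; j < nc; ++j) {
        if (j == v) continue;       // the (v, v) pair is unaffected
        int gj = g[j];
        if (gj == y) d += W(v, j) - a[v] * b[j] / m;
        else if (gj == x) d -= W(v, j) - a[v] * b[j] / m;
      }
      for (int i = 0; i < nr; ++i) {
        if (i == v) continue;
        int gi = g[i];
        if (gi == y) d += W(i, v) - a[i] * b[v] / m;
        else if (gi == x) d -= W(i, v) - a[i] * b[v] / m;
      }
    }
    return d / m;
  }

  // sum of modularity terms across module pair (x, y); merging x and y
  // raises Q by exactly this amount
  double crossQ(const std::vector<int>& g, int x, int y) const {
    double d = 0.0;
    for (int i = 0; i < nr; ++i) {
      int gi = g[i];
      if (gi != x && gi != y) continue;
      for (int j = 0; j < nc; ++j) {
        int gj = g[col_node(j)];
        if ((gi == x && gj == y) || (gi == y && gj == x))
          d += W(i, j) - a[i] * b[j] / m;
      }
    }
    return d / m;
  }
};

struct State {
  std::vector<int> g;
  std::vector<int> size;
  int nm;

  void init_singletons(int nnode) {
    g.resize(nnode);
    size.assign(nnode, 1);
    nm = nnode;
    for (int v = 0; v < nnode; ++v) g[v] = v;
  }

  // module x just lost its last member: keep labels contiguous
  void compact(int x) {
    if (size[x] != 0) return;
    int last = nm - 1;
    if (x != last) {
      for (size_t v = 0; v < g.size(); ++v)
        if (g[v] == last) g[v] = x;
      size[x] = size[last];
    }
    size.pop_back();
    --nm;
  }
};

bool accept(double d, double T, Rng& rng) {
  if (d > 0) return true;
  if (T <= 0) return false;
  return rng.unif() < std::exp(d / T);
}

} // namespace

// [[Rcpp::export]]
List anneal_modularity_cpp(NumericMatrix W, bool directed, int seed,
                           double t0, double cooling, double tmin_ratio,
                           double moves_factor, int restarts) {
  Problem P(W, directed);
  if (P.m <= 0) stop("network has no links");
  const int n = P.nnode;

  // the single-module partition (Q = 0 exactly) is always a candidate
  double bestQ = 0.0;
  std::vector<int> bestG(n, 0);

  for (int r = 0; r < restarts; ++r) {
    Rng rng((uint32_t)seed + 2654435761u * (uint32_t)r);
    State st;
    st.init_singletons(n);
    double Q = P.fullQ(st.g);
    if (Q > bestQ) { bestQ = Q; bestG = st.g; }

    // auto temperature: most sampled single-node moves accepted at start
    double T0 = t0;
    if (T0 <= 0) {
      std::vector<double> mags;
      for (int s = 0; s < 200; ++s) {
        int v = rng.unif_int(n);
        int y = rng.unif_int(st.nm);
        if (y == st.g[v]) continue;
        double d = std::fabs(P.delta_single(st.g, v, st.g[v], y));
        if (d > 0) mags.push_back(d);
      }
      if (mags.empty()) T0 = 0.1;
      else {
        std::sort(mags.begin(), mags.end());
        double q90 = mags[(size_t)(0.9 * (mags.size() - 1))];
        T0 = q90 / 0.2231435513;   // exp(-q90 / T0) = 0.8
      }
      if (T0 <= 0) T0 = 0.1;
    }

    const int nsingle = std::max(1, (int)(moves_factor * n * n));
    const int ncoll = std::max(1, (int)(moves_factor * n));
    double T = T0;
    const double Tmin = T0 * tmin_ratio;

    while (T > Tmin) {
      for (int s = 0; s < nsingle; ++s) {
        int v = rng.unif_int(n);
        int x = st.g[v];
        int y = rng.unif_int(st.nm + 1);   // st.nm proposes a new module
        if (y == x) continue;
        if (y == st.nm && st.size[x] == 1) continue;  // label-only no-op
        double d = P.delta_single(st.g, v, x, y);
        if (!accept(d, T, rng)) continue;
        if (y == st.nm) { st.size.push_back(0); ++st.nm; }
        st.g[v] = y;
        ++st.size[y];
        --st.size[x];
        st.compact(x);
        Q += d;
        if (Q > bestQ) { bestQ = Q; bestG = st.g; }
      }
      for (int s = 0; s < ncoll; ++s) {
        bool do_merge = (st.nm >= 2) && (rng.unif() < 0.5);
        if (do_merge) {
          int x = rng.unif_int(st.nm);
          int y = rng.unif_int(st.nm - 1);
          if (y >= x) ++y;
          double d = P.crossQ(st.g, x, y);
          if (!accept(d, T, rng)) continue;
          for (int v = 0; v < n; ++v)
            if (st.g[v] == y) st.g[v] = x;
          st.size[x] += st.size[y];
          st.size[y] = 0;
          st.compact(y);
          Q += d;
          if (Q > bestQ) { bestQ = Q; bestG = st.g; }
        } else {
          int x = rng.unif_int(st.nm);
          if (st.size[x] < 2) continue;
          int z = st.nm;
          std::vector<int> moved;
          for (int v = 0; v < n; ++v)
            if (st.g[v] == x && rng.unif() < 0.5) moved.push_back(v);
          if (moved.empty() || (int)moved.size() == st.size[x]) continue;
          for (int v : moved) st.g[v] = z;
          double d = -P.crossQ(st.g, x, z);
          if (accept(d, T, rng)) {
            st.size.push_back((int)moved.size());
            st.size[x] -= (int)moved.size();
            ++st.nm;
            Q += d;
            if (Q > bestQ) { bestQ = Q; bestG = st.g; }
          } else {
            for (int v : moved) st.g[v] = x;   // revert
          }
        }
      }
      Q = P.fullQ(st.g);   // resynchronise against drift
      T *= cooling;
    }
  }

  // relabel best partition contiguously in order of first appearance
  std::vector<int> relab(n, -1);
  IntegerVector membership(n);
  int next = 0;
  for (int v = 0; v < n; ++v) {
    if (relab[bestG[v]] < 0) relab[bestG[v]] = next++;
    membership[v] = relab[bestG[v]];
  }
  return List::create(_["Q"] = bestQ, _["membership"] = membership,
                      _["n_modules"] = next);
}
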