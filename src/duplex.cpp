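#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Intermolecular duplex folding: miRNA (5'->3') against a target (5'->3'),
// antiparallel, no intramolecular structure. A duplex is a chain of base
// pairs (i1,j1)..(ik,jk) with i strictly increasing and j strictly
// decreasing; consecutive pairs contribute a nearest-neighbour stack when
// adjacent, a bulge penalty when one strand loops out, and an interior-loop
// penalty otherwise. Dangling ends are free.

static const double INF = std::numeric_limits<double>::infinity();

struct Model {
  NumericMatrix stack;       // 6 x 6, pair-type on pair-type
  NumericVector bulge;       // 1..max_bulge
  NumericVector interior;    // total size 2..length(interior)+1 (index size-1)
  double asym_coef, asym_max, init;
  int max_bulge, max_interior;
};

static Model unpack_model(List m) {
  Model md;
  md.stack = as<NumericMatrix>(m["stack"]);
  md.bulge = as<NumericVector>(m["bulge"]);
  md.interior = as<NumericVector>(m["interior"]);
  md.asym_coef = as<double>(m["interior_asym"]);
  md.asym_max = as<double>(m["interior_asym_max"]);
  md.init = as<double>(m["duplex_init"]);
  md.max_bulge = as<int>(m["max_bulge"]);
  md.max_interior = as<int>(m["max_interior"]);
  return md;
}

// pair types: AU=0, UA=1, CG=2, GC=3, GU=4, UG=5; -1 = not pairable
static inline int pair_type(int a, int b) {
  // bases: A=0, C=1, G=2, U=3
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 1 && b == 2) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

static inline double gap_cost(const Model& md, int g1, int g2,
                              int pt_prev, int pt_cur) {
  if (g1 == 0 && g2 == 0) return md.stack(pt_prev, pt_cur);
  if (g2 == 0) {
    if (g1 > md.max_bulge) return INF;
    return md.bulge[g1 - 1];
  }
  if (g1 == 0) {
    if (g2 > md.max_bulge) return INF;
    return md.bulge[g2 - 1];
  }
  if (g1 > md.max_interior || g2 > md.max_interior) return INF;
  int tot = g1 + g2;
  if (tot - 1 > md.interior.size()) return INF;
  double asym = md.asym_coef * std::abs(g1 - g2);
  if (asym > md.asym_max) asym = md.asym_max;
  return md.interior[tot - 2] + asym;
}

// [[Rcpp::export(name = ".duplex_dp")]]
List duplex_dp(IntegerVector mi, IntegerVector tg, List model) {
  Model md = unpack_model(model);
  int m = mi.size(), n = tg.size();
  std::vector<double> E((size_t)m * n, INF);
  std::vector<int> par((size_t)m * n, -1);
  std::vector<int> pt((size_t)m * n, -1);
  double best = INF;
  int best_cell = -1;
  for (int i = 0; i < m; ++i) {
    for (int j = n - 1; j >= 0; --j) {
      int t = pair_type(mi[i], tg[j]);
      if (t < 0) continue;
      size_t c = (size_t)i * n + j;
      pt[c] = t;
      double e = md.init;  // (i,j) opens the duplex
      int p = -1;
      int gmax1 = std::max(md.max_bulge, md.max_interior);
      for (int g1 = 0; g1 <= gmax1 && i - 1 - g1 >= 0; ++g1) {
        int i0 = i - 1 - g1;
        for (int g2 = 0; g2 <= gmax1 && j + 1 + g2 < n; ++g2) {
          int j0 = j + 1 + g2;
          size_t c0 = (size_t)i0 * n + j0;
          if (pt[c0] < 0 || E[c0] == INF) continue;
          double gc = gap_cost(md, g1, g2, pt[c0], t);
          if (gc == INF) continue;
          double cand = E[c0] + gc;
          if (cand < e) { e = cand; p = (int)c0; }
        }
      }
      E[c] = e;
      par[c] = p;
      if (e < best) { best = e; best_cell = (int)c; }
    }
  }
  if (best_cell < 0 || best >= 0) {
    return List::create(_["mfe"] = 0.0,
                        _["mi_pos"] = IntegerVector(0),
                        _["tg_pos"] = IntegerVector(0));
  }
  std::vector<int> mi_pos, tg_pos;
  for (int c = best_cell; c >= 0; c = par[c]) {
    mi_pos.push_back(c / n + 1);
    tg_pos.push_back(c % n + 1);
  }
  std::reverse(mi_pos.begin(), mi_pos.end());
  std::reverse(tg_pos.begin(), tg_pos.end());
  return List::create(_["mfe"] = best,
                      _["mi_pos"] = wrap(mi_pos),
                      _["tg_pos"] = wrap(tg_pos));
}

// Brute-force oracle: enumerate every loop-bounded chain of pairs
// explicitly (no memoisation, no shared recurrence with the DP above).
// Only intended for tiny instances in tests.
struct EnumState {
  const Model* md;
  const IntegerVector* mi;
  const IntegerVector* tg;
  double best;
};

static void enum_rec(EnumState& st, int i, int j, int t, double e) {
  if (e < st.best) st.best = e;
  int m = st.mi->size(), n = st.tg->size();
  for (int i2 = i + 1; i2 < m; ++i2) {
    for (int j2 = j - 1; j2 >= 0; --j2) {
      int t2 = pair_type((*st.mi)[i2], (*st.tg)[j2]);
      if (t2 < 0) continue;
      double gc = gap_cost(*st.md, i2 - i - 1, j - j2 - 1, t, t2);
      if (gc == INF) continue;
      enum_rec(st, i2, j2, t2, e + gc);
    }
  }
}

// [[Rcpp::export(name = ".duplex_enum")]]
double duplex_enum(IntegerVector mi, IntegerVector tg, List model) {
  Model md = unpack_model(model);
  EnumState st{&md, &mi, &tg, 0.0};
  int m = mi.size(), n = tg.size();
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) {
      int t = pair_type(mi[i], tg[j]);
      if (t < 0) continue;
      enum_rec(st, i, j, t, md.init);
    }
  }
  return st.best < 0 ? st.best : 0.0;
}
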