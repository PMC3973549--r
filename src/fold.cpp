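#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>
using namespace Rcpp;

// Minimum-energy nested secondary structure under a nearest-neighbour
// stacking model:
//   * allowed pairs: AU, UA, GC, CG, GU, UG; hairpin loops >= min_loop nt
//   * each stack of adjacent pairs scores stack_gc / stack_gc_au /
//     stack_au, or stack_gu if either pair involves G:U
//   * every unpaired base enclosed by at least one pair costs loop_penalty
//   * exterior (unenclosed) bases are free
// Ties are broken deterministically: exterior bases prefer unpaired, helix
// interiors prefer the stacked continuation, branch points take the
// leftmost minimal split.

static const double INF = std::numeric_limits<double>::infinity();
static const double EPS = 1e-9;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'U': return 3;
    default:  return -1; // N and anything else: never pairs
  }
}

static inline bool pairable(int a, int b) {
  if (a < 0 || b < 0) return false;
  int x = a + b;                 // AU/UA: 0+3; GC/CG: 2+1; GU/UG: 2+3
  return x == 3 || (x == 5 && a != b);
}

static inline bool is_gu(int a, int b) { return a + b == 5 && a != b; }
static inline bool is_gc(int a, int b) { return a + b == 3 && (a == 1 || a == 2); }

struct FoldCtx {
  int n, min_loop;
  double p_loop, s_gc, s_gc_au, s_au, s_gu;
  std::vector<int> code;
  std::vector<double> V, W;   // n*n, row-major [i*n + j]
  std::vector<double> E;      // exterior prefix, size n
  std::vector<int> pairv;     // partner index or -1

  double stack_score(int i, int j) const {
    // stack formed by pairs (i,j) and (i+1,j-1)
    int a1 = code[i], b1 = code[j], a2 = code[i + 1], b2 = code[j - 1];
    if (is_gu(a1, b1) || is_gu(a2, b2)) return s_gu;
    bool g1 = is_gc(a1, b1), g2 = is_gc(a2, b2);
    if (g1 && g2) return s_gc;
    if (g1 || g2) return s_gc_au;
    return s_au;
  }

  double getV(int i, int j) const { return V[(size_t)i * n + j]; }
  double getW(int i, int j) const { return (i > j) ? 0.0 : W[(size_t)i * n + j]; }

  bool can_pair(int i, int j) const {
    return j - i - 1 >= min_loop && pairable(code[i], code[j]);
  }

  void fill() {
    V.assign((size_t)n * n, INF);
    // enclosed segments too short to hold a pair are all-unpaired
    W.assign((size_t)n * n, 0.0);
    for (int i = 0; i < n; ++i)
      for (int j = i; j < n; ++j)
        W[(size_t)i * n + j] = p_loop * (j - i + 1);
    for (int span = min_loop + 1; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        // V(i,j)
        if (can_pair(i, j)) {
          double best = getW(i + 1, j - 1); // covers hairpin (all-unpaired) too
          if (can_pair(i + 1, j - 1)) {
            double st = stack_score(i, j) + getV(i + 1, j - 1);
            if (st < best) best = st;
          }
          V[(size_t)i * n + j] = best;
        }
        // W(i,j) enclosed
        double w = getW(i, j - 1) + p_loop;
        for (int k = i; k <= j - min_loop - 1; ++k) {
          if (!can_pair(k, j)) continue;
          double cand = getV(k, j) + getW(i, k - 1);
          if (cand < w - EPS) w = cand;
          else if (cand < w) w = cand;
        }
        W[(size_t)i * n + j] = w;
      }
    }
    // exterior
    E.assign(n, 0.0);
    for (int j = 0; j < n; ++j) {
      double e = (j > 0) ? E[j - 1] : 0.0;
      for (int k = 0; k <= j - min_loop - 1; ++k) {
        if (!can_pair(k, j)) continue;
        double cand = getV(k, j) + (k > 0 ? E[k - 1] : 0.0);
        if (cand < e) e = cand;
      }
      E[j] = e;
    }
  }

  void traceV(int i, int j);
  void traceW(int i, int j);
  void traceE(int j);
};

void FoldCtx::traceV(int i, int j) {
  pairv[i] = j; pairv[j] = i;
  double v = getV(i, j);
  if (can_pair(i + 1, j - 1)) {
    double st = stack_score(i, j) + getV(i + 1, j - 1);
    if (st <= v + EPS) { traceV(i + 1, j - 1); return; }
  }
  traceW(i + 1, j - 1);
}

void FoldCtx::traceW(int i, int j) {
  while (i <= j) {
    double w = getW(i, j);
    bool done = false;
    for (int k = i; k <= j - min_loop - 1; ++k) {
      if (!can_pair(k, j)) continue;
      double cand = getV(k, j) + getW(i, k - 1);
      if (cand <= w + EPS) {
        traceV(k, j);
        j = k - 1;            // continue on the left remainder
        done = true;
        break;
      }
    }
    if (!done) --j;           // j unpaired
  }
}

void FoldCtx::traceE(int j) {
  while (j >= 0) {
    double e = E[j];
    double prev = (j > 0) ? E[j - 1] : 0.0;
    if (prev <= e + EPS) { --j; continue; }   // prefer unpaired exterior
    bool done = false;
    for (int k = 0; k <= j - min_loop - 1; ++k) {
      if (!can_pair(k, j)) continue;
      double cand = getV(k, j) + (k > 0 ? E[k - 1] : 0.0);
      if (cand <= e + EPS) {
        traceV(k, j);
        j = k - 1;
        done = true;
        break;
      }
    }
    if (!done) --j; // numerical safety; should not happen
  }
}

// [[Rcpp::export(name = ".fold_baseline_cpp")]]
List fold_baseline_cpp(std::string seq, double stack_gc, double stack_gc_au,
                       double stack_au, double stack_gu, double loop_penalty,
                       int min_loop) {
  int n = (int)seq.size();
  FoldCtx ctx;
  ctx.n = n; ctx.min_loop = min_loop; ctx.p_loop = loop_penalty;
  ctx.s_gc = stack_gc; ctx.s_gc_au = stack_gc_au;
  ctx.s_au = stack_au; ctx.s_gu = stack_gu;
  ctx.code.resize(n);
  for (int i = 0; i < n; ++i) ctx.code[i] = base_code(seq[i]);
  ctx.pairv.assign(n, -1);
  double energy = 0.0;
  if (n > ctx.min_loop + 1) {
    ctx.fill();
    energy = ctx.E[n - 1];
    ctx.traceE(n - 1);
  }
  std::string db(n, '.');
  for (int i = 0; i < n; ++i) {
    if (ctx.pairv[i] > i) { db[i] = '('; db[ctx.pairv[i]] = ')'; }
  }
  IntegerVector partner(n);
  for (int i = 0; i < n; ++i) partner[i] = ctx.pairv[i] + 1; // 1-based, 0 = unpaired
  return List::create(_["structure"] = db, _["energy"] = energy,
                      _["partner"] = partner);
}
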