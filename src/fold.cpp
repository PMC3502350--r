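#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Minimum-free-energy folding of a single RNA sequence under a reduced
// nearest-neighbor model: stacking energies for adjacent base pairs,
// tabulated hairpin/bulge/internal-loop initiation penalties with an
// asymmetry term, and an affine multiloop penalty.  Nested structures only
// (no pseudoknots), Watson-Crick and G:U pairs, minimum hairpin loop of 3,
// no dangles or coaxial stacking.  Zuker-style O(n^3) dynamic program with
// interior loops bounded at `max_interior` unpaired nucleotides.
//
// Tie-break among co-optimal structures is deterministic: the traceback
// prefers, in order, a paired base over an unpaired one at the leftmost
// undecided position, the smallest pairing partner, and stacked/interior
// extensions over multiloops over hairpin closure.

static const double INF = 1e9;
static const double EPS = 1e-7;

static inline int ptype(char a, char b) {
  if (a == 'c' && b == 'g') return 0;
  if (a == 'g' && b == 'c') return 1;
  if (a == 'g' && b == 'u') return 2;
  if (a == 'u' && b == 'g') return 3;
  if (a == 'a' && b == 'u') return 4;
  if (a == 'u' && b == 'a') return 5;
  return -1;
}

struct FoldCtx {
  int n;
  std::string s;
  const double *stack;          // 6x6, column-major from R
  const double *hpE, *bulgeE, *intE;  // indexed by loop size (1-based -> [size])
  int maxloop_tab;              // length of the penalty tables
  double asym_coef, asym_max;
  double ml_a, ml_b, ml_c;
  int max_interior, min_hairpin;
  std::vector<double> V, WM, WM2, WX;  // n*n, index i*n+j

  double st(int p1, int p2) const { return stack[p1 + 6 * p2]; }
  int pt(int i, int j) const { return ptype(s[i], s[j]); }
  bool canpair(int i, int j) const {
    return j - i - 1 >= min_hairpin && pt(i, j) >= 0;
  }
  double looptab(const double *tab, int size) const {
    if (size < 1) return INF;
    if (size <= maxloop_tab) return tab[size - 1];
    return tab[maxloop_tab - 1] +
           1.0785 * std::log((double) size / maxloop_tab);
  }
  double hairpin(int size) const {
    if (size < min_hairpin) return INF;
    return looptab(hpE, size);
  }
  double interior(int l1, int l2) const {
    if (l1 == 0 && l2 == 0) return INF;  // that is a stack
    if (l1 == 0 || l2 == 0) return looptab(bulgeE, l1 + l2);
    double asym = asym_coef * std::abs(l1 - l2);
    if (asym > asym_max) asym = asym_max;
    return looptab(intE, l1 + l2) + asym;
  }
};

static void fill(FoldCtx &c) {
  const int n = c.n;
  c.V.assign((size_t) n * n, INF);
  c.WM.assign((size_t) n * n, INF);
  c.WM2.assign((size_t) n * n, INF);
  c.WX.assign((size_t) n * n, 0.0);
  for (int span = 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      size_t ij = (size_t) i * n + j;
      // --- V: i pairs j
      if (c.canpair(i, j)) {
        double best = c.hairpin(j - i - 1);
        if (c.canpair(i + 1, j - 1)) {
          double e = c.st(c.pt(i, j), c.pt(i + 1, j - 1)) +
                     c.V[(size_t) (i + 1) * n + (j - 1)];
          if (e < best) best = e;
        }
        int maxl = c.max_interior;
        for (int l1 = 0; l1 <= maxl; ++l1) {
          int k = i + 1 + l1;
          if (k >= j) break;
          for (int l2 = (l1 == 0 ? 1 : 0); l1 + l2 <= maxl; ++l2) {
            int l = j - 1 - l2;
            if (l <= k) break;
            if (!c.canpair(k, l)) continue;
            double e = c.V[(size_t) k * n + l] + c.interior(l1, l2);
            if (e < best) best = e;
          }
        }
        if (j - i >= 4) {
          double e = c.WM2[(size_t) (i + 1) * n + (j - 1)] + c.ml_a + c.ml_b;
          if (e < best) best = e;
        }
        c.V[ij] = best;
      }
      // --- WM: >=1 multiloop branch on [i..j]
      {
        double best = INF;
        if (c.V[ij] < INF / 2) best = c.V[ij] + c.ml_b;
        double e = c.WM[(size_t) (i + 1) * n + j];
        if (e < INF / 2 && e + c.ml_c < best) best = e + c.ml_c;
        e = c.WM[(size_t) i * n + (j - 1)];
        if (e < INF / 2 && e + c.ml_c < best) best = e + c.ml_c;
        for (int k = i; k < j; ++k) {
          double a = c.WM[(size_t) i * n + k], b = c.WM[(size_t) (k + 1) * n + j];
          if (a < INF / 2 && b < INF / 2 && a + b < best) best = a + b;
        }
        c.WM[ij] = best;
      }
      // --- WM2: >=2 branches
      {
        double best = INF;
        for (int k = i; k < j; ++k) {
          double a = c.WM[(size_t) i * n + k], b = c.WM[(size_t) (k + 1) * n + j];
          if (a < INF / 2 && b < INF / 2 && a + b < best) best = a + b;
        }
        c.WM2[ij] = best;
      }
      // --- WX: external (no multiloop charge), empty allowed
      {
        double best = c.WX[(size_t) (i + 1) * n + j];  // i unpaired
        for (int l = i + 1; l <= j; ++l) {
          if (c.V[(size_t) i * n + l] >= INF / 2) continue;
          double rest = (l + 1 <= j) ? c.WX[(size_t) (l + 1) * n + j] : 0.0;
          double e = c.V[(size_t) i * n + l] + rest;
          if (e < best) best = e;
        }
        c.WX[ij] = best;
      }
    }
  }
}

struct TbItem { int i, j, what; };  // what: 0 ext, 1 pair, 2 WM, 3 WM2

static void traceback(FoldCtx &c, std::vector<int> &pair_of) {
  const int n = c.n;
  pair_of.assign(n, -1);
  std::vector<TbItem> stk;
  stk.push_back({0, n - 1, 0});
  while (!stk.empty()) {
    TbItem t = stk.back(); stk.pop_back();
    int i = t.i, j = t.j;
    if (i > j) continue;
    size_t ij = (size_t) i * n + j;
    if (t.what == 0) {
      if (i == j) continue;
      double w = c.WX[ij];
      bool done = false;
      for (int l = i + 1; l <= j && !done; ++l) {   // prefer i paired, smallest l
        if (c.V[(size_t) i * n + l] >= INF / 2) continue;
        double rest = (l + 1 <= j) ? c.WX[(size_t) (l + 1) * n + j] : 0.0;
        if (std::abs(c.V[(size_t) i * n + l] + rest - w) < EPS) {
          stk.push_back({i, l, 1});
          if (l + 1 <= j) stk.push_back({l + 1, j, 0});
          done = true;
        }
      }
      if (!done) stk.push_back({i + 1, j, 0});
    } else if (t.what == 1) {
      pair_of[i] = j; pair_of[j] = i;
      double v = c.V[ij];
      // stack
      if (c.canpair(i + 1, j - 1) &&
          std::abs(c.st(c.pt(i, j), c.pt(i + 1, j - 1)) +
                   c.V[(size_t) (i + 1) * n + (j - 1)] - v) < EPS) {
        stk.push_back({i + 1, j - 1, 1});
        continue;
      }
      // interior / bulge
      bool done = false;
      for (int l1 = 0; l1 <= c.max_interior && !done; ++l1) {
        int k = i + 1 + l1;
        if (k >= j) break;
        for (int l2 = (l1 == 0 ? 1 : 0); l1 + l2 <= c.max_interior; ++l2) {
          int l = j - 1 - l2;
          if (l <= k) break;
          if (!c.canpair(k, l)) continue;
          if (std::abs(c.V[(size_t) k * n + l] + c.interior(l1, l2) - v) < EPS) {
            stk.push_back({k, l, 1});
            done = true; break;
          }
        }
      }
      if (done) continue;
      // multiloop
      if (j - i >= 4 &&
          std::abs(c.WM2[(size_t) (i + 1) * n + (j - 1)] + c.ml_a + c.ml_b - v) < EPS) {
        stk.push_back({i + 1, j - 1, 3});
        continue;
      }
      // hairpin: nothing to do
    } else if (t.what == 2) {
      double w = c.WM[ij];
      if (c.V[ij] < INF / 2 && std::abs(c.V[ij] + c.ml_b - w) < EPS) {
        stk.push_back({i, j, 1});
        continue;
      }
      bool done = false;
      for (int k = i; k < j && !done; ++k) {
        double a = c.WM[(size_t) i * n + k], b = c.WM[(size_t) (k + 1) * n + j];
        if (a < INF / 2 && b < INF / 2 && std::abs(a + b - w) < EPS) {
          stk.push_back({i, k, 2});
          stk.push_back({k + 1, j, 2});
          done = true;
        }
      }
      if (done) continue;
      if (c.WM[(size_t) (i + 1) * n + j] < INF / 2 &&
          std::abs(c.WM[(size_t) (i + 1) * n + j] + c.ml_c - w) < EPS) {
        stk.push_back({i + 1, j, 2});
        continue;
      }
      if (c.WM[(size_t) i * n + (j - 1)] < INF / 2 &&
          std::abs(c.WM[(size_t) i * n + (j - 1)] + c.ml_c - w) < EPS) {
        stk.push_back({i, j - 1, 2});
        continue;
      }
    } else {  // WM2
      double w = c.WM2[ij];
      for (int k = i; k < j; ++k) {
        double a = c.WM[(size_t) i * n + k], b = c.WM[(size_t) (k + 1) * n + j];
        if (a < INF / 2 && b < INF / 2 && std::abs(a + b - w) < EPS) {
          stk.push_back({i, k, 2});
          stk.push_back({k + 1, j, 2});
          break;
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_fold_mfe")]]
List cpp_fold_mfe(std::string seq, NumericMatrix stack,
                  NumericVector hairpinE, NumericVector bulgeE,
                  NumericVector internalE, double asym_coef, double asym_max,
                  double ml_a, double ml_b, double ml_c,
                  int max_interior, int min_hairpin) {
  FoldCtx c;
  c.n = (int) seq.size();
  c.s = seq;
  c.stack = stack.begin();
  c.hpE = hairpinE.begin();
  c.bulgeE = bulgeE.begin();
  c.intE = internalE.begin();
  c.maxloop_tab = (int) hairpinE.size();
  c.asym_coef = asym_coef; c.asym_max = asym_max;
  c.ml_a = ml_a; c.ml_b = ml_b; c.ml_c = ml_c;
  c.max_interior = max_interior; c.min_hairpin = min_hairpin;

  fill(c);
  double mfe = c.n > 1 ? c.WX[(size_t) 0 * c.n + (c.n - 1)] : 0.0;
  std::vector<int> pair_of(c.n, -1);
  if (mfe < -EPS) {
    traceback(c, pair_of);
  } else {
    mfe = 0.0;  // empty structure is optimal (or tied): report no pairs
  }
  std::string db(c.n, '.');
  std::vector<int> pi, pj;
  for (int i = 0; i < c.n; ++i) {
    if (pair_of[i] > i) {
      db[i] = '(';
      db[pair_of[i]] = ')';
      pi.push_back(i);
      pj.push_back(pair_of[i]);
    }
  }
  IntegerMatrix pairs((int) pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) {
    pairs(k, 0) = pi[k];
    pairs(k, 1) = pj[k];
  }
  return List::create(_["mfe"] = mfe, _["structure"] = db,
                      _["pairs"] = pairs);
}
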