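#include <Rcpp.h>
using namespace Rcpp;

// Intermolecular duplex minimum-free-energy dynamic program.
//
// Bases are encoded A=0, C=1, G=2, U=3. A duplex is a set of base pairs
// (i, j) between the miRNA (5'->3', index i) and a target window (5'->3',
// index j) such that as i increases j strictly decreases (antiparallel,
// non-crossing, intermolecular only). Consecutive pairs contribute a
// nearest-neighbor stacking term; pairs separated by unpaired bases (at
// most max_loop per side) contribute a bulge/interior loop penalty.
// Terminal AU/GU pairs carry an end penalty; a constant initiation term is
// added once.

static inline int pair_index(int a, int b) {
  // AU=0, UA=1, CG=2, GC=3, GU=4, UG=5, else -1
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 1 && b == 2) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

static inline bool au_gu_end(int p) { return p == 0 || p == 1 || p == 4 || p == 5; }

// core DP on one window; fills best energy and pair list (1-based, window coords)
static double duplex_core(const IntegerVector& mi, const IntegerVector& tg,
                          int toff, int tlen,
                          const NumericMatrix& stack, const NumericMatrix& loop,
                          double init, double au_end, int max_loop,
                          std::vector<int>& best_mi, std::vector<int>& best_tj) {
  const int m = mi.size();
  const int n = tlen;
  const double INF = R_PosInf;
  std::vector<double> E((size_t)m * n, INF);
  std::vector<int> from((size_t)m * n, -1);
  std::vector<int> pidx((size_t)m * n, -1);

  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j)
      pidx[(size_t)i * n + j] = pair_index(mi[i], tg[toff + j]);

  double best = INF;
  int best_cell = -1;

  // i ascending, j descending: predecessors (i2 < i, j2 > j) already done
  for (int i = 0; i < m; ++i) {
    for (int j = n - 1; j >= 0; --j) {
      const size_t c = (size_t)i * n + j;
      const int p = pidx[c];
      if (p < 0) continue;
      double e = au_gu_end(p) ? au_end : 0.0; // opening terminal penalty
      int fr = -1;
      for (int i2 = std::max(0, i - 1 - max_loop); i2 < i; ++i2) {
        const int li = i - i2 - 1;
        for (int j2 = j + 1; j2 <= std::min(n - 1, j + 1 + max_loop); ++j2) {
          const size_t c2 = (size_t)i2 * n + j2;
          const int p2 = pidx[c2];
          if (p2 < 0 || E[c2] == INF) continue;
          const int lj = j2 - j - 1;
          const double cost = (li == 0 && lj == 0) ? stack(p2, p) : loop(li, lj);
          const double cand = E[c2] + cost;
          if (cand < e) { e = cand; fr = (int)c2; }
        }
      }
      E[c] = e;
      from[c] = fr;
      const double closed = e + (au_gu_end(p) ? au_end : 0.0) + init;
      if (closed < best) { best = closed; best_cell = (int)c; }
    }
  }

  best_mi.clear(); best_tj.clear();
  if (best_cell >= 0) {
    int c = best_cell;
    while (c >= 0) {
      best_mi.push_back(c / n + 1);
      best_tj.push_back(toff + c % n + 1);
      c = from[c];
    }
    std::reverse(best_mi.begin(), best_mi.end());
    std::reverse(best_tj.begin(), best_tj.end());
  }
  return best;
}

// [[Rcpp::export(name = ".duplex_mfe_cpp")]]
List duplex_mfe_cpp(IntegerVector mirna, IntegerVector target,
                    NumericMatrix stack, NumericMatrix loop,
                    double init, double au_end, int max_loop) {
  std::vector<int> bmi, btj;
  double e = duplex_core(mirna, target, 0, target.size(), stack, loop,
                         init, au_end, max_loop, bmi, btj);
  return List::create(_["mfe"] = e,
                      _["mirna_pos"] = wrap(bmi),
                      _["target_pos"] = wrap(btj));
}

// [[Rcpp::export(name = ".duplex_scan_cpp")]]
List duplex_scan_cpp(IntegerVector mirna, IntegerVector target,
                     NumericMatrix stack, NumericMatrix loop,
                     double init, double au_end, int max_loop,
                     int window, int step) {
  const int n = target.size();
  double best = R_PosInf;
  std::vector<int> bmi, btj;
  int best_start = -1, best_np = 0;
  for (int s = 0; s == 0 || s + window - step < n; s += step) {
    const int len = std::min(window, n - s);
    if (len < 2) break;
    std::vector<int> cmi, ctj;
    double e = duplex_core(mirna, target, s, len, stack, loop,
                           init, au_end, max_loop, cmi, ctj);
    if (e == R_PosInf) continue;
    const int ts = cmi.empty() ? -1 : *std::min_element(ctj.begin(), ctj.end());
    const int np = (int)cmi.size();
    // prefer lower energy; ties: smaller target start, then longer helix
    const bool better = (e < best - 1e-9) ||
      (std::abs(e - best) <= 1e-9 &&
       (ts < best_start || (ts == best_start && np > best_np)));
    if (better) {
      best = e; bmi = cmi; btj = ctj; best_start = ts; best_np = np;
    }
  }
  return List::create(_["mfe"] = best,
                      _["mirna_pos"] = wrap(bmi),
                      _["target_pos"] = wrap(btj));
}
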