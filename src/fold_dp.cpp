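#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Pair-type codes used throughout: AU=0, UA=1, CG=2, GC=3, GU=4, UG=5, none=-1.
// Bases are encoded A=0, C=1, G=2, U=3 on the R side.
static inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 1 && b == 2) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

// Minimum-free-energy folding restricted to a single hairpin: the pair set is
// a chain of nested pairs (helices interrupted by bulges and internal loops,
// one terminal loop, no multibranch loops).  E[i][j] is the energy of the
// substructure closed by pair (i,j), excluding the junction to its parent.
// Ties are broken toward more pairs, then the outermost pair with the smaller
// opening index, then the deterministic scan order of inner pairs
// (p ascending, q descending), so the stacked continuation is preferred.
// [[Rcpp::export]]
List fold_hairpin_cpp(IntegerVector seq,
                      NumericMatrix stack,      // 6 x 6, [outer, inner]
                      NumericVector hairpin_pen, // index l (0-based) = loop of l nt
                      NumericVector bulge_pen,   // index l = bulge of l nt
                      NumericMatrix internal_pen,// [l1, l2], each 0..K
                      int min_loop,
                      int max_interior,
                      NumericVector end_pen) {   // length 6, by pair type
  const int n = seq.size();
  const double INF = std::numeric_limits<double>::infinity();
  const double eps = 1e-9;
  const int K = max_interior;

  std::vector<std::vector<double> > E(n, std::vector<double>(n, INF));
  std::vector<std::vector<int> > NP(n, std::vector<int>(n, 0));
  std::vector<std::vector<int> > CP(n, std::vector<int>(n, -2)); // -1 = hairpin close
  std::vector<std::vector<int> > CQ(n, std::vector<int>(n, -2));

  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      const int j = i + span;
      const int pt = pair_type(seq[i], seq[j]);
      if (pt < 0) continue;
      const int loop_len = j - i - 1;
      double best = (loop_len >= min_loop && loop_len < hairpin_pen.size())
                      ? hairpin_pen[loop_len] : INF;
      int best_np = 0, bp = -1, bq = -1;
      const int pmax = std::min(i + 1 + K, j - min_loop - 2);
      for (int p = i + 1; p <= pmax; ++p) {
        const int qmin = std::max(p + min_loop + 1, j - 1 - K);
        for (int q = j - 1; q >= qmin; --q) {
          if (E[p][q] == INF) continue;
          const int l1 = p - i - 1, l2 = j - q - 1;
          double jn;
          if (l1 == 0 && l2 == 0) {
            const int ipt = pair_type(seq[p], seq[q]);
            jn = stack(pt, ipt);
          } else if (l1 == 0 || l2 == 0) {
            jn = bulge_pen[l1 + l2];
          } else {
            jn = internal_pen(l1, l2);
          }
          const double cand = E[p][q] + jn;
          const int cnp = NP[p][q];
          if (cand < best - eps || (cand < best + eps && cnp > best_np)) {
            best = cand; best_np = cnp; bp = p; bq = q;
          }
        }
      }
      if (best < INF) {
        E[i][j] = best;
        NP[i][j] = 1 + best_np;
        CP[i][j] = bp; CQ[i][j] = bq;
      }
    }
  }

  // Global minimum over all possible outermost pairs; empty structure scores 0.
  double mfe = 0.0;
  int gi = -1, gj = -1, gnp = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + min_loop + 1; j < n; ++j) {
      if (E[i][j] == INF) continue;
      const int pt = pair_type(seq[i], seq[j]);
      const double tot = E[i][j] + end_pen[pt];
      if (tot >= -eps) continue; // never prefer a paired structure over the empty one at >= 0
      const int np = NP[i][j];
      bool take = false;
      if (tot < mfe - eps) take = true;
      else if (tot < mfe + eps && gi >= 0) {
        if (np > gnp) take = true;
        else if (np == gnp && (i < gi || (i == gi && j < gj))) take = true;
      }
      if (take) { mfe = tot; gi = i; gj = j; gnp = np; }
    }
  }

  IntegerMatrix pairs(gnp, 2);
  if (gi >= 0) {
    int i = gi, j = gj, k = 0;
    while (i >= 0) {
      pairs(k, 0) = i + 1; pairs(k, 1) = j + 1; ++k;
      int p = CP[i][j], q = CQ[i][j];
      i = p; j = q;
      if (p == -1) break;
    }
  }
  return List::create(_["mfe"] = mfe, _["pairs"] = pairs);
}
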