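#include <Rcpp.h>
using namespace Rcpp;

// Best ungapped placement of a position-specific scoring matrix on a query.
//
// query: 1-based residue indices into the 20-letter alphabet.
// pssm:  L x 20 matrix of per-column log-odds scores (bits).
// min_overlap: minimum number of profile columns that must lie on the query.
//
// Returns c(score, qstart, qend, pstart, pend) for the best-scoring shift
// (1-based, inclusive). Ties resolve to the smallest shift.
// [[Rcpp::export]]
NumericVector pssm_best_placement(IntegerVector query, NumericMatrix pssm,
                                  int min_overlap) {
  const int n = query.size();
  const int L = pssm.nrow();
  if (min_overlap < 1) min_overlap = 1;
  if (min_overlap > L) min_overlap = L;
  double best = R_NegInf;
  int best_s = NA_INTEGER, best_j0 = 0, best_j1 = 0;
  // s: query position (1-based) aligned with profile column 1 (may be <= 0)
  for (int s = min_overlap - L + 1; s <= n - min_overlap + 1; ++s) {
    int j0 = std::max(1, 2 - s);        // first profile column on the query
    int j1 = std::min(L, n - s + 1);    // last profile column on the query
    if (j1 - j0 + 1 < min_overlap) continue;
    double sc = 0.0;
    for (int j = j0; j <= j1; ++j) {
      int q = query[s + j - 2];         // residue index at query pos s+j-1
      sc += pssm(j - 1, q - 1);
    }
    if (sc > best) {
      best = sc;
      best_s = s;
      best_j0 = j0;
      best_j1 = j1;
    }
  }
  NumericVector out(5);
  if (best_s == NA_INTEGER) {
    out[0] = R_NegInf;
    out[1] = out[2] = out[3] = out[4] = NA_REAL;
  } else {
    out[0] = best;
    out[1] = best_s + best_j0 - 1;  // qstart
    out[2] = best_s + best_j1 - 1;  // qend
    out[3] = best_j0;               // profile start
    out[4] = best_j1;               // profile end
  }
  return out;
}
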