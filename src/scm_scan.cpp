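#include <Rcpp.h>
using namespace Rcpp;

// Greedy step of the Set Covering Machine: scan every candidate threshold
// rule ("ray") and return the one maximising U = |N_h| - p * |Pbar_h|, where
// N_h are the still-uncovered negatives on which the rule is FALSE (a
// conjunction classifies a sample negative as soon as one rule is false) and
// Pbar_h are the still-active positives on which the rule is false.
//
// Candidate thresholds are midpoints between consecutive distinct sorted
// training values of each attribute, in both directions (x <= t, x > t).
// Constant attributes contribute no candidates.
//
// Tie-break for equal U: larger |N_h|, then smaller attribute index, then
// smaller threshold, then direction "leq" before "gt". The scan visits
// candidates in exactly that order and replaces the incumbent only on a
// strict improvement, which realises the tie-break.
//
// X:   training matrix (n x p), column-major.
// ord: per-column sort permutation of X (1-based row indices), n x p.
// neg_state / pos_state: length-n logical; membership in the current
//   remaining-negative / active-positive sets.
// penalty: p >= 0.
//
// Returns a list; attr == 0 signals that no candidate rule exists.
// [[Rcpp::export]]
List scm_best_rule_cpp(NumericMatrix X, IntegerMatrix ord,
                       LogicalVector neg_state, LogicalVector pos_state,
                       double penalty) {
  const int n = X.nrow(), p = X.ncol();
  int best_attr = 0;            // 1-based; 0 = none found
  int best_dir = 0;             // 0 = leq, 1 = gt
  double best_thr = NA_REAL, best_U = R_NegInf;
  int best_Nh = -1, best_Pbar = -1;

  int total_neg = 0, total_pos = 0;
  for (int i = 0; i < n; ++i) {
    if (neg_state[i]) ++total_neg;
    if (pos_state[i]) ++total_pos;
  }

  const double *xp = REAL(X);
  const int *op = INTEGER(ord);
  const int *negp = LOGICAL(neg_state);
  const int *posp = LOGICAL(pos_state);

  for (int j = 0; j < p; ++j) {
    const double *xc = xp + (R_xlen_t)j * n;
    const int *oc = op + (R_xlen_t)j * n;
    int cum_neg = 0, cum_pos = 0;  // counts among the first i sorted rows
    for (int i = 0; i < n - 1; ++i) {
      const int row = oc[i] - 1;
      cum_neg += negp[row];
      cum_pos += posp[row];
      const double lo = xc[row];
      const double hi = xc[oc[i + 1] - 1];
      if (!(hi > lo)) continue;  // no cut between tied values
      const double thr = lo + (hi - lo) / 2.0;

      // direction leq: rule true iff x <= thr, false on the upper block
      {
        const int Nh = total_neg - cum_neg;
        const int Pbar = total_pos - cum_pos;
        const double U = Nh - penalty * Pbar;
        if (U > best_U || (U == best_U && Nh > best_Nh)) {
          best_U = U; best_Nh = Nh; best_Pbar = Pbar;
          best_attr = j + 1; best_dir = 0; best_thr = thr;
        }
      }
      // direction gt: rule true iff x > thr, false on the lower block
      {
        const int Nh = cum_neg;
        const int Pbar = cum_pos;
        const double U = Nh - penalty * Pbar;
        if (U > best_U || (U == best_U && Nh > best_Nh)) {
          best_U = U; best_Nh = Nh; best_Pbar = Pbar;
          best_attr = j + 1; best_dir = 1; best_thr = thr;
        }
      }
    }
  }

  return List::create(_["attr"] = best_attr,
                      _["direction"] = best_dir,
                      _["threshold"] = best_thr,
                      _["U"] = best_U,
                      _["Nh"] = best_Nh,
                      _["Pbar"] = best_Pbar);
}
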