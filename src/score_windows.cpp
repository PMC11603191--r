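#include <Rcpp.h>
using namespace Rcpp;

// Slide a position-specific log-odds matrix along an integer-encoded amino
// acid sequence and return the score of every window.
//
// Encoding contract (see aa_encode() on the R side):
//   1..20  -> row index into M (standard residues)
//   21     -> 'X' (unknown), contributes 0 bits
//   22     -> '*' (stop), poisons the window: score is -Inf
//
// M is 20 x L (residues x profile columns), in bits.
// [[Rcpp::export]]
NumericVector score_windows_cpp(IntegerVector idx, NumericMatrix M) {
  const int n = idx.size();
  const int L = M.ncol();
  const int nw = n - L + 1;
  if (nw < 1) return NumericVector(0);
  NumericVector out(nw);
  for (int s = 0; s < nw; ++s) {
    double acc = 0.0;
    bool stopped = false;
    for (int j = 0; j < L; ++j) {
      const int code = idx[s + j];
      if (code == 22) { stopped = true; break; }
      if (code >= 1 && code <= 20) acc += M(code - 1, j);
      // code 21 ('X') and anything else contribute 0
    }
    out[s] = stopped ? R_NegInf : acc;
  }
  return out;
}

// Threshold-pruned variant: windows whose score provably cannot reach
// `cutoff` are reported as -Inf without full evaluation. The bound uses the
// per-column maximum attainable contribution (clamped at 0 because 'X'
// contributes 0), so no window at or above the cutoff is ever pruned.
// [[Rcpp::export]]
NumericVector score_windows_cutoff_cpp(IntegerVector idx, NumericMatrix M,
                                       double cutoff) {
  const int n = idx.size();
  const int L = M.ncol();
  const int nw = n - L + 1;
  if (nw < 1) return NumericVector(0);
  std::vector<double> suffix(L + 1, 0.0);
  for (int j = L - 1; j >= 0; --j) {
    double colmax = 0.0;  // 'X' floor
    for (int a = 0; a < 20; ++a) colmax = std::max(colmax, M(a, j));
    suffix[j] = suffix[j + 1] + colmax;
  }
  NumericVector out(nw);
  for (int s = 0; s < nw; ++s) {
    double acc = 0.0;
    bool alive = true;
    for (int j = 0; j < L; ++j) {
      const int code = idx[s + j];
      if (code == 22) { alive = false; break; }
      if (code >= 1 && code <= 20) acc += M(code - 1, j);
      if (acc + suffix[j + 1] < cutoff) { alive = false; break; }
    }
    out[s] = alive ? acc : R_NegInf;
  }
  return out;
}

// Score n independent windows given as an n x L matrix of residue codes
// (used for E-value calibration against a residue null model).
// [[Rcpp::export]]
NumericVector score_window_matrix_cpp(IntegerMatrix idx, NumericMatrix M) {
  const int n = idx.nrow();
  const int L = M.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    bool stopped = false;
    for (int j = 0; j < L; ++j) {
      const int code = idx(i, j);
      if (code == 22) { stopped = true; break; }
      if (code >= 1 && code <= 20) acc += M(code - 1, j);
    }
    out[i] = stopped ? R_NegInf : acc;
  }
  return out;
}
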