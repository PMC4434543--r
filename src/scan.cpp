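#include <Rcpp.h>
using namespace Rcpp;

// Sliding log-odds PWM scores over an integer-coded nucleotide sequence.
//
// code:  0..3 for A,C,G,T; any negative value marks an ambiguous base (N)
//        or padding between concatenated sequences.
// lodds: 4 x L log-odds matrix (rows A,C,G,T; columns motif positions).
//
// Returns one score per candidate start (length(code) - L + 1); windows
// containing an ambiguous base score NA and are skipped by callers.
// [[Rcpp::export]]
NumericVector scan_scores_cpp(IntegerVector code, NumericMatrix lodds) {
  const int n = code.size();
  const int L = lodds.ncol();
  const int W = n - L + 1;
  if (W < 1) return NumericVector(0);
  NumericVector out(W);
  for (int i = 0; i < W; ++i) {
    double s = 0.0;
    bool ok = true;
    for (int j = 0; j < L; ++j) {
      const int c = code[i + j];
      if (c < 0) { ok = false; break; }
      s += lodds(c, j);
    }
    out[i] = ok ? s : NA_REAL;
  }
  return out;
}
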