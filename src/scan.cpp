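// PSSM sliding-window scoring. Sequence encoding A=0, C=1, G=2, T=3;
// any other symbol makes the covering offsets unscorable (-Inf).

#include <Rcpp.h>
using namespace Rcpp;

// pssm: 4 x L log-odds matrix; returns raw score at every offset (1 score
// per start position on the given strand's sequence)
// [[Rcpp::export]]
NumericVector pssm_scores_cpp(IntegerVector seq, NumericMatrix pssm) {
  int n = seq.size(), L = pssm.ncol();
  if (n < L) return NumericVector(0);
  NumericVector out(n - L + 1);
  const int* sp = INTEGER(seq);
  const double* mp = REAL(pssm); // column-major, 4 rows
  for (int off = 0; off + L <= n; ++off) {
    double sc = 0.0;
    bool ok = true;
    for (int k = 0; k < L; ++k) {
      int b = sp[off + k];
      if (b < 0 || b > 3) { ok = false; break; }
      sc += mp[4 * k + b];
    }
    out[off] = ok ? sc : R_NegInf;
  }
  return out;
}
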