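// Smith-Waterman local alignment with affine gaps (gap of length k costs
// open + k * extend, BLASTn-style conventions). Returns the single best
// local alignment with a deterministic traceback (on ties: diagonal, then
// up, then left; best cell = smallest (i, j)).

#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector q, IntegerVector s, double match,
                  double mismatch, double gap_open, double gap_extend) {
  int n = q.size(), m = s.size();
  // H: best score ending at (i,j) with (i,j) aligned or gap-ended
  // E: gap in query (consuming subject), F: gap in subject (consuming query)
  std::vector<double> H((size_t)(n + 1) * (m + 1), 0.0),
      E((size_t)(n + 1) * (m + 1), -1e18), F((size_t)(n + 1) * (m + 1), -1e18);
  // traceback pointers: 0 stop, 1 diag, 2 up (gap in subject), 3 left (gap in query)
  std::vector<unsigned char> PH((size_t)(n + 1) * (m + 1), 0),
      PE((size_t)(n + 1) * (m + 1), 0), PF((size_t)(n + 1) * (m + 1), 0);
  auto idx = [m](int i, int j) { return (size_t)i * (m + 1) + j; };
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      size_t c = idx(i, j);
      double eo = H[idx(i, j - 1)] - gap_open - gap_extend;
      double ee = E[idx(i, j - 1)] - gap_extend;
      if (eo >= ee) { E[c] = eo; PE[c] = 0; } else { E[c] = ee; PE[c] = 1; }
      double fo = H[idx(i - 1, j)] - gap_open - gap_extend;
      double fe = F[idx(i - 1, j)] - gap_extend;
      if (fo >= fe) { F[c] = fo; PF[c] = 0; } else { F[c] = fe; PF[c] = 1; }
      double sub = (q[i - 1] == s[j - 1] && q[i - 1] >= 0) ? match : mismatch;
      double diag = H[idx(i - 1, j - 1)] + sub;
      double h = 0.0; unsigned char ph = 0;
      if (diag > h) { h = diag; ph = 1; }
      if (F[c] > h) { h = F[c]; ph = 2; }
      if (E[c] > h) { h = E[c]; ph = 3; }
      H[c] = h; PH[c] = ph;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  // traceback
  int i = bi, j = bj;
  int matches = 0, columns = 0;
  int qend = bi, send = bj, qstart = bi, sstart = bj;
  int state = 0; // 0 in H, 1 in E, 2 in F
  while (i > 0 && j > 0) {
    size_t c = idx(i, j);
    if (state == 0) {
      unsigned char p = PH[c];
      if (p == 0) break;
      if (p == 1) {
        ++columns;
        if (q[i - 1] == s[j - 1] && q[i - 1] >= 0) ++matches;
        qstart = i; sstart = j;
        --i; --j;
      } else if (p == 2) {
        state = 2;
      } else {
        state = 1;
      }
    } else if (state == 1) { // E: gap in query, consume subject
      ++columns;
      sstart = j;
      unsigned char p = PE[c];
      --j;
      state = (p == 1) ? 1 : 0;
    } else { // F: gap in subject, consume query
      ++columns;
      qstart = i;
      unsigned char p = PF[c];
      --i;
      state = (p == 1) ? 2 : 0;
    }
  }
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["qstart"] = NA_INTEGER,
                        _["qend"] = NA_INTEGER, _["sstart"] = NA_INTEGER,
                        _["send"] = NA_INTEGER, _["matches"] = 0,
                        _["columns"] = 0);
  }
  return List::create(_["score"] = best, _["qstart"] = qstart,
                      _["qend"] = qend, _["sstart"] = sstart,
                      _["send"] = send, _["matches"] = matches,
                      _["columns"] = columns);
}

// score-only variant (two rolling rows); used for bulk screening.
// Raw-pointer accesses keep the inner loop vectorizable.
// [[Rcpp::export]]
double sw_score_cpp(IntegerVector q, IntegerVector s, double match,
                    double mismatch, double gap_open, double gap_extend) {
  int n = q.size(), m = s.size();
  std::vector<double> H0v(m + 1, 0.0), H1v(m + 1, 0.0), Fvv(m + 1, -1e18);
  const int* qp = INTEGER(q);
  const int* sp = INTEGER(s);
  const double goe = gap_open + gap_extend, ge = gap_extend;
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double e = -1e18; // gap in query, within-row
    double* h0 = H0v.data();
    double* h1 = H1v.data();
    double* fv = Fvv.data();
    h1[0] = 0.0;
    const int qi = qp[i - 1];
    for (int j = 1; j <= m; ++j) {
      e = std::max(h1[j - 1] - goe, e - ge);
      fv[j] = std::max(h0[j] - goe, fv[j] - ge);
      double sub = (qi == sp[j - 1] && qi >= 0) ? match : mismatch;
      double h = h0[j - 1] + sub;
      if (h < 0) h = 0;
      if (fv[j] > h) h = fv[j];
      if (e > h) h = e;
      h1[j] = h;
      if (h > best) best = h;
    }
    std::swap(H0v, H1v);
  }
  return best;
}
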