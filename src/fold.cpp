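// RNA secondary-structure kernels: Zuker-style MFE fold and McCaskill
// partition function / base-pair probabilities over a simplified
// nearest-neighbour model (stacking for the 6 canonical pair types plus
// linear hairpin / internal / multiloop penalties, minimum hairpin size h).
//
// Sequence encoding: A=0, C=1, G=2, U=3 (anything else never pairs).
// All energies kcal/mol. Structure space: nested, h-respecting, internal
// loops capped at max_il unpaired bases (same cap in MFE and partition
// recursions, so both address the identical ensemble).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <stack>
#include <array>
#include <algorithm>
using namespace Rcpp;

static const double INF = 1e9;

struct FoldModel {
  double stack[6][6];
  bool wobble;
  double Ha, Hb;   // hairpin: Ha + Hb * size
  double Ia, Ib;   // internal/bulge: Ia + Ib * unpaired
  double Ma, Mb, Mc; // multiloop: Ma + Mb * (branches incl. closing) + Mc * unpaired
  int h;           // minimum hairpin size
  int max_il;      // max unpaired bases in an internal loop
  double RT;
};

static inline int pair_type_raw(int a, int b) {
  // AU UA GC CG GU UG -> 0..5, else -1
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 1 && b == 2) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

static inline int pair_type_m(const FoldModel& fm, int a, int b) {
  int t = pair_type_raw(a, b);
  if (t >= 4 && !fm.wobble) return -1;
  return t;
}

static FoldModel model_from_list(const List& m) {
  FoldModel fm;
  NumericMatrix st = m["stack"];
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 6; ++b) fm.stack[a][b] = st(a, b);
  fm.Ha = m["hairpin_a"]; fm.Hb = m["hairpin_b"];
  fm.Ia = m["internal_a"]; fm.Ib = m["internal_b"];
  fm.Ma = m["multi_a"]; fm.Mb = m["multi_b"]; fm.Mc = m["multi_c"];
  fm.h = as<int>(m["hmin"]);
  fm.wobble = as<bool>(m["wobble"]);
  fm.max_il = as<int>(m["max_internal"]);
  fm.RT = m["RT"];
  return fm;
}

// internal-loop / bulge / stack energy for outer pair (i,j), inner (k,l)
static inline double il_energy(const FoldModel& fm, const std::vector<int>& s,
                               int i, int j, int k, int l) {
  int n1 = k - i - 1, n2 = j - l - 1;
  if (n1 == 0 && n2 == 0)
    return fm.stack[pair_type_raw(s[i], s[j])][pair_type_raw(s[k], s[l])];
  return fm.Ia + fm.Ib * (n1 + n2);
}

struct DPState {
  int n;
  std::vector<int> s;
  std::vector<double> V, WM, WM1;
  std::vector<double> W;
  FoldModel fm;
  inline double& v(int i, int j)  { return V[i * n + j]; }
  inline double& wm(int i, int j) { return WM[i * n + j]; }
  inline double& wm1(int i, int j){ return WM1[i * n + j]; }
};

static void fill_mfe(DPState& st) {
  int n = st.n;
  const FoldModel& fm = st.fm;
  const std::vector<int>& s = st.s;
  st.V.assign((size_t)n * n, INF);
  st.WM.assign((size_t)n * n, INF);
  st.WM1.assign((size_t)n * n, INF);
  for (int d = 1; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      // V(i,j)
      if (pair_type_m(st.fm, s[i], s[j]) >= 0 && j - i - 1 >= fm.h) {
        double best = fm.Ha + fm.Hb * (j - i - 1); // hairpin
        for (int k = i + 1; k < j; ++k) {
          if (k - i - 1 > fm.max_il) break;
          for (int l = j - 1; l > k; --l) {
            int sz = (k - i - 1) + (j - l - 1);
            if (sz > fm.max_il) break;
            if (st.v(k, l) >= INF) continue;
            double e = il_energy(fm, s, i, j, k, l) + st.v(k, l);
            if (e < best) best = e;
          }
        }
        // multiloop: closing pair + last branch starting at u
        for (int u = i + 2; u < j - 1; ++u) {
          double a = st.wm(i + 1, u - 1), b = st.wm1(u, j - 1);
          if (a < INF && b < INF) {
            double e = fm.Ma + fm.Mb + a + b;
            if (e < best) best = e;
          }
        }
        st.v(i, j) = best;
      }
      // WM1(i,j): exactly one branch starting at i, right side unpaired
      {
        double best = INF;
        for (int l = i + fm.h + 1; l <= j; ++l) {
          if (st.v(i, l) >= INF) continue;
          double e = st.v(i, l) + fm.Mb + fm.Mc * (j - l);
          if (e < best) best = e;
        }
        st.wm1(i, j) = best;
      }
      // WM(i,j): >=1 branch; u = start of last branch
      {
        double best = INF;
        for (int u = i; u <= j; ++u) {
          double b = st.wm1(u, j);
          if (b >= INF) continue;
          double left = fm.Mc * (u - i);
          if (u > i) left = std::min(left, st.wm(i, u - 1));
          double e = left + b;
          if (e < best) best = e;
        }
        st.wm(i, j) = best;
      }
    }
  }
  // exterior
  st.W.assign(n + 1, 0.0);
  for (int j = 0; j < n; ++j) {
    double best = st.W[j]; // j+1-th prefix; W[j] is prefix [0..j-1]
    for (int k = 0; k <= j; ++k) {
      if (st.v(k, j) >= INF) continue;
      double e = st.W[k] + st.v(k, j);
      if (e < best) best = e;
    }
    st.W[j + 1] = best;
  }
}

// deterministic traceback; fixed scan order (hairpin, internal loops with
// ascending k / descending l, multiloop ascending u; exterior prefers the
// unpaired extension, then ascending k)
static void traceback(DPState& st, std::vector<int>& pt) {
  int n = st.n;
  const FoldModel& fm = st.fm;
  const std::vector<int>& s = st.s;
  pt.assign(n, -1);
  const double eps = 1e-9;
  std::stack<std::array<int, 3>> todo; // (i, j, kind) kind 0=W suffix? use kinds
  // kinds: 0 = exterior prefix [0..j-1] (i ignored), 1 = V(i,j), 2 = WM(i,j), 3 = WM1(i,j)
  todo.push({0, n, 0});
  while (!todo.empty()) {
    auto t = todo.top(); todo.pop();
    int i = t[0], j = t[1], kind = t[2];
    if (kind == 0) {
      int jj = j; // prefix length
      while (jj > 0) {
        if (std::fabs(st.W[jj] - st.W[jj - 1]) < eps) { --jj; continue; }
        // find k with W[k] + V(k, jj-1) == W[jj]
        bool found = false;
        for (int k = 0; k <= jj - 1; ++k) {
          if (st.v(k, jj - 1) >= INF) continue;
          if (std::fabs(st.W[k] + st.v(k, jj - 1) - st.W[jj]) < eps) {
            todo.push({k, jj - 1, 1});
            jj = k;
            found = true;
            break;
          }
        }
        if (!found) { --jj; } // unpaired
      }
    } else if (kind == 1) {
      pt[i] = j; pt[j] = i;
      double target = st.v(i, j);
      double hp = fm.Ha + fm.Hb * (j - i - 1);
      if (std::fabs(hp - target) < eps) continue;
      bool done = false;
      for (int k = i + 1; k < j && !done; ++k) {
        if (k - i - 1 > fm.max_il) break;
        for (int l = j - 1; l > k; --l) {
          int sz = (k - i - 1) + (j - l - 1);
          if (sz > fm.max_il) break;
          if (st.v(k, l) >= INF) continue;
          if (std::fabs(il_energy(fm, s, i, j, k, l) + st.v(k, l) - target) < eps) {
            todo.push({k, l, 1});
            done = true; break;
          }
        }
      }
      if (done) continue;
      for (int u = i + 2; u < j - 1; ++u) {
        double a = st.wm(i + 1, u - 1), b = st.wm1(u, j - 1);
        if (a >= INF || b >= INF) continue;
        if (std::fabs(fm.Ma + fm.Mb + a + b - target) < eps) {
          todo.push({i + 1, u - 1, 2});
          todo.push({u, j - 1, 3});
          break;
        }
      }
    } else if (kind == 2) {
      double target = st.wm(i, j);
      for (int u = i; u <= j; ++u) {
        double b = st.wm1(u, j);
        if (b >= INF) continue;
        if (std::fabs(fm.Mc * (u - i) + b - target) < eps) {
          todo.push({u, j, 3});
          break;
        }
        if (u > i && st.wm(i, u - 1) < INF &&
            std::fabs(st.wm(i, u - 1) + b - target) < eps) {
          todo.push({i, u - 1, 2});
          todo.push({u, j, 3});
          break;
        }
      }
    } else { // WM1
      double target = st.wm1(i, j);
      for (int l = i + fm.h + 1; l <= j; ++l) {
        if (st.v(i, l) >= INF) continue;
        if (std::fabs(st.v(i, l) + fm.Mb + fm.Mc * (j - l) - target) < eps) {
          todo.push({i, l, 1});
          break;
        }
      }
    }
  }
}

// [[Rcpp::export]]
List fold_mfe_cpp(IntegerVector seq, List model) {
  FoldModel fm = model_from_list(model);
  int n = seq.size();
  DPState st;
  st.n = n; st.fm = fm;
  st.s.assign(seq.begin(), seq.end());
  if (n == 0) return List::create(_["energy"] = 0.0, _["pairs"] = IntegerVector(0));
  fill_mfe(st);
  double e = st.W[n];
  std::vector<int> pt;
  traceback(st, pt);
  IntegerVector pairs(n);
  for (int i = 0; i < n; ++i) pairs[i] = pt[i] < 0 ? NA_INTEGER : pt[i] + 1; // 1-based
  return List::create(_["energy"] = e, _["pairs"] = pairs);
}

// [[Rcpp::export]]
List fold_partition_cpp(IntegerVector seq, List model) {
  FoldModel fm = model_from_list(model);
  int n = seq.size();
  std::vector<int> s(seq.begin(), seq.end());
  double RT = fm.RT;
  if (n == 0)
    return List::create(_["G"] = 0.0, _["bpp"] = NumericMatrix(0, 0));
  std::vector<double> QB((size_t)n * n, 0.0), QM((size_t)n * n, 0.0),
      QM1((size_t)n * n, 0.0);
  auto qb = [&](int i, int j) -> double& { return QB[(size_t)i * n + j]; };
  auto qm = [&](int i, int j) -> double& { return QM[(size_t)i * n + j]; };
  auto qm1 = [&](int i, int j) -> double& { return QM1[(size_t)i * n + j]; };
  for (int d = 1; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      if (pair_type_m(fm, s[i], s[j]) >= 0 && j - i - 1 >= fm.h) {
        double z = std::exp(-(fm.Ha + fm.Hb * (j - i - 1)) / RT);
        for (int k = i + 1; k < j; ++k) {
          if (k - i - 1 > fm.max_il) break;
          for (int l = j - 1; l > k; --l) {
            int sz = (k - i - 1) + (j - l - 1);
            if (sz > fm.max_il) break;
            if (qb(k, l) == 0.0) continue;
            z += std::exp(-il_energy(fm, s, i, j, k, l) / RT) * qb(k, l);
          }
        }
        double zml = 0.0;
        for (int u = i + 2; u < j - 1; ++u)
          zml += qm(i + 1, u - 1) * qm1(u, j - 1);
        z += std::exp(-(fm.Ma + fm.Mb) / RT) * zml;
        qb(i, j) = z;
      }
      {
        double z = 0.0;
        for (int l = i + fm.h + 1; l <= j; ++l)
          if (qb(i, l) > 0.0)
            z += qb(i, l) * std::exp(-(fm.Mb + fm.Mc * (j - l)) / RT);
        qm1(i, j) = z;
      }
      {
        double z = 0.0;
        for (int u = i; u <= j; ++u) {
          if (qm1(u, j) == 0.0) continue;
          double left = std::exp(-fm.Mc * (u - i) / RT);
          if (u > i) left += qm(i, u - 1);
          z += left * qm1(u, j);
        }
        qm(i, j) = z;
      }
    }
  }
  // exterior prefix/suffix
  std::vector<double> Qf(n + 1, 1.0), Qbk(n + 2, 1.0);
  for (int j = 0; j < n; ++j) {
    double z = Qf[j];
    for (int k = 0; k <= j; ++k)
      if (qb(k, j) > 0.0) z += Qf[k] * qb(k, j);
    Qf[j + 1] = z;
  }
  for (int i = n - 1; i >= 0; --i) {
    double z = Qbk[i + 1];
    for (int l = i; l < n; ++l)
      if (qb(i, l) > 0.0) z += qb(i, l) * Qbk[l + 1];
    Qbk[i] = z;
  }
  double Z = Qf[n];
  // outside: probabilities, processed outer -> inner
  NumericMatrix P(n, n);
  for (int d = n - 1; d >= 1; --d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      if (qb(i, j) == 0.0) continue;
      double p = P(i, j);
      p += qb(i, j) * Qf[i] * Qbk[j + 1] / Z; // exterior branch
      P(i, j) = p;
      if (p <= 0.0) continue;
      double coef = p / qb(i, j);
      // push internal-loop contributions to inner pairs
      for (int k = i + 1; k < j; ++k) {
        if (k - i - 1 > fm.max_il) break;
        for (int l = j - 1; l > k; --l) {
          int sz = (k - i - 1) + (j - l - 1);
          if (sz > fm.max_il) break;
          if (qb(k, l) == 0.0) continue;
          P(k, l) += coef * std::exp(-il_energy(fm, s, i, j, k, l) / RT) * qb(k, l);
        }
      }
      // push multiloop contributions: inner branch (k,l)
      double pref = coef * std::exp(-(fm.Ma + 2.0 * fm.Mb) / RT);
      for (int k = i + 1; k < j; ++k) {
        for (int l = k + fm.h + 1; l < j; ++l) {
          if (qb(k, l) == 0.0) continue;
          double lft_un = std::exp(-fm.Mc * (k - i - 1) / RT);
          double rgt_un = std::exp(-fm.Mc * (j - 1 - l) / RT);
          double lft_qm = (k - 1 >= i + 1) ? qm(i + 1, k - 1) : 0.0;
          double rgt_qm = (l + 1 <= j - 1) ? qm(l + 1, j - 1) : 0.0;
          double around = (lft_un + lft_qm) * (rgt_un + rgt_qm) - lft_un * rgt_un;
          if (around > 0.0)
            P(k, l) += pref * around * qb(k, l);
        }
      }
    }
  }
  double G = -RT * std::log(Z);
  // symmetrize for convenience
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) P(j, i) = P(i, j);
  return List::create(_["G"] = G, _["bpp"] = P);
}
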