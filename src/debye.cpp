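#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double sinc(double x) {
  // sin(x)/x with the x -> 0 limit taken as 1
  return (std::fabs(x) < 1e-12) ? 1.0 : std::sin(x) / x;
}

// Orientationally averaged Debye cross intensity between atom sets A and B:
//   X(q_s) = sum_{i in A} sum_{j in B} FA(i,s) FB(j,s) sinc(q_s d_ij)
// With A == B (same coordinates and factors) this is the full Debye sum,
// including the i == j self terms.
// [[Rcpp::export]]
NumericVector cpp_debye_cross(NumericMatrix coordsA, NumericMatrix FA,
                              NumericMatrix coordsB, NumericMatrix FB,
                              NumericVector q) {
  const int nA = coordsA.nrow(), nB = coordsB.nrow(), S = q.size();
  NumericVector out(S);
  for (int i = 0; i < nA; ++i) {
    const double xi = coordsA(i, 0), yi = coordsA(i, 1), zi = coordsA(i, 2);
    for (int j = 0; j < nB; ++j) {
      const double dx = xi - coordsB(j, 0);
      const double dy = yi - coordsB(j, 1);
      const double dz = zi - coordsB(j, 2);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      for (int s = 0; s < S; ++s)
        out[s] += FA(i, s) * FB(j, s) * sinc(q[s] * d);
    }
  }
  return out;
}

// Per-B-atom cross sums: row k holds sum_{i in A} FA(i,s) FB(k,s) sinc(q_s d_ik).
// Used to precompute each candidate ion's subprofile relative to the RNA.
// [[Rcpp::export]]
NumericMatrix cpp_debye_cross_rows(NumericMatrix coordsA, NumericMatrix FA,
                                   NumericMatrix coordsB, NumericMatrix FB,
                                   NumericVector q) {
  const int nA = coordsA.nrow(), nB = coordsB.nrow(), S = q.size();
  NumericMatrix out(nB, S);
  for (int k = 0; k < nB; ++k) {
    const double xk = coordsB(k, 0), yk = coordsB(k, 1), zk = coordsB(k, 2);
    for (int i = 0; i < nA; ++i) {
      const double dx = coordsA(i, 0) - xk;
      const double dy = coordsA(i, 1) - yk;
      const double dz = coordsA(i, 2) - zk;
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      for (int s = 0; s < S; ++s)
        out(k, s) += FA(i, s) * FB(k, s) * sinc(q[s] * d);
    }
  }
  return out;
}

// Six partial Debye intensities in one distance pass, for the FoXS-style
// decomposition I(q) = Ivv - 2 u Ivs + u^2 Iss + 2 v Ivw - 2 u v Isw + v^2 Iww
// where u(q) carries the excluded-volume adjustment and v = c2.
// FV/FS/FW are n x S matrices: vacuum, dummy-solvent and (accessibility-
// weighted) water factors per atom. Rows of the result: vv, vs, ss, vw, sw, ww.
// [[Rcpp::export]]
NumericMatrix cpp_debye_partials(NumericMatrix coords, NumericMatrix FV,
                                 NumericMatrix FS, NumericMatrix FW,
                                 NumericVector q) {
  const int n = coords.nrow(), S = q.size();
  NumericMatrix out(6, S);
  for (int i = 0; i < n; ++i) {
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    for (int j = 0; j < n; ++j) {
      const double dx = xi - coords(j, 0);
      const double dy = yi - coords(j, 1);
      const double dz = zi - coords(j, 2);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      for (int s = 0; s < S; ++s) {
        const double sc = sinc(q[s] * d);
        out(0, s) += FV(i, s) * FV(j, s) * sc;
        out(1, s) += FV(i, s) * FS(j, s) * sc;
        out(2, s) += FS(i, s) * FS(j, s) * sc;
        out(3, s) += FV(i, s) * FW(j, s) * sc;
        out(4, s) += FS(i, s) * FW(j, s) * sc;
        out(5, s) += FW(i, s) * FW(j, s) * sc;
      }
    }
  }
  return out;
}
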