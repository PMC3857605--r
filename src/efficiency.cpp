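#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// In-place Floyd-Warshall on a dense column-major buffer.
// Entries non-negative, R_PosInf marks absent edges, diagonal zero on entry.
// Exact for non-negative lengths. Column-major access order keeps the inner
// loop contiguous.
static void fw_inplace(double* D, int n) {
  for (int k = 0; k < n; ++k) {
    const double* colk = D + (size_t) k * n;
    for (int i = 0; i < n; ++i) {
      double dki = colk[i];
      if (!R_finite(dki)) continue;
      double* coli = D + (size_t) i * n;
      for (int j = 0; j < n; ++j) { // D(j,i) via k; branchless for SIMD
        double alt = colk[j] + dki;
        coli[j] = alt < coli[j] ? alt : coli[j];
      }
    }
  }
}

// All-pairs shortest paths over a matrix of edge lengths.
// [[Rcpp::export]]
NumericMatrix fw_cpp(NumericMatrix E) {
  int n = E.nrow();
  NumericMatrix D = clone(E);
  for (int i = 0; i < n; ++i) D(i, i) = 0.0;
  fw_inplace(REAL(D), n);
  return D;
}

// Raw per-node local efficiency over neighborhood subgraphs.
// W: strength matrix (w > 0 defines adjacency); L: fiber lengths (mm).
// weighted: edge lengths are l/w (weighted travel distance) instead of l.
// weight_term: each ordered-pair term is ((1/d_jk) * w_ij * w_ik)^(1/3)
// (the weighted nodal form); otherwise the term is 1/d_jk (the subgraph
// efficiency E(G_i)). Paths are restricted to the neighborhood subgraph.
// [[Rcpp::export]]
NumericVector local_eff_cpp(NumericMatrix W, NumericMatrix L,
                            bool weighted, bool weight_term) {
  int n = W.nrow();
  NumericVector out(n);
  const double* w = REAL(W);
  const double* l = REAL(L);
  std::vector<int> nbr(n);
  std::vector<double> sub((size_t) n * n);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j != i && w[(size_t) j * n + i] > 0) nbr[m++] = j;
    }
    if (m < 2) { out[i] = 0.0; continue; }
    for (int b = 0; b < m; ++b) {
      size_t colb = (size_t) nbr[b] * n;
      double* subb = sub.data() + (size_t) b * m;
      for (int a = 0; a < m; ++a) {
        double wab = w[colb + nbr[a]];
        subb[a] = (wab > 0)
          ? (weighted ? l[colb + nbr[a]] / wab : l[colb + nbr[a]])
          : R_PosInf;
      }
      subb[b] = 0.0;
    }
    fw_inplace(sub.data(), m);
    double total = 0.0;
    size_t coli = (size_t) i * n;
    for (int a = 0; a < m; ++a) {
      double wia = w[coli + nbr[a]];
      const double* suba = sub.data() + (size_t) a * m;
      for (int b = 0; b < m; ++b) {
        if (a == b) continue;
        double d = suba[b];
        if (!R_finite(d) || d <= 0) continue;
        if (weight_term) {
          total += std::cbrt((1.0 / d) * wia * w[coli + nbr[b]]);
        } else {
          total += 1.0 / d;
        }
      }
    }
    out[i] = total / ((double) m * (m - 1));
  }
  return out;
}
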