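#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Normalized mutual information between two integer-coded vectors.
// MI and entropies use natural logs of empirical frequencies;
// NMI = MI / sqrt(Hx * Hy), 0 if either entropy is 0.
static double nmi_pair(const int* x, const int* y, int n, int lx, int ly,
                       std::vector<double>& joint,
                       std::vector<double>& px, std::vector<double>& py) {
  std::fill(joint.begin(), joint.begin() + lx * ly, 0.0);
  std::fill(px.begin(), px.begin() + lx, 0.0);
  std::fill(py.begin(), py.begin() + ly, 0.0);
  const double w = 1.0 / n;
  for (int i = 0; i < n; ++i) {
    joint[x[i] * ly + y[i]] += w;
    px[x[i]] += w;
    py[y[i]] += w;
  }
  double hx = 0.0, hy = 0.0, mi = 0.0;
  for (int a = 0; a < lx; ++a) if (px[a] > 0) hx -= px[a] * std::log(px[a]);
  for (int b = 0; b < ly; ++b) if (py[b] > 0) hy -= py[b] * std::log(py[b]);
  if (hx <= 0.0 || hy <= 0.0) return 0.0;
  for (int a = 0; a < lx; ++a) {
    for (int b = 0; b < ly; ++b) {
      double p = joint[a * ly + b];
      if (p > 0) mi += p * std::log(p / (px[a] * py[b]));
    }
  }
  double v = mi / std::sqrt(hx * hy);
  if (v < 0) v = 0;
  if (v > 1) v = 1;
  return v;
}

// Per-row descending dense ranks with ties broken by a precomputed id
// order; entries of -Inf sink to the bottom.
// [[Rcpp::export]]
IntegerMatrix cpp_row_ranks(NumericMatrix B, IntegerVector id_order) {
  const int nr = B.nrow(), nc = B.ncol();
  IntegerMatrix out(nr, nc);
  std::vector<int> ord(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) ord[j] = id_order[j] - 1;
    std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
      return B(i, a) > B(i, b);
    });
    for (int r = 0; r < nc; ++r) out(i, ord[r]) = r + 1;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_nmi_block(IntegerMatrix A, IntegerMatrix B,
                            IntegerVector nlevA, IntegerVector nlevB,
                            bool symmetric) {
  const int n = A.nrow(), p = A.ncol(), q = B.ncol();
  if (B.nrow() != n) stop("row mismatch");
  int maxl = 2;
  for (int j = 0; j < p; ++j) maxl = std::max(maxl, nlevA[j]);
  for (int j = 0; j < q; ++j) maxl = std::max(maxl, nlevB[j]);
  std::vector<double> joint(maxl * maxl), px(maxl), py(maxl);
  NumericMatrix out(p, q);
  for (int i = 0; i < p; ++i) {
    const int j0 = symmetric ? i : 0;
    for (int j = j0; j < q; ++j) {
      double v = nmi_pair(&A(0, i), &B(0, j), n, nlevA[i], nlevB[j],
                          joint, px, py);
      out(i, j) = v;
      if (symmetric) out(j, i) = v;
    }
  }
  return out;
}
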