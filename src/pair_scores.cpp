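#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// All-pairs TSP scoring statistics.
//
// X: genes x samples expression, R: within-sample ranks of X (same shape),
// sens: per-sample class indicator (true = sensitive).
// Returns one row per unordered gene pair (i < j, 1-based indices) with the
// within-class fractions P(x_i > x_j) (ties counting 1/2) and the
// within-class mean rank differences rank_i - rank_j.
//
// Data are copied once into row-major buffers with sensitive samples first,
// so the O(G^2 n) scan runs over contiguous memory without branching on the
// class label.
// [[Rcpp::export]]
NumericMatrix pairScoreStats(const NumericMatrix& X, const NumericMatrix& R,
                             const LogicalVector& sens) {
  const int G = X.nrow();
  const int n = X.ncol();
  if (R.nrow() != G || R.ncol() != n)
    stop("rank matrix must match the expression matrix");
  if (sens.size() != n) stop("labels must match the number of samples");

  std::vector<int> order;
  order.reserve(n);
  for (int s = 0; s < n; ++s) if (sens[s]) order.push_back(s);
  const int nS = (int)order.size();
  for (int s = 0; s < n; ++s) if (!sens[s]) order.push_back(s);
  const int nR = n - nS;
  if (nS == 0 || nR == 0) stop("both classes must be non-empty");

  std::vector<double> xr((size_t)G * n), rr((size_t)G * n);
  for (int c = 0; c < n; ++c) {
    const int s = order[c];
    for (int i = 0; i < G; ++i) {
      xr[(size_t)i * n + c] = X(i, s);
      rr[(size_t)i * n + c] = R(i, s);
    }
  }

  const R_xlen_t npair = (R_xlen_t)G * (G - 1) / 2;
  NumericMatrix out(npair, 6);
  R_xlen_t row = 0;
  for (int i = 0; i < G; ++i) {
    const double* xi = &xr[(size_t)i * n];
    const double* ri = &rr[(size_t)i * n];
    for (int j = i + 1; j < G; ++j) {
      const double* xj = &xr[(size_t)j * n];
      const double* rj = &rr[(size_t)j * n];
      double cS = 0.0, rS = 0.0, cR = 0.0, rR = 0.0;
      for (int s = 0; s < nS; ++s) {
        cS += (xi[s] > xj[s]) + 0.5 * (xi[s] == xj[s]);
        rS += ri[s] - rj[s];
      }
      for (int s = nS; s < n; ++s) {
        cR += (xi[s] > xj[s]) + 0.5 * (xi[s] == xj[s]);
        rR += ri[s] - rj[s];
      }
      out(row, 0) = i + 1;
      out(row, 1) = j + 1;
      out(row, 2) = cS / nS;
      out(row, 3) = cR / nR;
      out(row, 4) = rS / nS;
      out(row, 5) = rR / nR;
      ++row;
    }
  }
  colnames(out) = CharacterVector::create("i", "j", "pS", "pR", "rdS", "rdR");
  return out;
}
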