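// Hot loops of the 3D convolution engine: the im2col gather (padded volume ->
// patch matrix) and its transpose scatter-add. Everything else (GEMM, pooling,
// activations) stays in R/BLAS.

#include <Rcpp.h>
using namespace Rcpp;

// out(i, j) = x[idx(i, j) - 1]; idx is 1-based into x.
// [[Rcpp::export(name = ".gather_cols")]]
NumericMatrix gather_cols(const NumericVector& x, const IntegerMatrix& idx) {
  const int nr = idx.nrow(), nc = idx.ncol();
  NumericMatrix out(nr, nc);
  const double* xp = REAL(x);
  const int* ip = INTEGER(idx);
  double* op = REAL(out);
  const R_xlen_t n = (R_xlen_t)nr * nc;
  for (R_xlen_t k = 0; k < n; ++k) op[k] = xp[ip[k] - 1];
  return out;
}

// acc[idx(i, j) - 1] += vals(i, j) over all entries; acc has length n.
// [[Rcpp::export(name = ".scatter_add")]]
NumericVector scatter_add(const int n, const IntegerMatrix& idx,
                          const NumericMatrix& vals) {
  NumericVector acc(n);
  const int* ip = INTEGER(idx);
  const double* vp = REAL(vals);
  double* ap = REAL(acc);
  const R_xlen_t m = (R_xlen_t)idx.nrow() * idx.ncol();
  for (R_xlen_t k = 0; k < m; ++k) ap[ip[k] - 1] += vp[k];
  return acc;
}
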