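// Fast gather / scatter-add kernels for the 3-D convolution layers.
//
// The R side caches, per layer geometry, an integer index matrix mapping
// every (output position, kernel offset, input channel) element of the
// im2col matrix to its 0-based position in the *unpadded* input array,
// with -1 marking same-padding positions. These kernels then realize the
// im2col gather and the transposed scatter-add without materializing any
// padded intermediate.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix hcn_gather(NumericVector x, IntegerVector idx, int nr, int nc) {
  NumericMatrix M(nr, nc);
  const double* xp = REAL(x);
  const int* ip = INTEGER(idx);
  double* mp = REAL(M);
  R_xlen_t n = (R_xlen_t)nr * nc;
  for (R_xlen_t j = 0; j < n; ++j) {
    int id = ip[j];
    mp[j] = id < 0 ? 0.0 : xp[id];
  }
  return M;
}

// [[Rcpp::export]]
NumericVector hcn_scatter_add(NumericMatrix dM, IntegerVector idx,
                              double n_out) {
  NumericVector out((R_xlen_t)n_out);
  const double* dp = REAL(dM);
  const int* ip = INTEGER(idx);
  double* op = REAL(out);
  R_xlen_t n = dM.size();
  for (R_xlen_t j = 0; j < n; ++j) {
    int id = ip[j];
    if (id >= 0) op[id] += dp[j];
  }
  return out;
}
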