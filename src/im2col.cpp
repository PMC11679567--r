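// Hot inner kernels of the 1-D convolution layers: patch unrolling
// (im2col) and its adjoint scatter-add (col2im), same padding, stride 1.
#include <Rcpp.h>
using namespace Rcpp;

// X: (C, L, B) array -> (C*k, L*B) matrix of unrolled k-wide patches
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector X, int C, int L, int B, int k) {
  int p = (k - 1) / 2;
  NumericMatrix out(C * k, L * B);
  const double* x = X.begin();
  double* o = out.begin();
  for (int b = 0; b < B; ++b) {
    const double* xb = x + (R_xlen_t)b * C * L;
    for (int l = 0; l < L; ++l) {
      double* col = o + ((R_xlen_t)b * L + l) * C * k;
      for (int j = 0; j < k; ++j) {
        int t = l + j - p;
        if (t >= 0 && t < L) {
          const double* src = xb + (R_xlen_t)t * C;
          double* dst = col + j * C;
          for (int c = 0; c < C; ++c) dst[c] = src[c];
        } else {
          double* dst = col + j * C;
          for (int c = 0; c < C; ++c) dst[c] = 0.0;
        }
      }
    }
  }
  return out;
}

// adjoint of im2col_cpp: (C*k, L*B) -> (C, L, B)
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix Dcol, int C, int L, int B, int k) {
  int p = (k - 1) / 2;
  NumericVector out((R_xlen_t)C * L * B);
  const double* d = Dcol.begin();
  double* o = out.begin();
  for (int b = 0; b < B; ++b) {
    double* ob = o + (R_xlen_t)b * C * L;
    for (int l = 0; l < L; ++l) {
      const double* col = d + ((R_xlen_t)b * L + l) * C * k;
      for (int j = 0; j < k; ++j) {
        int t = l + j - p;
        if (t >= 0 && t < L) {
          double* dst = ob + (R_xlen_t)t * C;
          const double* src = col + j * C;
          for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(C, L, B);
  return out;
}
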