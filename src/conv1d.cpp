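// im2col / col2im kernels for the raw-waveform GAN.
//
// Signals are R arrays dim (L, C, B) — time fastest — and conv weights are
// dim (K, Cin, Cout). The convolutions themselves are GEMMs in R (BLAS):
//   fwd:        y(Co, Lo*B)   = t(Wmat) %*% im2col(x)
//   bwd input:  gx            = col2im(Wmat %*% gy(Co, Lo*B))
//   bwd weight: gW(K*Ci, Co)  = im2col(x) %*% t(gy(Co, Lo*B))
// with Wmat = matrix(W, K*Ci, Co); im2col rows are ordered k fastest, then
// ci, matching Wmat's row order.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col1d(NumericVector x, int L, int Ci, int B,
                       int K, int stride, int pad) {
  int Lo = (L + 2 * pad - K) / stride + 1;
  NumericMatrix cols(K * Ci, static_cast<R_xlen_t>(Lo) * B);
  const double *px = x.begin();
  double *pc = cols.begin();
  for (int b = 0; b < B; ++b) {
    for (int lo = 0; lo < Lo; ++lo) {
      double *col = pc + (static_cast<R_xlen_t>(b) * Lo + lo) *
        (static_cast<R_xlen_t>(K) * Ci);
      int base = lo * stride - pad;
      int k0 = base < 0 ? -base : 0;
      int k1 = base + K > L ? L - base : K;
      for (int ci = 0; ci < Ci; ++ci) {
        const double *xi = px + (static_cast<R_xlen_t>(b) * Ci + ci) * L + base;
        double *dst = col + static_cast<R_xlen_t>(ci) * K;
        for (int k = 0; k < k0; ++k) dst[k] = 0.0;
        for (int k = k0; k < k1; ++k) dst[k] = xi[k];
        for (int k = k1; k < K; ++k) dst[k] = 0.0;
      }
    }
  }
  return cols;
}

// Adjoint of im2col1d: scatter-add column patches back into the signal.
// [[Rcpp::export]]
NumericVector col2im1d(NumericMatrix cols, int L, int Ci, int B,
                       int K, int stride, int pad) {
  int Lo = (L + 2 * pad - K) / stride + 1;
  NumericVector x(static_cast<R_xlen_t>(L) * Ci * B);
  const double *pc = cols.begin();
  double *px = x.begin();
  for (int b = 0; b < B; ++b) {
    for (int lo = 0; lo < Lo; ++lo) {
      const double *col = pc + (static_cast<R_xlen_t>(b) * Lo + lo) *
        (static_cast<R_xlen_t>(K) * Ci);
      int base = lo * stride - pad;
      int k0 = base < 0 ? -base : 0;
      int k1 = base + K > L ? L - base : K;
      for (int ci = 0; ci < Ci; ++ci) {
        double *xi = px + (static_cast<R_xlen_t>(b) * Ci + ci) * L + base;
        const double *src = col + static_cast<R_xlen_t>(ci) * K;
        for (int k = k0; k < k1; ++k) xi[k] += src[k];
      }
    }
  }
  x.attr("dim") = IntegerVector::create(L, Ci, B);
  return x;
}
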