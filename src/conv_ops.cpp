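// Hot kernels of the 1-D convolution and max-pooling layers: the im2col
// gather, its col2im scatter-add adjoint, and pooling with argmax. Arrays
// are (batch, length, channels) with batch fastest, matching R's layout.

#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// X: flat (B, L, C) array; returns (B*L, k*C) matrix whose column
// (o*C + c) holds channel c shifted by offset o - padl (zero outside).
// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericVector& X, int B, int L, int C,
                         int k, int padl) {
  NumericMatrix out(B * L, k * C);
  const double* x = X.begin();
  double* o_ = out.begin();
  for (int m = 0; m < k * C; ++m) {
    int off = m / C - padl;
    int c = m % C;
    double* col = o_ + (R_xlen_t)m * B * L;
    for (int l = 0; l < L; ++l) {
      int src = l + off;
      if (src >= 0 && src < L)
        std::memcpy(col + (R_xlen_t)l * B,
                    x + ((R_xlen_t)c * L + src) * B, sizeof(double) * B);
    }
  }
  return out;
}

// Adjoint of cpp_im2col: scatter-add the (B*L, k*C) gradient back onto the
// (B, L, C) input.
// [[Rcpp::export]]
NumericVector cpp_col2im(const NumericMatrix& dXc, int B, int L, int C,
                         int k, int padl) {
  NumericVector out((R_xlen_t)B * L * C);
  double* o_ = out.begin();
  const double* d = dXc.begin();
  for (int m = 0; m < k * C; ++m) {
    int off = m / C - padl;
    int c = m % C;
    const double* col = d + (R_xlen_t)m * B * L;
    for (int l = 0; l < L; ++l) {
      int src = l + off;
      if (src >= 0 && src < L) {
        double* dst = o_ + ((R_xlen_t)c * L + src) * B;
        const double* s = col + (R_xlen_t)l * B;
        for (int b = 0; b < B; ++b) dst[b] += s[b];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(B, L, C);
  return out;
}

// Non-overlapping max pooling of width p; returns the pooled (B, L/p, C)
// array and the 1-based argmax offsets used by the backward pass.
// [[Rcpp::export]]
List cpp_maxpool_fw(const NumericVector& X, int B, int L, int C, int p) {
  int Lout = L / p;
  NumericVector out((R_xlen_t)B * Lout * C);
  IntegerVector amax((R_xlen_t)B * Lout * C);
  const double* x = X.begin();
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Lout; ++j)
      for (int b = 0; b < B; ++b) {
        R_xlen_t base = ((R_xlen_t)c * L + (R_xlen_t)j * p) * B + b;
        double best = x[base];
        int bi = 1;
        for (int i = 1; i < p; ++i) {
          double v = x[base + (R_xlen_t)i * B];
          if (v > best) { best = v; bi = i + 1; }
        }
        R_xlen_t oidx = ((R_xlen_t)c * Lout + j) * B + b;
        out[oidx] = best;
        amax[oidx] = bi;
      }
  out.attr("dim") = IntegerVector::create(B, Lout, C);
  amax.attr("dim") = IntegerVector::create(B, Lout, C);
  return List::create(_["out"] = out, _["amax"] = amax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(const NumericVector& dY,
                             const IntegerVector& amax,
                             int B, int L, int C, int p) {
  int Lout = L / p;
  NumericVector out((R_xlen_t)B * L * C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Lout; ++j)
      for (int b = 0; b < B; ++b) {
        R_xlen_t oidx = ((R_xlen_t)c * Lout + j) * B + b;
        int i = amax[oidx] - 1;
        out[((R_xlen_t)c * L + (R_xlen_t)j * p + i) * B + b] = dY[oidx];
      }
  out.attr("dim") = IntegerVector::create(B, L, C);
  return out;
}
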