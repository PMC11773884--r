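// Depthwise k x k convolution (stride 1, implicit same padding) on
// channel-first activation arrays (C, H, W, N), plus its backward pass.
// These are the hot kernels of the residual block; everything else in the
// network reduces to BLAS matrix products and stays in R.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector dwconv_fwd_cpp(const NumericVector& x, const IntegerVector& dims,
                             const NumericVector& w, const NumericVector& b,
                             int k, int pad) {
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  NumericVector y(x.size());
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* yp = y.begin();
  const R_xlen_t planeH = (R_xlen_t)C;         // stride of h
  const R_xlen_t planeW = (R_xlen_t)C * H;     // stride of w
  const R_xlen_t planeN = (R_xlen_t)C * H * W; // stride of n

  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < W; ++wo) {
      for (int ho = 0; ho < H; ++ho) {
        double* yo = yp + n * planeN + wo * planeW + ho * planeH;
        for (int c = 0; c < C; ++c) yo[c] = b[c];
        for (int kj = 0; kj < k; ++kj) {
          int wi = wo + kj - pad;
          if (wi < 0 || wi >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            int hi = ho + ki - pad;
            if (hi < 0 || hi >= H) continue;
            const double* xi = xp + n * planeN + wi * planeW + hi * planeH;
            const double* wk = wp + (R_xlen_t)C * (ki + k * kj);
            for (int c = 0; c < C; ++c) yo[c] += xi[c] * wk[c];
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List dwconv_bwd_cpp(const NumericVector& x, const NumericVector& dy,
                    const IntegerVector& dims, const NumericVector& w,
                    int k, int pad) {
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  NumericVector dx(x.size());
  NumericVector dw((R_xlen_t)C * k * k);
  NumericVector db(C);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  const double* wp = w.begin();
  double* dxp = dx.begin();
  double* dwp = dw.begin();
  const R_xlen_t planeH = (R_xlen_t)C;
  const R_xlen_t planeW = (R_xlen_t)C * H;
  const R_xlen_t planeN = (R_xlen_t)C * H * W;

  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < W; ++wo) {
      for (int ho = 0; ho < H; ++ho) {
        const double* g = dyp + n * planeN + wo * planeW + ho * planeH;
        for (int c = 0; c < C; ++c) db[c] += g[c];
        for (int kj = 0; kj < k; ++kj) {
          int wi = wo + kj - pad;
          if (wi < 0 || wi >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            int hi = ho + ki - pad;
            if (hi < 0 || hi >= H) continue;
            const R_xlen_t off = n * planeN + wi * planeW + hi * planeH;
            const double* xi = xp + off;
            double* dxi = dxp + off;
            const double* wk = wp + (R_xlen_t)C * (ki + k * kj);
            double* dwk = dwp + (R_xlen_t)C * (ki + k * kj);
            for (int c = 0; c < C; ++c) {
              dwk[c] += g[c] * xi[c];
              dxi[c] += g[c] * wk[c];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
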