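#include <Rcpp.h>
using namespace Rcpp;

// Unrolls an (H, W, C) column-major array into a (kh*kw*C) x (Ho*Wo) matrix
// of receptive-field columns for a strided convolution with zero padding.
// Column l = ho + Ho*wo; row r = ki + kh*kj + kh*kw*c.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C,
                         int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int K = kh * kw * C;
  const int L = Ho * Wo;
  NumericMatrix cols(K, L);
  const double *px = x.begin();
  double *pc = cols.begin();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int l = ho + Ho * wo;
      double *col = pc + (size_t)l * K;
      for (int c = 0; c < C; ++c) {
        const double *plane = px + (size_t)c * H * W;
        for (int kj = 0; kj < kw; ++kj) {
          const int w = wo * stride - pad + kj;
          const bool win = (w >= 0 && w < W);
          for (int ki = 0; ki < kh; ++ki) {
            const int h = ho * stride - pad + ki;
            const int r = ki + kh * (kj + kw * c);
            col[r] = (win && h >= 0 && h < H) ? plane[h + (size_t)H * w] : 0.0;
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of cpp_im2col: scatter-adds receptive-field columns back onto the
// (H, W, C) input grid. Used for the input gradient of a convolution.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C,
                         int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int K = kh * kw * C;
  NumericVector x(H * W * C);
  double *px = x.begin();
  const double *pc = cols.begin();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int l = ho + Ho * wo;
      const double *col = pc + (size_t)l * K;
      for (int c = 0; c < C; ++c) {
        double *plane = px + (size_t)c * H * W;
        for (int kj = 0; kj < kw; ++kj) {
          const int w = wo * stride - pad + kj;
          if (w < 0 || w >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            const int h = ho * stride - pad + ki;
            if (h < 0 || h >= H) continue;
            plane[h + (size_t)H * w] += col[ki + kh * (kj + kw * c)];
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C);
  return x;
}
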