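// Data-movement kernels for the convolution layers: im2col/col2im with
// implicit "same" zero padding.  Activations use channels-last
// (H, W, N, C) layout; the column matrix has rows ordered (i, j, n) and
// columns ordered (di, dj, c), matching the column-major flattening of a
// (k, k, Cin, Cout) kernel array.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col_nc(NumericVector x, int H, int W, int N, int C, int k) {
  const int p = (k - 1) / 2;
  const long HWN = (long)H * W * N;
  NumericMatrix out(HWN, (long)k * k * C);
  const double* xd = x.begin();
  for (int c = 0; c < C; ++c) {
    const long xoff = (long)c * H * W * N;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const long col = (long)di + (long)k * dj + (long)k * k * c;
        double* od = &out(0, col);
        for (int n = 0; n < N; ++n) {
          const long xn = xoff + (long)n * H * W;
          const long on = (long)n * H * W;
          for (int j = 0; j < W; ++j) {
            const int js = j + dj - p;
            double* ocol = od + on + (long)j * H;
            if (js < 0 || js >= W) {
              for (int i = 0; i < H; ++i) ocol[i] = 0.0;
              continue;
            }
            const double* xcol = xd + xn + (long)js * H;
            const int shift = di - p;  // source row = i + shift
            int i0 = std::max(0, -shift);
            int i1 = std::min(H, H - shift);
            for (int i = 0; i < i0; ++i) ocol[i] = 0.0;
            for (int i = i0; i < i1; ++i) ocol[i] = xcol[i + shift];
            for (int i = i1; i < H; ++i) ocol[i] = 0.0;
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_nc(NumericMatrix cols, int H, int W, int N, int C,
                        int k) {
  const int p = (k - 1) / 2;
  NumericVector out((long)H * W * N * C);
  double* od = out.begin();
  for (int c = 0; c < C; ++c) {
    const long ooff = (long)c * H * W * N;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const long col = (long)di + (long)k * dj + (long)k * k * c;
        const double* cd = &cols(0, col);
        for (int n = 0; n < N; ++n) {
          const long on = ooff + (long)n * H * W;
          const long cn = (long)n * H * W;
          for (int j = 0; j < W; ++j) {
            const int js = j + dj - p;
            if (js < 0 || js >= W) continue;
            const double* ccol = cd + cn + (long)j * H;
            double* ocol = od + on + (long)js * H;
            const int shift = di - p;
            int i0 = std::max(0, -shift);
            int i1 = std::min(H, H - shift);
            for (int i = i0; i < i1; ++i) ocol[i + shift] += ccol[i];
          }
        }
      }
    }
  }
  return out;
}
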