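#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Patch extraction for convolution. x is an (H, W, C) array (column-major,
// as R stores it). Returns a (C*k*k) x (Ho*Wo) matrix where row index is
// ordered (dy fastest, then dx, then c) and column index is ho + Ho*wo.
// Zero padding `pad`, stride `stride`.
// [[Rcpp::export(name = ".cpp_im2col")]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(C * k * k, Ho * Wo);
  const double* px = x.begin();
  double* po = out.begin();
  const int nrow = C * k * k;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = ho + Ho * wo;
      double* dst = po + (R_xlen_t)col * nrow;
      const int hi0 = ho * stride - pad;
      const int wi0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        const double* xc = px + (R_xlen_t)c * H * W;
        for (int dx = 0; dx < k; ++dx) {
          const int wi = wi0 + dx;
          for (int dy = 0; dy < k; ++dy) {
            const int hi = hi0 + dy;
            double v = 0.0;
            if (hi >= 0 && hi < H && wi >= 0 && wi < W)
              v = xc[hi + (R_xlen_t)wi * H];
            *dst++ = v;
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col: scatter-add columns back into an (H, W, C) array.
// [[Rcpp::export(name = ".cpp_col2im")]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector x((R_xlen_t)H * W * C);
  double* px = x.begin();
  const double* pc = cols.begin();
  const int nrow = C * k * k;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = ho + Ho * wo;
      const double* src = pc + (R_xlen_t)col * nrow;
      const int hi0 = ho * stride - pad;
      const int wi0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        double* xc = px + (R_xlen_t)c * H * W;
        for (int dx = 0; dx < k; ++dx) {
          const int wi = wi0 + dx;
          for (int dy = 0; dy < k; ++dy) {
            const int hi = hi0 + dy;
            if (hi >= 0 && hi < H && wi >= 0 && wi < W)
              xc[hi + (R_xlen_t)wi * H] += *src;
            ++src;
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C);
  return x;
}

// 8-connectivity connected-component labelling of a binary matrix.
// Returns an integer matrix of labels (0 = background, 1..n components),
// numbered in column-major scan order of each component's first pixel.
// [[Rcpp::export(name = ".cpp_label8")]]
IntegerMatrix cpp_label8(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  const int dh[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dw[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      if (mask(h, w) != 0 && lab(h, w) == 0) {
        ++next;
        stack.clear();
        stack.push_back(h + w * H);
        lab(h, w) = next;
        while (!stack.empty()) {
          const int idx = stack.back();
          stack.pop_back();
          const int ch = idx % H, cw = idx / H;
          for (int d = 0; d < 8; ++d) {
            const int nh = ch + dh[d], nw = cw + dw[d];
            if (nh >= 0 && nh < H && nw >= 0 && nw < W &&
                mask(nh, nw) != 0 && lab(nh, nw) == 0) {
              lab(nh, nw) = next;
              stack.push_back(nh + nw * H);
            }
          }
        }
      }
    }
  }
  return lab;
}
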