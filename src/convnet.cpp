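// Minimal CPU training primitives for the segmentation / regression networks.
// Layout conventions (match the R side):
//   * activations: arma::cube (H, W, C), column-major as R arrays
//   * conv weights: matrix (k*k*Cin, Cout); the row index is dr + k*dc + k*k*c,
//     i.e. the column-major flattening of an R array dim (k, k, Cin, Cout)
//   * stride is always 1, padding "same" (pad = (k-1)/2)
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

static mat im2col(const cube& x, int k, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out(H * (size_t)W, (size_t)k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dc = 0; dc < k; ++dc) {
      for (int dr = 0; dr < k; ++dr) {
        const int col = dr + k * dc + k * k * c;
        const int r0 = std::max(0, pad - dr);          // dest rows [r0, r1)
        const int r1 = std::min(H, H + pad - dr);
        const int c0 = std::max(0, pad - dc);
        const int c1 = std::min(W, W + pad - dc);
        if (r1 <= r0 || c1 <= c0) continue;
        double* dst0 = out.colptr(col);
        for (int wc = c0; wc < c1; ++wc) {
          const double* src = &x(r0 + dr - pad, wc + dc - pad, c);
          std::memcpy(dst0 + (size_t)wc * H + r0, src,
                      (size_t)(r1 - r0) * sizeof(double));
        }
      }
    }
  }
  return out;
}

static cube col2im(const mat& g, int H, int W, int C, int k, int pad) {
  cube out(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dc = 0; dc < k; ++dc) {
      for (int dr = 0; dr < k; ++dr) {
        const int col = dr + k * dc + k * k * c;
        const int r0 = std::max(0, pad - dr);
        const int r1 = std::min(H, H + pad - dr);
        const int c0 = std::max(0, pad - dc);
        const int c1 = std::min(W, W + pad - dc);
        if (r1 <= r0 || c1 <= c0) continue;
        const double* src0 = g.colptr(col);
        for (int wc = c0; wc < c1; ++wc) {
          double* dst = &out(r0 + dr - pad, wc + dc - pad, c);
          const double* src = src0 + (size_t)wc * H + r0;
          for (int r = 0; r < r1 - r0; ++r) dst[r] += src[r];
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube nn_conv_fw(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, int k, int pad) {
  mat y = im2col(x, k, pad) * w;
  y.each_row() += b.t();
  cube out(x.n_rows, x.n_cols, w.n_cols);
  std::memcpy(out.memptr(), y.memptr(), y.n_elem * sizeof(double));
  return out;
}

// [[Rcpp::export]]
Rcpp::List nn_conv_bw(const arma::cube& x, const arma::mat& w,
                      const arma::cube& gy, int k, int pad) {
  const int H = x.n_rows, W = x.n_cols;
  mat gym((double*)gy.memptr(), (size_t)H * W, gy.n_slices);
  mat cols = im2col(x, k, pad);
  mat gw = cols.t() * gym;
  vec gb = arma::sum(gym, 0).t();
  cube gx = col2im(gym * w.t(), H, W, x.n_slices, k, pad);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling (H, W even); idx stores the within-window argmax (0..3,
// column-major: 0 = (0,0), 1 = (1,0), 2 = (0,1), 3 = (1,1)).
// [[Rcpp::export]]
Rcpp::List nn_pool_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int h = H / 2, w = W / 2;
  cube y(h, w, C);
  IntegerVector idx((size_t)h * w * C);
  size_t p = 0;
  for (int c = 0; c < C; ++c)
    for (int wc = 0; wc < w; ++wc)
      for (int r = 0; r < h; ++r) {
        const double v00 = x(2 * r, 2 * wc, c), v10 = x(2 * r + 1, 2 * wc, c);
        const double v01 = x(2 * r, 2 * wc + 1, c),
                     v11 = x(2 * r + 1, 2 * wc + 1, c);
        double best = v00; int bi = 0;
        if (v10 > best) { best = v10; bi = 1; }
        if (v01 > best) { best = v01; bi = 2; }
        if (v11 > best) { best = v11; bi = 3; }
        y(r, wc, c) = best;
        idx[p++] = bi;
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube nn_pool_bw(const arma::cube& gy, const Rcpp::IntegerVector& idx,
                      int H, int W) {
  const int C = gy.n_slices, h = gy.n_rows, w = gy.n_cols;
  cube gx(H, W, C, arma::fill::zeros);
  size_t p = 0;
  for (int c = 0; c < C; ++c)
    for (int wc = 0; wc < w; ++wc)
      for (int r = 0; r < h; ++r) {
        const int bi = idx[p];
        gx(2 * r + (bi & 1), 2 * wc + (bi >> 1), c) = gy(r, wc, c);
        ++p;
      }
  return gx;
}

// nearest-neighbour 2x upsampling
// [[Rcpp::export]]
arma::cube nn_up_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int wc = 0; wc < W; ++wc)
      for (int r = 0; r < H; ++r) {
        const double v = x(r, wc, c);
        y(2 * r, 2 * wc, c) = v;
        y(2 * r + 1, 2 * wc, c) = v;
        y(2 * r, 2 * wc + 1, c) = v;
        y(2 * r + 1, 2 * wc + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube nn_up_bw(const arma::cube& gy) {
  const int H = gy.n_rows / 2, W = gy.n_cols / 2, C = gy.n_slices;
  cube gx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int wc = 0; wc < W; ++wc)
      for (int r = 0; r < H; ++r)
        gx(r, wc, c) = gy(2 * r, 2 * wc, c) + gy(2 * r + 1, 2 * wc, c) +
                       gy(2 * r, 2 * wc + 1, c) + gy(2 * r + 1, 2 * wc + 1, c);
  return gx;
}
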