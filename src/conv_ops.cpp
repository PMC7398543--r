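// Low-level numerical kernels for the patch-wise U-net: same-padding 2D
// convolution (im2col + GEMM) with its backward pass, 2x2 max pooling with an
// argmax cache, x2 nearest-neighbour upsampling, per-pixel channel softmax,
// and the exact Euclidean Hausdorff distance between binary masks.
//
// Array conventions: a feature map is an arma::cube (H rows, W cols,
// C channels), i.e. an R array dim = c(H, W, C).  A conv weight is a matrix of
// size (kh*kw*cin) x cout whose row index is c*kh*kw + q*kh + p for kernel
// offset (p, q) in channel c; im2col produces columns in the same order so
// the forward pass is a single GEMM.  Padding is "same": pad floor((k-1)/2)
// before the origin, so even kernels (2x2) anchor at the top-left and output
// size equals input size.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Builds M of size (H*W) x (kh*kw*C): row j*H+i holds the receptive field of
// output pixel (i, j), column c*kh*kw + q*kh + p its (p, q) offset in channel
// c. Stored output-major so every (column, j) pair is a contiguous run that
// can be block-copied from the image column.
static void im2col(const cube& x, const int kh, const int kw, mat& M) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pt = (kh - 1) / 2, pl = (kw - 1) / 2;
  M.zeros(H * W, kh * kw * C);
  for (int c = 0; c < C; ++c) {
    for (int q = 0; q < kw; ++q) {
      for (int p = 0; p < kh; ++p) {
        const int col = c * kh * kw + q * kh + p;
        const int i0 = std::max(0, pt - p), i1 = std::min(H, H + pt - p);
        if (i1 <= i0) continue;
        double* dst0 = M.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int jj = j + q - pl;
          if (jj < 0 || jj >= W) continue;
          const double* src = &x(i0 + p - pt, jj, c);
          std::memcpy(dst0 + j * H + i0, src, (i1 - i0) * sizeof(double));
        }
      }
    }
  }
}

// scatter-add inverse of im2col
static void col2im(const mat& M, const int kh, const int kw,
                   const int H, const int W, const int C, cube& x) {
  const int pt = (kh - 1) / 2, pl = (kw - 1) / 2;
  x.zeros(H, W, C);
  for (int c = 0; c < C; ++c) {
    for (int q = 0; q < kw; ++q) {
      for (int p = 0; p < kh; ++p) {
        const int col = c * kh * kw + q * kh + p;
        const int i0 = std::max(0, pt - p), i1 = std::min(H, H + pt - p);
        if (i1 <= i0) continue;
        const double* src0 = M.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int jj = j + q - pl;
          if (jj < 0 || jj >= W) continue;
          double* dst = &x(i0 + p - pt, jj, c);
          const double* src = src0 + j * H + i0;
          for (int i = 0; i < i1 - i0; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_forward")]]
arma::cube conv2d_forward(const arma::cube& x, const arma::mat& w,
                          const arma::vec& b, const int kh, const int kw) {
  const int H = x.n_rows, W = x.n_cols;
  const int cout = w.n_cols;
  mat M;
  im2col(x, kh, kw, M);
  mat y = M * w;                  // (H*W) x cout
  y.each_row() += b.t();
  cube out(y.memptr(), H, W, cout);
  return out;
}

// [[Rcpp::export(name = ".conv2d_backward")]]
Rcpp::List conv2d_backward(const arma::cube& x, const arma::mat& w,
                           const arma::cube& gout, const int kh, const int kw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int cout = gout.n_slices;
  mat M;
  im2col(x, kh, kw, M);
  mat g(const_cast<double*>(gout.memptr()), H * W, cout, false, true);
  mat gw = M.t() * g;             // (kh*kw*C) x cout
  vec gb = sum(g, 0).t();
  mat gM = g * w.t();             // (H*W) x (kh*kw*C)
  cube gx;
  col2im(gM, kh, kw, H, W, C, gx);
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// [[Rcpp::export(name = ".maxpool_forward")]]
Rcpp::List maxpool_forward(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  umat idx(Ho * Wo, C);           // linear index into the H x W input plane
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        int bi = 2 * i, bj = 2 * j;
        double best = x(bi, bj, c);
        int besti = bi, bestj = bj;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const double v = x(bi + di, bj + dj, c);
            if (v > best) { best = v; besti = bi + di; bestj = bj + dj; }
          }
        }
        y(i, j, c) = best;
        idx(j * Ho + i, c) = (unsigned) (bestj * H + besti);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(name = ".maxpool_backward")]]
arma::cube maxpool_backward(const arma::umat& idx, const arma::cube& gy,
                            const int H, const int W) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, C = gy.n_slices;
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const unsigned k = idx(j * Ho + i, c);
        gx(k % H, k / H, c) += gy(i, j, c);
      }
    }
  }
  return gx;
}

// [[Rcpp::export(name = ".upsample_forward")]]
arma::cube upsample_forward(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        y(2 * i,     2 * j,     c) = v;
        y(2 * i + 1, 2 * j,     c) = v;
        y(2 * i,     2 * j + 1, c) = v;
        y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export(name = ".upsample_backward")]]
arma::cube upsample_backward(const arma::cube& gy) {
  const int H = gy.n_rows / 2, W = gy.n_cols / 2, C = gy.n_slices;
  cube gx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        gx(i, j, c) = gy(2 * i, 2 * j, c) + gy(2 * i + 1, 2 * j, c) +
                      gy(2 * i, 2 * j + 1, c) + gy(2 * i + 1, 2 * j + 1, c);
  return gx;
}

// [[Rcpp::export(name = ".softmax_channels")]]
arma::cube softmax_channels(const arma::cube& logits) {
  const int H = logits.n_rows, W = logits.n_cols, C = logits.n_slices;
  cube p(H, W, C);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double m = logits(i, j, 0);
      for (int c = 1; c < C; ++c) m = std::max(m, logits(i, j, c));
      double s = 0.0;
      for (int c = 0; c < C; ++c) {
        const double e = std::exp(logits(i, j, c) - m);
        p(i, j, c) = e;
        s += e;
      }
      for (int c = 0; c < C; ++c) p(i, j, c) /= s;
    }
  }
  return p;
}

static double directed_hd_sq(const mat& A, const mat& B) {
  double worst = 0.0;
  for (uword a = 0; a < A.n_rows; ++a) {
    double best = datum::inf;
    for (uword b = 0; b < B.n_rows; ++b) {
      const double dr = A(a, 0) - B(b, 0), dc = A(a, 1) - B(b, 1);
      const double d = dr * dr + dc * dc;
      if (d < best) {
        best = d;
        if (best <= worst) break;  // cannot raise the running maximum
      }
    }
    if (best > worst) worst = best;
  }
  return worst;
}

// [[Rcpp::export(name = ".hausdorff_points")]]
double hausdorff_points(const arma::mat& a, const arma::mat& b) {
  if (a.n_rows == 0 || b.n_rows == 0) return NA_REAL;
  return std::sqrt(std::max(directed_hd_sq(a, b), directed_hd_sq(b, a)));
}
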