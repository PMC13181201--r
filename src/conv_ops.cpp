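// Convolutional layer primitives (forward + backward) used by the
// reconstruction networks. Single-sample tensors are arma::cube with
// dimensions (H, W, C); weights are flat matrices so that every product
// runs through BLAS:
//   conv weights      : C_out x (C_in*kh*kw)
//   transposed-conv   : C_in  x (C_out*kh*kw)
// Column index inside a weight row block is (c*kh + di)*kw + dj.
//
// The patch matrix is kept transposed, K: (Ho*Wo) x (C*kh*kw), so both
// the patch gather and the GEMM touch contiguous memory; a cube's memory
// is exactly the (H*W) x C matrix of its vectorised slices, which the
// code aliases without copying.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static inline int conv_out(int H, int k, int stride, int pad) {
  return (H + 2 * pad - k) / stride + 1;
}

static inline void valid_range(int n_out, int n_in, int stride, int pad,
                               int d, int& lo, int& hi) {
  lo = 0;
  while (lo < n_out && lo * stride - pad + d < 0) ++lo;
  hi = n_out;
  while (hi > lo && (hi - 1) * stride - pad + d >= n_in) --hi;
}

// K(oj*Ho + oi, (c*kh + di)*kw + dj) = x(i, j, c)
static mat im2col_t(const cube& x, int kh, int kw, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = conv_out(H, kh, stride, pad);
  const int Wo = conv_out(W, kw, stride, pad);
  mat K((size_t)Ho * Wo, (size_t)C * kh * kw, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int di = 0; di < kh; ++di) {
      int ilo, ihi;
      valid_range(Ho, H, stride, pad, di, ilo, ihi);
      for (int dj = 0; dj < kw; ++dj) {
        int jlo, jhi;
        valid_range(Wo, W, stride, pad, dj, jlo, jhi);
        double* Kcol = K.colptr((size_t)(c * kh + di) * kw + dj);
        for (int oj = jlo; oj < jhi; ++oj) {
          const int j = oj * stride - pad + dj;
          const double* xcol = &x(0, j, c);
          double* Kc = Kcol + (size_t)oj * Ho;
          for (int oi = ilo; oi < ihi; ++oi)
            Kc[oi] = xcol[oi * stride - pad + di];
        }
      }
    }
  }
  return K;
}

// adjoint of im2col_t: accumulate K back into the (H, W, C) cube
static void col2im_t_acc(cube& x, const mat& K, int kh, int kw, int stride,
                         int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = conv_out(H, kh, stride, pad);
  const int Wo = conv_out(W, kw, stride, pad);
  for (int c = 0; c < C; ++c) {
    for (int di = 0; di < kh; ++di) {
      int ilo, ihi;
      valid_range(Ho, H, stride, pad, di, ilo, ihi);
      for (int dj = 0; dj < kw; ++dj) {
        int jlo, jhi;
        valid_range(Wo, W, stride, pad, dj, jlo, jhi);
        const double* Kcol = K.colptr((size_t)(c * kh + di) * kw + dj);
        for (int oj = jlo; oj < jhi; ++oj) {
          const int j = oj * stride - pad + dj;
          double* xcol = &x(0, j, c);
          const double* Kc = Kcol + (size_t)oj * Ho;
          for (int oi = ilo; oi < ihi; ++oi)
            xcol[oi * stride - pad + di] += Kc[oi];
        }
      }
    }
  }
}

// zero-copy (H*W) x C matrix view of a cube's memory
static inline mat cube_view(const cube& x) {
  return mat(const_cast<double*>(x.memptr()), x.n_rows * x.n_cols,
             x.n_slices, false, true);
}

// [[Rcpp::export]]
arma::cube cpp_conv2d(const arma::cube& x, const arma::mat& W,
                      const arma::vec& b, int kh, int kw, int stride,
                      int pad) {
  const int Ho = conv_out(x.n_rows, kh, stride, pad);
  const int Wo = conv_out(x.n_cols, kw, stride, pad);
  mat K = im2col_t(x, kh, kw, stride, pad);
  cube y(Ho, Wo, W.n_rows);
  mat yv = cube_view(y);
  yv = K * W.t();
  yv.each_row() += b.t();
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& W,
                          const arma::cube& dy, int kh, int kw, int stride,
                          int pad) {
  mat dyv = cube_view(dy);
  mat K = im2col_t(x, kh, kw, stride, pad);
  mat dW = dyv.t() * K;
  vec db = sum(dyv, 0).t();
  mat dK = dyv * W;
  cube dx(x.n_rows, x.n_cols, x.n_slices, fill::zeros);
  col2im_t_acc(dx, dK, kh, kw, stride, pad);
  return List::create(Named("dx") = dx, Named("dW") = dW, Named("db") = db);
}

// transposed convolution: output H = (Hin-1)*stride + kh - 2*pad
// [[Rcpp::export]]
arma::cube cpp_convT2d(const arma::cube& x, const arma::mat& W,
                       const arma::vec& b, int kh, int kw, int stride,
                       int pad, int Cout) {
  const int Hout = (x.n_rows - 1) * stride + kh - 2 * pad;
  const int Wout = (x.n_cols - 1) * stride + kw - 2 * pad;
  mat xv = cube_view(x);
  mat K = xv * W;  // (Hin*Win) x (Cout*kh*kw)
  cube y(Hout, Wout, Cout, fill::zeros);
  col2im_t_acc(y, K, kh, kw, stride, pad);
  mat yv = cube_view(y);
  yv.each_row() += b.t();
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_convT2d_bwd(const arma::cube& x, const arma::mat& W,
                           const arma::cube& dy, int kh, int kw, int stride,
                           int pad) {
  mat K = im2col_t(dy, kh, kw, stride, pad);  // (Hin*Win) x (Cout*kh*kw)
  cube dx(x.n_rows, x.n_cols, x.n_slices);
  mat dxv = cube_view(dx);
  dxv = K * W.t();
  mat xv = cube_view(x);
  mat dW = xv.t() * K;
  mat dyv = cube_view(dy);
  vec db = sum(dyv, 0).t();
  return List::create(Named("dx") = dx, Named("dW") = dW, Named("db") = db);
}

// 2x2 max pooling, stride 2; argmax stored as code 0..3 (di*2 + dj)
// [[Rcpp::export]]
Rcpp::List cpp_maxpool2(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C), amax(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int oj = 0; oj < Wo; ++oj) {
      const double* x0 = &x(0, 2 * oj, c);
      const double* x1 = &x(0, 2 * oj + 1, c);
      for (int oi = 0; oi < Ho; ++oi) {
        double best = x0[2 * oi];
        int code = 0;
        if (x1[2 * oi] > best) { best = x1[2 * oi]; code = 1; }
        if (x0[2 * oi + 1] > best) { best = x0[2 * oi + 1]; code = 2; }
        if (x1[2 * oi + 1] > best) { best = x1[2 * oi + 1]; code = 3; }
        y(oi, oj, c) = best;
        amax(oi, oj, c) = code;
      }
    }
  }
  return List::create(Named("y") = y, Named("amax") = amax);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::cube& amax, const arma::cube& dy,
                            int H, int W) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int oj = 0; oj < Wo; ++oj)
      for (int oi = 0; oi < Ho; ++oi) {
        const int code = (int)amax(oi, oj, c);
        dx(2 * oi + code / 2, 2 * oj + code % 2, c) += dy(oi, oj, c);
      }
  return dx;
}

// bilinear 2x upsampling, half-pixel-centre convention
static void up2_weights(int n_out, int n_in, ivec& i0, ivec& i1, vec& w1) {
  i0.set_size(n_out); i1.set_size(n_out); w1.set_size(n_out);
  for (int i = 0; i < n_out; ++i) {
    double src = (i + 0.5) / 2.0 - 0.5;
    int f = (int)std::floor(src);
    double w = src - f;
    i0(i) = std::min(std::max(f, 0), n_in - 1);
    i1(i) = std::min(std::max(f + 1, 0), n_in - 1);
    w1(i) = w;
  }
}

// [[Rcpp::export]]
arma::cube cpp_upsample2(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = 2 * H, Wo = 2 * W;
  ivec ri0, ri1, ci0, ci1; vec rw, cw;
  up2_weights(Ho, H, ri0, ri1, rw);
  up2_weights(Wo, W, ci0, ci1, cw);
  cube y(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j) {
      const double* xa = &x(0, ci0(j), c);
      const double* xb = &x(0, ci1(j), c);
      double* yc = &y(0, j, c);
      const double w = cw(j);
      for (int i = 0; i < Ho; ++i) {
        double top = (1 - w) * xa[ri0(i)] + w * xb[ri0(i)];
        double bot = (1 - w) * xa[ri1(i)] + w * xb[ri1(i)];
        yc[i] = (1 - rw(i)) * top + rw(i) * bot;
      }
    }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bwd(const arma::cube& dy, int Hin, int Win) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  ivec ri0, ri1, ci0, ci1; vec rw, cw;
  up2_weights(Ho, Hin, ri0, ri1, rw);
  up2_weights(Wo, Win, ci0, ci1, cw);
  cube dx(Hin, Win, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j) {
      double* xa = &dx(0, ci0(j), c);
      double* xb = &dx(0, ci1(j), c);
      const double* dc = &dy(0, j, c);
      const double w = cw(j);
      for (int i = 0; i < Ho; ++i) {
        const double g = dc[i];
        xa[ri0(i)] += (1 - rw(i)) * (1 - w) * g;
        xb[ri0(i)] += (1 - rw(i)) * w * g;
        xa[ri1(i)] += rw(i) * (1 - w) * g;
        xb[ri1(i)] += rw(i) * w * g;
      }
    }
  return dx;
}
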