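// Dense numeric kernels for the U-Net forward/backward passes and for the
// Gaussian-windowed SSIM maps. Convolutions are im2col + GEMM so the inner
// work runs through BLAS. Tensors are Armadillo cubes laid out (H, W, C),
// matching R arrays with dim c(H, W, C).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Patch layout for a k x k window over Cin channels: column index
// p = ci*k*k + dj*k + di (row offset di fastest), which equals an R array
// with dim c(k, k, Cin, Cout) flattened to a (k*k*Cin) x Cout matrix.
static mat im2col(const cube& x, const int k, const int pad) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  mat M(H * W, k * k * Cin, fill::zeros);
  for (int ci = 0; ci < Cin; ++ci) {
    const mat& s = x.slice(ci);
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int p = ci * k * k + dj * k + di;
        const int oi = di - pad, oj = dj - pad;  // src = dest + offset
        const int i0 = std::max(0, -oi), i1 = std::min(H, H - oi);
        const int j0 = std::max(0, -oj), j1 = std::min(W, W - oj);
        if (i1 <= i0) continue;
        double* dst = M.colptr(p);
        for (int j = j0; j < j1; ++j) {
          const double* src = s.colptr(j + oj) + (i0 + oi);
          std::copy(src, src + (i1 - i0), dst + i0 + j * H);
        }
      }
    }
  }
  return M;
}

// Adjoint of im2col: scatter-add patch columns back onto the image grid.
static cube col2im(const mat& G, const int H, const int W, const int Cin,
                   const int k, const int pad) {
  cube gx(H, W, Cin, fill::zeros);
  for (int ci = 0; ci < Cin; ++ci) {
    mat& s = gx.slice(ci);
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int p = ci * k * k + dj * k + di;
        const int oi = di - pad, oj = dj - pad;
        const int i0 = std::max(0, -oi), i1 = std::min(H, H - oi);
        const int j0 = std::max(0, -oj), j1 = std::min(W, W - oj);
        if (i1 <= i0) continue;
        const double* src = G.colptr(p);
        for (int j = j0; j < j1; ++j) {
          double* dst = s.colptr(j + oj) + (i0 + oi);
          const double* g = src + i0 + j * H;
          for (int i = 0; i < i1 - i0; ++i) dst[i] += g[i];
        }
      }
    }
  }
  return gx;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fw(const arma::cube& x, const arma::mat& W,
                         const arma::vec& b, const int k, const int pad) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int Cout = W.n_cols;
  mat Y = im2col(x, k, pad) * W;
  cube y(H, Wd, Cout);
  for (int co = 0; co < Cout; ++co)
    y.slice(co) = reshape(Y.col(co), H, Wd) + b(co);
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bw(const arma::cube& x, const arma::mat& W,
                         const arma::cube& gy, const int k, const int pad) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = W.n_cols;
  mat G(H * Wd, Cout);
  for (int co = 0; co < Cout; ++co) G.col(co) = vectorise(gy.slice(co));
  mat M = im2col(x, k, pad);
  mat gW = M.t() * G;
  vec gb = sum(G, 0).t();
  cube gx = col2im(G * W.t(), H, Wd, Cin, k, pad);
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// 2x2 max pooling, stride 2. idx stores the argmax offset code di + 2*dj.
// [[Rcpp::export]]
Rcpp::List cpp_maxpool2_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int h = H / 2, w = W / 2;
  cube y(h, w, C);
  ucube idx(h, w, C);
  for (int c = 0; c < C; ++c) {
    const mat& s = x.slice(c);
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        double best = s(2 * i, 2 * j);
        unsigned code = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const double v = s(2 * i + di, 2 * j + dj);
            if (v > best) { best = v; code = di + 2 * dj; }
          }
        y(i, j, c) = best;
        idx(i, j, c) = code;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bw(const arma::ucube& idx, const arma::cube& gy) {
  const int h = gy.n_rows, w = gy.n_cols, C = gy.n_slices;
  cube gx(2 * h, 2 * w, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        const unsigned code = idx(i, j, c);
        gx(2 * i + (code & 1u), 2 * j + (code >> 1), c) += gy(i, j, c);
      }
  return gx;
}

// Transposed convolution, kernel 2x2, stride 2: each input pixel paints a
// 2x2 output block. W is (Cin) x (4*Cout) with column q = co*4 + dj*2 + di.
// [[Rcpp::export]]
arma::cube cpp_upconv2_fw(const arma::cube& x, const arma::mat& W,
                          const arma::vec& b) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = W.n_cols / 4;
  mat X(H * Wd, Cin);
  for (int ci = 0; ci < Cin; ++ci) X.col(ci) = vectorise(x.slice(ci));
  mat Y = X * W;
  cube y(2 * H, 2 * Wd, Cout);
  for (int co = 0; co < Cout; ++co) {
    mat& s = y.slice(co);
    s.fill(b(co));
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        const double* src = Y.colptr(co * 4 + dj * 2 + di);
        for (int j = 0; j < Wd; ++j)
          for (int i = 0; i < H; ++i)
            s(2 * i + di, 2 * j + dj) += src[i + j * H];
      }
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_upconv2_bw(const arma::cube& x, const arma::mat& W,
                          const arma::cube& gy) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = W.n_cols / 4;
  mat X(H * Wd, Cin);
  for (int ci = 0; ci < Cin; ++ci) X.col(ci) = vectorise(x.slice(ci));
  mat G(H * Wd, 4 * Cout);
  vec gb(Cout);
  for (int co = 0; co < Cout; ++co) {
    const mat& s = gy.slice(co);
    gb(co) = accu(s);
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        double* dst = G.colptr(co * 4 + dj * 2 + di);
        for (int j = 0; j < Wd; ++j)
          for (int i = 0; i < H; ++i)
            dst[i + j * H] = s(2 * i + di, 2 * j + dj);
      }
  }
  mat gXm = G * W.t();
  cube gx(H, Wd, Cin);
  for (int ci = 0; ci < Cin; ++ci)
    gx.slice(ci) = reshape(gXm.col(ci), H, Wd);
  mat gW = X.t() * G;
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// Valid-mode cross-correlation with a small kernel (SSIM windowing).
// [[Rcpp::export]]
arma::mat cpp_filter2_valid(const arma::mat& x, const arma::mat& k) {
  const int H = x.n_rows, W = x.n_cols;
  const int kh = k.n_rows, kw = k.n_cols;
  const int h = H - kh + 1, w = W - kw + 1;
  mat y(h, w, fill::zeros);
  for (int dj = 0; dj < kw; ++dj)
    for (int di = 0; di < kh; ++di) {
      const double kv = k(di, dj);
      if (kv == 0.0) continue;
      y += kv * x.submat(di, dj, di + h - 1, dj + w - 1);
    }
  return y;
}

// Adjoint of cpp_filter2_valid: scatter a valid-size map back to full size.
// [[Rcpp::export]]
arma::mat cpp_filter2_valid_adjoint(const arma::mat& g, const arma::mat& k,
                                    const int H, const int W) {
  const int kh = k.n_rows, kw = k.n_cols;
  const int h = g.n_rows, w = g.n_cols;
  mat x(H, W, fill::zeros);
  for (int dj = 0; dj < kw; ++dj)
    for (int di = 0; di < kh; ++di) {
      const double kv = k(di, dj);
      if (kv == 0.0) continue;
      x.submat(di, dj, di + h - 1, dj + w - 1) += kv * g;
    }
  return x;
}
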