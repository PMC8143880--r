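// Low-level numeric kernels for the segmentation networks.
//
// Feature maps are arma::cube (h x w x channels), matching R arrays with
// dim c(h, w, c). Convolution weights are stored as matrices of shape
// (k*k*a) x b with patch-entry index q = c*k*k + di*k + dj, so that
// im2col(x) %*% W is the convolution. All convolutions are stride 1 with
// symmetric zero padding; downsampling is done by 2x2 max pooling and
// upsampling by factor-2 bilinear interpolation or 2x2 stride-2
// transposed convolution.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// im2col via whole-submatrix copies: for each (channel, kernel offset) the
// valid region of the input slice is one rectangular block of the P column
// viewed as an h x w matrix.
static mat im2col(const cube& x, int k, int pad) {
  const int h = x.n_rows, w = x.n_cols, a = x.n_slices;
  mat P(h * (size_t)w, (size_t)k * k * a, fill::zeros);
  for (int c = 0; c < a; ++c) {
    const mat& xc = x.slice(c);
    for (int di = 0; di < k; ++di) {
      const int i0 = std::max(0, pad - di);          // output rows with valid si
      const int i1 = std::min(h - 1, h - 1 + pad - di);
      if (i0 > i1) continue;
      for (int dj = 0; dj < k; ++dj) {
        const int j0 = std::max(0, pad - dj);
        const int j1 = std::min(w - 1, w - 1 + pad - dj);
        if (j0 > j1) continue;
        const int q = c * k * k + di * k + dj;
        mat Pq(P.colptr(q), h, w, false, true);
        Pq.submat(i0, j0, i1, j1) =
          xc.submat(i0 + di - pad, j0 + dj - pad, i1 + di - pad,
                    j1 + dj - pad);
      }
    }
  }
  return P;
}

static cube col2im(const mat& dP, int h, int w, int a, int k, int pad) {
  cube gx(h, w, a, fill::zeros);
  for (int c = 0; c < a; ++c) {
    mat& gc = gx.slice(c);
    for (int di = 0; di < k; ++di) {
      const int i0 = std::max(0, pad - di);
      const int i1 = std::min(h - 1, h - 1 + pad - di);
      if (i0 > i1) continue;
      for (int dj = 0; dj < k; ++dj) {
        const int j0 = std::max(0, pad - dj);
        const int j1 = std::min(w - 1, w - 1 + pad - dj);
        if (j0 > j1) continue;
        const int q = c * k * k + di * k + dj;
        const mat Pq(const_cast<double*>(dP.colptr(q)), h, w, false, true);
        gc.submat(i0 + di - pad, j0 + dj - pad, i1 + di - pad, j1 + dj - pad)
          += Pq.submat(i0, j0, i1, j1);
      }
    }
  }
  return gx;
}

// Optionally applies a fused ReLU to the output.
// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const arma::mat& W,
                          const arma::vec& bias, int k, int pad,
                          bool relu = false) {
  const int h = x.n_rows, w = x.n_cols;
  const int b = W.n_cols;
  mat P = im2col(x, k, pad);
  mat Y = P * W;
  Y.each_row() += bias.t();
  if (relu) Y.clamp(0.0, datum::inf);
  cube out(Y.memptr(), h, w, b);
  return out;
}

// Backward pass. With `relu = true`, `out` must be the (post-ReLU) forward
// output: the incoming gradient is gated by out > 0 before the linear
// backward. `need_gx = false` skips the input-gradient computation (used at
// the network input).
// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& W, int k,
                          int pad, const arma::cube& gout,
                          const arma::cube& out, bool relu = false,
                          bool need_gx = true) {
  const int h = x.n_rows, w = x.n_cols, a = x.n_slices;
  const int b = gout.n_slices;
  cube Gc;
  if (relu) {
    Gc = gout;
    for (int o = 0; o < b; ++o) {
      Gc.slice(o) %= conv_to<mat>::from(out.slice(o) > 0);
    }
  } else {
    Gc = gout;
  }
  // im2col the *gradient* (9b columns, usually the thin side): both the
  // input gradient and the weight gradient then come out of one GEMM each,
  // with a kernel-flip index remapping and no col2im scatter.
  mat Pg = im2col(Gc, k, pad);
  const mat G(Gc.memptr(), (size_t)h * w, b, false);
  vec gb = sum(G, 0).t();
  const mat X(const_cast<double*>(x.memptr()), (size_t)h * w, a, false);
  // gWr[(o,di,dj), c] = gW[(c, k-1-di, k-1-dj), o]
  mat gWr = Pg.t() * X;
  mat gW((size_t)k * k * a, b);
  for (int o = 0; o < b; ++o) {
    for (int di = 0; di < k; ++di) {
      for (int dj = 0; dj < k; ++dj) {
        const int qg = o * k * k + di * k + dj;
        const int e = (k - 1 - di) * k + (k - 1 - dj);
        for (int c = 0; c < a; ++c) {
          gW(c * k * k + e, o) = gWr(qg, c);
        }
      }
    }
  }
  cube gx;
  if (need_gx) {
    // Wt[(o,di,dj), c] = W[(c, k-1-di, k-1-dj), o]
    mat Wt((size_t)k * k * b, a);
    for (int o = 0; o < b; ++o) {
      for (int di = 0; di < k; ++di) {
        for (int dj = 0; dj < k; ++dj) {
          const int qg = o * k * k + di * k + dj;
          const int e = (k - 1 - di) * k + (k - 1 - dj);
          for (int c = 0; c < a; ++c) {
            Wt(qg, c) = W(c * k * k + e, o);
          }
        }
      }
    }
    mat gxm = Pg * Wt;
    gx = cube(gxm.memptr(), h, w, a);
  } else {
    gx = cube(1, 1, 1, fill::zeros);
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// Instance normalisation over spatial dims per channel, with affine
// parameters and optional fused ReLU. Returns the output plus the
// normalised activations and inverse standard deviations for the backward
// pass.
// [[Rcpp::export]]
Rcpp::List cpp_instnorm_fwd(const arma::cube& x, const arma::vec& gamma,
                            const arma::vec& beta, bool relu = false,
                            double eps = 1e-5) {
  const int h = x.n_rows, w = x.n_cols, c = x.n_slices;
  cube out(h, w, c), xhat(h, w, c);
  vec istd(c);
  const size_t n = (size_t)h * w;
  for (int ch = 0; ch < c; ++ch) {
    const double* xp = x.slice_memptr(ch);
    double* hp = xhat.slice_memptr(ch);
    double* op = out.slice_memptr(ch);
    double s1 = 0, s2 = 0;
    for (size_t i = 0; i < n; ++i) { s1 += xp[i]; s2 += xp[i] * xp[i]; }
    const double mu = s1 / n;
    const double var = s2 / n - mu * mu;
    const double is = 1.0 / std::sqrt(std::max(var, 0.0) + eps);
    istd(ch) = is;
    const double g = gamma(ch), b = beta(ch);
    for (size_t i = 0; i < n; ++i) {
      const double xh = (xp[i] - mu) * is;
      hp[i] = xh;
      double y = g * xh + b;
      if (relu && y < 0) y = 0;
      op[i] = y;
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("istd") = istd);
}

// [[Rcpp::export]]
Rcpp::List cpp_instnorm_bwd(const arma::cube& gout, const arma::cube& out,
                            const arma::cube& xhat, const arma::vec& istd,
                            const arma::vec& gamma, bool relu = false) {
  const int h = gout.n_rows, w = gout.n_cols, c = gout.n_slices;
  cube gx(h, w, c);
  vec ggamma(c), gbeta(c);
  const size_t n = (size_t)h * w;
  for (int ch = 0; ch < c; ++ch) {
    const double* gp = gout.slice_memptr(ch);
    const double* op = out.slice_memptr(ch);
    const double* hp = xhat.slice_memptr(ch);
    double* dp = gx.slice_memptr(ch);
    double sg = 0, sgx = 0;
    for (size_t i = 0; i < n; ++i) {
      const double g = (relu && op[i] <= 0) ? 0.0 : gp[i];
      sg += g;
      sgx += g * hp[i];
    }
    ggamma(ch) = sgx;
    gbeta(ch) = sg;
    const double a = gamma(ch) * istd(ch);
    const double mg = sg / n, mgx = sgx / n;
    for (size_t i = 0; i < n; ++i) {
      const double g = (relu && op[i] <= 0) ? 0.0 : gp[i];
      dp[i] = a * (g - mg - hp[i] * mgx);
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("ggamma") = ggamma,
                            Rcpp::Named("gbeta") = gbeta);
}

// Softmax over the channel dimension of an (h, w, C) cube.
// [[Rcpp::export]]
arma::cube cpp_softmax3(const arma::cube& z) {
  const int h = z.n_rows, w = z.n_cols, C = z.n_slices;
  cube p(h, w, C);
  mat m = z.slice(0);
  for (int c = 1; c < C; ++c) m = max(m, z.slice(c));
  mat s(h, w, fill::zeros);
  for (int c = 0; c < C; ++c) {
    p.slice(c) = exp(z.slice(c) - m);
    s += p.slice(c);
  }
  for (int c = 0; c < C; ++c) p.slice(c) /= s;
  return p;
}

// Depthwise k x k convolution: W is (k*k) x c, channel c filtered alone.
// Implemented as k*k shifted-submatrix AXPY operations per channel.
// [[Rcpp::export]]
arma::cube cpp_depthwise_fwd(const arma::cube& x, const arma::mat& W,
                             const arma::vec& bias, int k, int pad,
                             bool relu = false) {
  const int h = x.n_rows, w = x.n_cols, c = x.n_slices;
  cube out(h, w, c);
  for (int ch = 0; ch < c; ++ch) {
    const mat& xc = x.slice(ch);
    mat& oc = out.slice(ch);
    oc.fill(bias(ch));
    for (int di = 0; di < k; ++di) {
      const int i0 = std::max(0, pad - di);
      const int i1 = std::min(h - 1, h - 1 + pad - di);
      if (i0 > i1) continue;
      for (int dj = 0; dj < k; ++dj) {
        const int j0 = std::max(0, pad - dj);
        const int j1 = std::min(w - 1, w - 1 + pad - dj);
        if (j0 > j1) continue;
        oc.submat(i0, j0, i1, j1) +=
          W(di * k + dj, ch) * xc.submat(i0 + di - pad, j0 + dj - pad,
                                         i1 + di - pad, j1 + dj - pad);
      }
    }
    if (relu) oc.clamp(0.0, datum::inf);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_depthwise_bwd(const arma::cube& x, const arma::mat& W, int k,
                             int pad, const arma::cube& gout,
                             const arma::cube& out, bool relu = false) {
  const int h = x.n_rows, w = x.n_cols, c = x.n_slices;
  cube gx(h, w, c, fill::zeros);
  mat gW(W.n_rows, W.n_cols, fill::zeros);
  vec gb(c, fill::zeros);
  for (int ch = 0; ch < c; ++ch) {
    const mat& xc = x.slice(ch);
    const mat gc = relu ? mat(gout.slice(ch) % (out.slice(ch) > 0))
                        : gout.slice(ch);
    mat& gxc = gx.slice(ch);
    gb(ch) = accu(gc);
    for (int di = 0; di < k; ++di) {
      const int i0 = std::max(0, pad - di);
      const int i1 = std::min(h - 1, h - 1 + pad - di);
      if (i0 > i1) continue;
      for (int dj = 0; dj < k; ++dj) {
        const int j0 = std::max(0, pad - dj);
        const int j1 = std::min(w - 1, w - 1 + pad - dj);
        if (j0 > j1) continue;
        const auto gsub = gc.submat(i0, j0, i1, j1);
        const auto xsub = xc.submat(i0 + di - pad, j0 + dj - pad,
                                    i1 + di - pad, j1 + dj - pad);
        gW(di * k + dj, ch) = accu(gsub % xsub);
        gxc.submat(i0 + di - pad, j0 + dj - pad, i1 + di - pad,
                   j1 + dj - pad) += W(di * k + dj, ch) * gsub;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// 2x2 max pooling, stride 2. Stores the flat spatial argmax per output cell.
// [[Rcpp::export]]
Rcpp::List cpp_maxpool2_fwd(const arma::cube& x) {
  const int h = x.n_rows, w = x.n_cols, c = x.n_slices;
  if (h % 2 != 0 || w % 2 != 0)
    Rcpp::stop("max pooling needs even spatial dimensions, got %d x %d", h, w);
  const int h2 = h / 2, w2 = w / 2;
  cube out(h2, w2, c);
  icube idx(h2, w2, c);
  for (int ch = 0; ch < c; ++ch) {
    for (int j = 0; j < w2; ++j) {
      for (int i = 0; i < h2; ++i) {
        double best = -datum::inf;
        int barg = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int si = 2 * i + di, sj = 2 * j + dj;
            const double v = x(si, sj, ch);
            if (v > best) { best = v; barg = si + sj * h; }
          }
        }
        out(i, j, ch) = best;
        idx(i, j, ch) = barg;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::cube& gout, const arma::icube& idx,
                            int h, int w) {
  const int h2 = gout.n_rows, w2 = gout.n_cols, c = gout.n_slices;
  cube gx(h, w, c, fill::zeros);
  for (int ch = 0; ch < c; ++ch) {
    for (int j = 0; j < w2; ++j) {
      for (int i = 0; i < h2; ++i) {
        const int flat = idx(i, j, ch);
        gx(flat % h, flat / h, ch) += gout(i, j, ch);
      }
    }
  }
  return gx;
}

// Factor-2 bilinear upsampling (half-pixel-center convention):
// source coordinate of output index i is (i + 0.5) / 2 - 0.5, clamped.
static void bilinear_axes(int n_out, int n_in, ivec& lo, ivec& hi, vec& wt) {
  lo.set_size(n_out); hi.set_size(n_out); wt.set_size(n_out);
  const double scale = (double)n_in / n_out;
  for (int i = 0; i < n_out; ++i) {
    double s = (i + 0.5) * scale - 0.5;
    if (s < 0) s = 0;
    if (s > n_in - 1) s = n_in - 1;
    const int l = (int)std::floor(s);
    lo(i) = l;
    hi(i) = std::min(l + 1, n_in - 1);
    wt(i) = s - l;
  }
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_fwd(const arma::cube& x) {
  const int h = x.n_rows, w = x.n_cols, c = x.n_slices;
  const int H = 2 * h, W = 2 * w;
  ivec i0, i1, j0, j1; vec wi, wj;
  bilinear_axes(H, h, i0, i1, wi);
  bilinear_axes(W, w, j0, j1, wj);
  cube out(H, W, c);
  for (int ch = 0; ch < c; ++ch) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const double a = (1 - wi(i)) * (1 - wj(j)) * x(i0(i), j0(j), ch)
                       + wi(i) * (1 - wj(j)) * x(i1(i), j0(j), ch)
                       + (1 - wi(i)) * wj(j) * x(i0(i), j1(j), ch)
                       + wi(i) * wj(j) * x(i1(i), j1(j), ch);
        out(i, j, ch) = a;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bwd(const arma::cube& gout, int h, int w) {
  const int H = gout.n_rows, W = gout.n_cols, c = gout.n_slices;
  ivec i0, i1, j0, j1; vec wi, wj;
  bilinear_axes(H, h, i0, i1, wi);
  bilinear_axes(W, w, j0, j1, wj);
  cube gx(h, w, c, fill::zeros);
  for (int ch = 0; ch < c; ++ch) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const double g = gout(i, j, ch);
        gx(i0(i), j0(j), ch) += (1 - wi(i)) * (1 - wj(j)) * g;
        gx(i1(i), j0(j), ch) += wi(i) * (1 - wj(j)) * g;
        gx(i0(i), j1(j), ch) += (1 - wi(i)) * wj(j) * g;
        gx(i1(i), j1(j), ch) += wi(i) * wj(j) * g;
      }
    }
  }
  return gx;
}

// Transposed convolution, 2x2 kernel, stride 2 (doubles the spatial size).
// W is a x (4*b) with column index o*4 + di*2 + dj.
// [[Rcpp::export]]
arma::cube cpp_tconv2_fwd(const arma::cube& x, const arma::mat& W,
                          const arma::vec& bias) {
  const int h = x.n_rows, w = x.n_cols, a = x.n_slices;
  const int b = W.n_cols / 4;
  mat X(const_cast<double*>(x.memptr()), (size_t)h * w, a, false);
  mat Y = X * W;  // hw x 4b
  cube out(2 * h, 2 * w, b);
  for (int o = 0; o < b; ++o) {
    for (int dj = 0; dj < 2; ++dj) {
      for (int di = 0; di < 2; ++di) {
        const int q = o * 4 + di * 2 + dj;
        for (int j = 0; j < w; ++j)
          for (int i = 0; i < h; ++i)
            out(2 * i + di, 2 * j + dj, o) = Y(i + (size_t)j * h, q) + bias(o);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_tconv2_bwd(const arma::cube& x, const arma::mat& W,
                          const arma::cube& gout) {
  const int h = x.n_rows, w = x.n_cols, a = x.n_slices;
  const int b = W.n_cols / 4;
  mat X(const_cast<double*>(x.memptr()), (size_t)h * w, a, false);
  mat G((size_t)h * w, 4 * b);
  vec gb(b, fill::zeros);
  for (int o = 0; o < b; ++o) {
    double s = 0;
    for (int dj = 0; dj < 2; ++dj) {
      for (int di = 0; di < 2; ++di) {
        const int q = o * 4 + di * 2 + dj;
        for (int j = 0; j < w; ++j)
          for (int i = 0; i < h; ++i) {
            const double g = gout(2 * i + di, 2 * j + dj, o);
            G(i + (size_t)j * h, q) = g;
            s += g;
          }
      }
    }
    gb(o) = s;
  }
  mat gW = X.t() * G;
  mat gX = G * W.t();
  cube gx(gX.memptr(), h, w, a);
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// General bilinear / nearest resize of a single-channel image.
// [[Rcpp::export]]
arma::mat cpp_resize(const arma::mat& img, int H, int W, bool nearest) {
  const int h = img.n_rows, w = img.n_cols;
  mat out(H, W);
  const double sr = (double)h / H, sc = (double)w / W;
  for (int j = 0; j < W; ++j) {
    double cs = (j + 0.5) * sc - 0.5;
    for (int i = 0; i < H; ++i) {
      double rs = (i + 0.5) * sr - 0.5;
      if (nearest) {
        int ri = (int)std::round(rs), cj = (int)std::round(cs);
        ri = std::min(std::max(ri, 0), h - 1);
        cj = std::min(std::max(cj, 0), w - 1);
        out(i, j) = img(ri, cj);
      } else {
        double r = std::min(std::max(rs, 0.0), (double)(h - 1));
        double c = std::min(std::max(cs, 0.0), (double)(w - 1));
        const int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
        const int r1 = std::min(r0 + 1, h - 1), c1 = std::min(c0 + 1, w - 1);
        const double fr = r - r0, fc = c - c0;
        out(i, j) = (1 - fr) * (1 - fc) * img(r0, c0)
                  + fr * (1 - fc) * img(r1, c0)
                  + (1 - fr) * fc * img(r0, c1)
                  + fr * fc * img(r1, c1);
      }
    }
  }
  return out;
}

// Inverse-mapped affine warp about the image centre.
// Minv is the 2x2 inverse transform acting on (row, col) offsets; shift is
// an extra (row, col) translation applied in output space.
// [[Rcpp::export]]
arma::mat cpp_warp_affine(const arma::mat& img, const arma::mat& Minv,
                          const arma::vec& shift, double fill, bool nearest) {
  const int h = img.n_rows, w = img.n_cols;
  const double cr = (h - 1) / 2.0, cc = (w - 1) / 2.0;
  mat out(h, w);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      const double dr = i - cr - shift(0), dc = j - cc - shift(1);
      const double rs = Minv(0, 0) * dr + Minv(0, 1) * dc + cr;
      const double cs = Minv(1, 0) * dr + Minv(1, 1) * dc + cc;
      if (rs < -0.5 || rs > h - 0.5 || cs < -0.5 || cs > w - 0.5) {
        out(i, j) = fill;
        continue;
      }
      if (nearest) {
        int ri = (int)std::round(rs), cj = (int)std::round(cs);
        ri = std::min(std::max(ri, 0), h - 1);
        cj = std::min(std::max(cj, 0), w - 1);
        out(i, j) = img(ri, cj);
      } else {
        const double r = std::min(std::max(rs, 0.0), (double)(h - 1));
        const double c = std::min(std::max(cs, 0.0), (double)(w - 1));
        const int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
        const int r1 = std::min(r0 + 1, h - 1), c1 = std::min(c0 + 1, w - 1);
        const double fr = r - r0, fc = c - c0;
        out(i, j) = (1 - fr) * (1 - fc) * img(r0, c0)
                  + fr * (1 - fc) * img(r1, c0)
                  + (1 - fr) * fc * img(r0, c1)
                  + fr * fc * img(r1, c1);
      }
    }
  }
  return out;
}
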