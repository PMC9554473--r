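// Minimal dense 2-D convolution and max-pooling kernels (forward + backward)
// used by the R-level network engine.  Tensor layout everywhere is the R
// array convention: activations H x W x C x N, weights kh x kw x Cin x Cout,
// all column-major doubles.  Convolutions are computed per image by im2col
// followed by a single BLAS matrix product.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// Fill the (P x K) patch matrix for one image. P = Ho*Wo (ho fastest),
// K = kh*kw*Cin ordered (ki, kj, ci) to match the R weight layout.
// valid output range [lo, hi) for one kernel tap along a dimension
static inline void tap_range(int n_in, int n_out, int k, int stride, int pad,
                             int& lo, int& hi) {
  // input index i = o*stride - pad + k must satisfy 0 <= i < n_in
  lo = (pad - k + stride - 1) / stride;
  if (lo < 0) lo = 0;
  hi = (n_in - 1 - k + pad) / stride + 1;
  if (hi > n_out) hi = n_out;
  if (hi < lo) hi = lo;
}

static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& Mt) {
  int k = 0;
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + (size_t)ci * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      int wlo, whi;
      tap_range(W, Wo, kj, stride, pad, wlo, whi);
      for (int ki = 0; ki < kh; ++ki, ++k) {
        int hlo, hhi;
        tap_range(H, Ho, ki, stride, pad, hlo, hhi);
        double* col = Mt.colptr(k);
        if (wlo > 0) std::fill(col, col + (size_t)wlo * Ho, 0.0);
        if (whi < Wo) {
          std::fill(col + (size_t)whi * Ho, col + (size_t)Wo * Ho, 0.0);
        }
        for (int wo = wlo; wo < whi; ++wo) {
          const int wi = wo * stride - pad + kj;
          double* dst = col + (size_t)wo * Ho;
          const double* src = xc + (size_t)wi * H - pad + ki;
          if (hlo > 0) std::fill(dst, dst + hlo, 0.0);
          if (hhi < Ho) std::fill(dst + hhi, dst + Ho, 0.0);
          if (stride == 1) {
            memcpy(dst + hlo, src + hlo, (size_t)(hhi - hlo) * sizeof(double));
          } else {
            for (int ho = hlo; ho < hhi; ++ho) dst[ho] = src[ho * stride];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv2d_forward")]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 Nullable<NumericVector> bias,
                                 int stride, int pad) {
  int dx[4], dw[4];
  get_dims4(x, dx); get_dims4(w, dw);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Cin = dw[2], Cout = dw[3];
  if (Cin != C) stop("channel mismatch between input and kernel");
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("kernel larger than padded input");
  const int K = kh * kw * Cin, P = Ho * Wo;

  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector out((size_t)P * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  const bool pointwise = (kh == 1 && kw == 1 && stride == 1 && pad == 0);
  arma::mat Mt;
  if (!pointwise) Mt.set_size(P, K);
  arma::rowvec b;
  const bool has_b = bias.isNotNull();
  if (has_b) {
    NumericVector bv(bias);
    b = arma::rowvec(bv.begin(), Cout);
  }
  for (int n = 0; n < N; ++n) {
    double* xn = const_cast<double*>(x.begin()) + (size_t)n * H * W * C;
    arma::mat Yt(out.begin() + (size_t)n * P * Cout, P, Cout, false, true);
    if (pointwise) {
      arma::mat X(xn, P, C, false, true);   // 1x1 conv is a plain GEMM
      Yt = X * Wm;
    } else {
      im2col(xn, H, W, C, kh, kw, stride, pad, Ho, Wo, Mt);
      Yt = Mt * Wm;
    }
    if (has_b) Yt.each_row() += b;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_conv2d_backward")]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                         int stride, int pad, bool has_bias,
                         bool compute_dx = true) {
  int dx4[4], dw4[4], dy4[4];
  get_dims4(x, dx4); get_dims4(w, dw4); get_dims4(dy, dy4);
  const int H = dx4[0], W = dx4[1], C = dx4[2], N = dx4[3];
  const int kh = dw4[0], kw = dw4[1], Cout = dw4[3];
  const int Ho = dy4[0], Wo = dy4[1];
  const int K = kh * kw * C, P = Ho * Wo;

  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector dxv((size_t)H * W * C * N);
  dxv.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dwv((size_t)K * Cout);
  dwv.attr("dim") = IntegerVector::create(kh, kw, C, Cout);
  arma::mat dWm(dwv.begin(), K, Cout, false, true);
  arma::rowvec db(Cout, arma::fill::zeros);

  const bool pointwise = (kh == 1 && kw == 1 && stride == 1 && pad == 0);
  arma::mat Mt;
  if (!pointwise) Mt.set_size(P, K);
  for (int n = 0; n < N; ++n) {
    double* xn = const_cast<double*>(x.begin()) + (size_t)n * H * W * C;
    arma::mat dYt(const_cast<double*>(dy.begin()) + (size_t)n * P * Cout,
                  P, Cout, false, true);
    if (has_bias) db += arma::sum(dYt, 0);
    double* dxn = dxv.begin() + (size_t)n * H * W * C;
    if (pointwise) {
      arma::mat X(xn, P, C, false, true);
      dWm += X.t() * dYt;
      if (compute_dx) {
        arma::mat dX(dxn, P, C, false, true);
        dX = dYt * Wm.t();
      }
      continue;
    }
    im2col(xn, H, W, C, kh, kw, stride, pad, Ho, Wo, Mt);
    dWm += Mt.t() * dYt;
    if (!compute_dx) continue;
    arma::mat dMt = dYt * Wm.t();  // P x K
    int k = 0;
    for (int ci = 0; ci < C; ++ci) {
      double* dxc = dxn + (size_t)ci * H * W;
      for (int kj = 0; kj < kw; ++kj) {
        int wlo, whi;
        tap_range(W, Wo, kj, stride, pad, wlo, whi);
        for (int ki = 0; ki < kh; ++ki, ++k) {
          int hlo, hhi;
          tap_range(H, Ho, ki, stride, pad, hlo, hhi);
          const double* col = dMt.colptr(k);
          for (int wo = wlo; wo < whi; ++wo) {
            const int wi = wo * stride - pad + kj;
            double* dst = dxc + (size_t)wi * H - pad + ki;
            const double* src = col + (size_t)wo * Ho;
            if (stride == 1) {
              for (int ho = hlo; ho < hhi; ++ho) dst[ho] += src[ho];
            } else {
              for (int ho = hlo; ho < hhi; ++ho) dst[ho * stride] += src[ho];
            }
          }
        }
      }
    }
  }
  List res = List::create(_["dx"] = dxv, _["dw"] = dwv);
  if (has_bias) res["db"] = NumericVector(db.begin(), db.end());
  return res;
}

// [[Rcpp::export(name = ".cpp_maxpool_forward")]]
List cpp_maxpool_forward(NumericVector x, int k, int stride, int pad) {
  int d[4];
  get_dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector out((size_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((size_t)Ho * Wo * C * N);  // 0-based index into image
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    for (int ci = 0; ci < C; ++ci) {
      const double* xc = xn + (size_t)ci * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho, ++o) {
          double best = -HUGE_VAL; int bi = -1;
          for (int kj = 0; kj < k; ++kj) {
            const int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              const double v = xc[(size_t)wi * H + hi];
              if (v > best) { best = v; bi = hi + H * wi + H * W * ci; }
            }
          }
          out[o] = best;
          idx[o] = bi;
        }
      }
    }
  }
  return List::create(_["y"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool_backward")]]
NumericVector cpp_maxpool_backward(NumericVector dy, IntegerVector idx,
                                   IntegerVector in_dim) {
  const int H = in_dim[0], W = in_dim[1], C = in_dim[2], N = in_dim[3];
  int d[4];
  get_dims4(dy, d);
  const size_t per_out = (size_t)d[0] * d[1] * d[2];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    const size_t oo = (size_t)n * per_out;
    double* dxn = dx.begin() + (size_t)n * H * W * C;
    for (size_t o = 0; o < per_out; ++o) {
      const int bi = idx[oo + o];
      if (bi >= 0) dxn[bi] += dy[oo + o];
    }
  }
  return dx;
}

// ---- fused elementwise helpers (hot paths of batch norm / SiLU) -----------

// per-channel sums and sums of squares of an H x W x C x N array
// [[Rcpp::export(name = ".cpp_channel_stats")]]
List cpp_channel_stats(NumericVector x) {
  int d[4];
  get_dims4(x, d);
  const size_t HW = (size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector s(C), s2(C);
  const double* p = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double a = 0, b = 0;
      for (size_t i = 0; i < HW; ++i, ++p) { a += *p; b += *p * *p; }
      s[c] += a; s2[c] += b;
    }
  }
  return List::create(_["sum"] = s, _["sumsq"] = s2);
}

// y = x * a[c] + b[c]; optionally also return xhat = x * a2[c] + b2[c]
// [[Rcpp::export(name = ".cpp_scale_shift")]]
NumericVector cpp_scale_shift(NumericVector x, NumericVector a,
                              NumericVector b) {
  int d[4];
  get_dims4(x, d);
  const size_t HW = (size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* p = x.begin();
  double* q = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double ac = a[c], bc = b[c];
      for (size_t i = 0; i < HW; ++i) *q++ = *p++ * ac + bc;
    }
  }
  return y;
}

// dx = istd[c] * (dxhat - s1[c] - xhat * s2[c])
// [[Rcpp::export(name = ".cpp_bn_backward_dx")]]
NumericVector cpp_bn_backward_dx(NumericVector dxhat, NumericVector xhat,
                                 NumericVector s1, NumericVector s2,
                                 NumericVector istd) {
  int d[4];
  get_dims4(dxhat, d);
  const size_t HW = (size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector dx(dxhat.size());
  dx.attr("dim") = dxhat.attr("dim");
  const double* pd = dxhat.begin();
  const double* px = xhat.begin();
  double* q = dx.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double i_c = istd[c], s1c = s1[c], s2c = s2[c];
      for (size_t i = 0; i < HW; ++i) {
        *q++ = i_c * (*pd++ - s1c - *px++ * s2c);
      }
    }
  }
  return dx;
}

// [[Rcpp::export(name = ".cpp_silu_forward")]]
NumericVector cpp_silu_forward(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double v = x[i];
    y[i] = v / (1.0 + std::exp(-v));
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_silu_backward")]]
NumericVector cpp_silu_backward(NumericVector dy, NumericVector x) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  for (R_xlen_t i = 0; i < dy.size(); ++i) {
    const double s = 1.0 / (1.0 + std::exp(-x[i]));
    dx[i] = dy[i] * s * (1.0 + x[i] * (1.0 - s));
  }
  return dx;
}
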