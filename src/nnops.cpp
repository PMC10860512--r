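// Layer kernels for the 2D segmentation network.
// Layout convention (column-major, matching R arrays):
//   activations: (H, W, C, N);  weights: (k, k, Cin, Cout); stride is always 1.
// Convolution uses a transposed im2col (patch matrix HW x k*k*Cin, filled
// with contiguous column copies) followed by one GEMM per image; 1x1
// convolutions skip im2col and multiply channel matrices in place.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fill M (HW x k*k*Cin) with patches of one image (H,W,Cin).
static void im2col_t(const double* x, int H, int W, int Cin, int k, int pad,
                     arma::mat& M) {
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        double* col = M.colptr(ki + k * kj + k * k * c);
        int di = ki - pad, dj = kj - pad;
        int i0 = std::max(0, -di), i1 = std::min(H, H - di); // valid out rows
        for (int j = 0; j < W; ++j) {
          double* dst = col + (size_t)H * j;
          int jj = j + dj;
          if (jj < 0 || jj >= W) { std::fill(dst, dst + H, 0.0); continue; }
          const double* src = xc + (size_t)H * jj + di;
          if (i0 > 0) std::fill(dst, dst + i0, 0.0);
          if (i1 > i0) std::copy(src + i0, src + i1, dst + i0);
          if (i1 < H) std::fill(dst + i1, dst + H, 0.0);
        }
      }
    }
  }
}

// Scatter-add columns of GM (HW x k*k*Cin) back into one image gradient.
static void col2im_t(const arma::mat& GM, int H, int W, int Cin, int k,
                     int pad, double* gx) {
  for (int c = 0; c < Cin; ++c) {
    double* gc = gx + (size_t)H * W * c;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const double* col = GM.colptr(ki + k * kj + k * k * c);
        int di = ki - pad, dj = kj - pad;
        int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        for (int j = 0; j < W; ++j) {
          int jj = j + dj;
          if (jj < 0 || jj >= W) continue;
          const double* src = col + (size_t)H * j;
          double* dst = gc + (size_t)H * jj + di;
          for (int i = i0; i < i1; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

static IntegerVector dim4(SEXP a) {
  IntegerVector d = Rf_getAttrib(a, R_DimSymbol);
  return d;
}

// [[Rcpp::export]]
NumericVector nn_conv2d(NumericVector x, NumericVector w, NumericVector b,
                        int pad) {
  IntegerVector xd = dim4(x), wd = dim4(w);
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  if (wd[1] != k || wd[2] != Cin) stop("weight/input channel mismatch");
  size_t HW = (size_t)H * W;
  NumericVector y(HW * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat wm(const_cast<double*>(w.begin()), (size_t)k * k * Cin, Cout,
               false, true);
  arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);
  if (k == 1) {
    for (int n = 0; n < N; ++n) {
      arma::mat X(const_cast<double*>(x.begin()) + HW * Cin * n, HW, Cin,
                  false, true);
      arma::mat Y(y.begin() + HW * Cout * n, HW, Cout, false, true);
      Y = X * wm;
      Y.each_row() += bv;
    }
    return y;
  }
  arma::mat M(HW, (size_t)k * k * Cin);
  for (int n = 0; n < N; ++n) {
    im2col_t(x.begin() + HW * Cin * n, H, W, Cin, k, pad, M);
    arma::mat Y(y.begin() + HW * Cout * n, HW, Cout, false, true);
    Y = M * wm;
    Y.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List nn_conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
                  int pad) {
  IntegerVector xd = dim4(x), wd = dim4(w);
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  size_t HW = (size_t)H * W;
  NumericVector gx(HW * Cin * N);
  gx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  NumericVector gw((size_t)k * k * Cin * Cout);
  gw.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  NumericVector gb(Cout);
  arma::mat wm(const_cast<double*>(w.begin()), (size_t)k * k * Cin, Cout,
               false, true);
  arma::mat gwm(gw.begin(), (size_t)k * k * Cin, Cout, false, true);
  arma::rowvec gbv(gb.begin(), Cout, false, true);
  if (k == 1) {
    for (int n = 0; n < N; ++n) {
      arma::mat X(const_cast<double*>(x.begin()) + HW * Cin * n, HW, Cin,
                  false, true);
      arma::mat GY(const_cast<double*>(gy.begin()) + HW * Cout * n, HW, Cout,
                   false, true);
      arma::mat GX(gx.begin() + HW * Cin * n, HW, Cin, false, true);
      gwm += X.t() * GY;
      gbv += arma::sum(GY, 0);
      GX = GY * wm.t();
    }
    return List::create(Named("gx") = gx, Named("gw") = gw, Named("gb") = gb);
  }
  arma::mat M(HW, (size_t)k * k * Cin);
  for (int n = 0; n < N; ++n) {
    im2col_t(x.begin() + HW * Cin * n, H, W, Cin, k, pad, M);
    arma::mat GY(const_cast<double*>(gy.begin()) + HW * Cout * n, HW, Cout,
                 false, true);
    gwm += M.t() * GY;
    gbv += arma::sum(GY, 0);
    arma::mat GM = GY * wm.t();   // HW x k*k*Cin
    col2im_t(GM, H, W, Cin, k, pad, gx.begin() + HW * Cin * n);
  }
  return List::create(Named("gx") = gx, Named("gw") = gw, Named("gb") = gb);
}

// ---- batch normalization -------------------------------------------------

// Per-channel sums over (H, W, N) of a and (optionally) a*b.
// [[Rcpp::export]]
List nn_ch_stats(NumericVector a, Nullable<NumericVector> b) {
  IntegerVector d = dim4(a);
  size_t HW = (size_t)d[0] * d[1];
  int C = d[2], N = d[3];
  NumericVector s1(C), s2(C);
  bool dot = b.isNotNull();
  NumericVector bb;
  if (dot) bb = b.get();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* pa = a.begin() + HW * (c + (size_t)C * n);
      double acc1 = 0, acc2 = 0;
      if (dot) {
        const double* pb = bb.begin() + HW * (c + (size_t)C * n);
        for (size_t i = 0; i < HW; ++i) { acc1 += pa[i]; acc2 += pa[i] * pb[i]; }
      } else {
        for (size_t i = 0; i < HW; ++i) { acc1 += pa[i]; acc2 += pa[i] * pa[i]; }
      }
      s1[c] += acc1; s2[c] += acc2;
    }
  return List::create(Named("s1") = s1, Named("s2") = s2);
}

// y = (x - mu[c]) * inv[c] * gamma[c] + beta[c]
// [[Rcpp::export]]
NumericVector nn_bn_apply(NumericVector x, NumericVector mu, NumericVector inv,
                          NumericVector gamma, NumericVector beta) {
  IntegerVector d = dim4(x);
  size_t HW = (size_t)d[0] * d[1];
  int C = d[2], N = d[3];
  NumericVector y(x.size());
  y.attr("dim") = d;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* px = x.begin() + HW * (c + (size_t)C * n);
      double* py = y.begin() + HW * (c + (size_t)C * n);
      double a = inv[c] * gamma[c], b0 = beta[c] - mu[c] * a;
      for (size_t i = 0; i < HW; ++i) py[i] = px[i] * a + b0;
    }
  return y;
}

// Backward of batch normalization (training statistics).
// [[Rcpp::export]]
List nn_bn_bw(NumericVector x, NumericVector mu, NumericVector inv,
              NumericVector gamma, NumericVector gy) {
  IntegerVector d = dim4(x);
  size_t HW = (size_t)d[0] * d[1];
  int C = d[2], N = d[3];
  double m = (double)HW * N;
  NumericVector gx(x.size()); gx.attr("dim") = d;
  NumericVector ggamma(C), gbeta(C), sg(C), sgx(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* px = x.begin() + HW * (c + (size_t)C * n);
      const double* pg = gy.begin() + HW * (c + (size_t)C * n);
      double a1 = 0, a2 = 0;
      for (size_t i = 0; i < HW; ++i) {
        a1 += pg[i];
        a2 += pg[i] * (px[i] - mu[c]);
      }
      sg[c] += a1; sgx[c] += a2 * inv[c];
    }
  for (int c = 0; c < C; ++c) { gbeta[c] = sg[c]; ggamma[c] = sgx[c]; }
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* px = x.begin() + HW * (c + (size_t)C * n);
      const double* pg = gy.begin() + HW * (c + (size_t)C * n);
      double* pgx = gx.begin() + HW * (c + (size_t)C * n);
      double gi = gamma[c] * inv[c];
      for (size_t i = 0; i < HW; ++i) {
        double xhat = (px[i] - mu[c]) * inv[c];
        pgx[i] = gi * (pg[i] - (sg[c] + xhat * sgx[c]) / m);
      }
    }
  return List::create(Named("gx") = gx, Named("ggamma") = ggamma,
                      Named("gbeta") = gbeta);
}

// ---- activations ---------------------------------------------------------

// [[Rcpp::export]]
NumericVector nn_lrelu(NumericVector x, double alpha) {
  NumericVector y(x.size()); y.attr("dim") = x.attr("dim");
  const double* px = x.begin(); double* py = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i)
    py[i] = px[i] > 0 ? px[i] : alpha * px[i];
  return y;
}

// [[Rcpp::export]]
NumericVector nn_lrelu_bw(NumericVector x, double alpha, NumericVector gy) {
  NumericVector gx(x.size()); gx.attr("dim") = x.attr("dim");
  const double* px = x.begin(); const double* pg = gy.begin();
  double* pd = gx.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i)
    pd[i] = px[i] > 0 ? pg[i] : alpha * pg[i];
  return gx;
}

// ---- 2x2 max pooling and nearest-neighbour upsampling --------------------

// [[Rcpp::export]]
List nn_maxpool2(NumericVector x) {
  IntegerVector d = dim4(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int h = H / 2, w = W / 2;
  size_t on = (size_t)h * w * C * N;
  NumericVector y(on);
  y.attr("dim") = IntegerVector::create(h, w, C, N);
  IntegerVector idx(on);
  const double* px = x.begin();
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xp = px + (size_t)H * W * cn;
    double* yp = y.begin() + (size_t)h * w * cn;
    int* ip = idx.begin() + (size_t)h * w * cn;
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        int i0 = 2 * i, j0 = 2 * j;
        int best = i0 + H * j0;
        double bv = xp[best];
        int cand[3] = { i0 + 1 + H * j0, i0 + H * (j0 + 1), i0 + 1 + H * (j0 + 1) };
        for (int q = 0; q < 3; ++q)
          if (xp[cand[q]] > bv) { bv = xp[cand[q]]; best = cand[q]; }
        yp[i + (size_t)h * j] = bv;
        ip[i + (size_t)h * j] = best;
      }
  }
  return List::create(Named("y") = y, Named("idx") = idx);
}

// [[Rcpp::export]]
NumericVector nn_maxpool2_bw(IntegerVector idx, NumericVector gy,
                             IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int h = H / 2, w = W / 2;
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xdim;
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    double* gp = gx.begin() + (size_t)H * W * cn;
    const double* gyp = gy.begin() + (size_t)h * w * cn;
    const int* ip = idx.begin() + (size_t)h * w * cn;
    for (size_t q = 0; q < (size_t)h * w; ++q) gp[ip[q]] += gyp[q];
  }
  return gx;
}

// [[Rcpp::export]]
NumericVector nn_upsample2(NumericVector x) {
  IntegerVector d = dim4(x);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int H2 = 2 * H, W2 = 2 * W;
  NumericVector y((size_t)H2 * W2 * C * N);
  y.attr("dim") = IntegerVector::create(H2, W2, C, N);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xp = x.begin() + (size_t)H * W * cn;
    double* yp = y.begin() + (size_t)H2 * W2 * cn;
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double v = xp[i + (size_t)H * j];
        size_t o = 2 * i + (size_t)H2 * 2 * j;
        yp[o] = v; yp[o + 1] = v;
        yp[o + H2] = v; yp[o + H2 + 1] = v;
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector nn_upsample2_bw(NumericVector gy) {
  IntegerVector d = dim4(gy);
  int H2 = d[0], W2 = d[1], C = d[2], N = d[3];
  int H = H2 / 2, W = W2 / 2;
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* gp = gy.begin() + (size_t)H2 * W2 * cn;
    double* xp = gx.begin() + (size_t)H * W * cn;
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        size_t o = 2 * i + (size_t)H2 * 2 * j;
        xp[i + (size_t)H * j] = gp[o] + gp[o + 1] + gp[o + H2] + gp[o + H2 + 1];
      }
  }
  return gx;
}
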