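// Low-level convolution kernels for the autodiff engine.
//
// Tensors are R arrays with dim = c(N, C, H, W), column-major, so the
// linear index of element (n, c, h, w) (0-based) is
//   n + N * (c + C * (h + H * w)).
// The batch index varies fastest in memory; the patch ("im2col") matrix is
// therefore laid out with rows indexed by (n, oh, ow) and columns by
// (ci, kh, kw), which makes every inner copy loop a contiguous run over n.
// One GEMM per channel group covers the whole batch.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int* d) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a rank-4 array");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// Patch matrix for one channel group, whole batch:
// colT is (N*Ho*Wo) x (Cg*k*k); row index = n + N*(oh + Ho*ow),
// column index = ci + Cg*(kh + k*kw).
static void im2col_batch(const double* x, int N, int C, int H, int W,
                         int c0, int Cg, int k, int stride, int pad,
                         int Ho, int Wo, arma::mat& colT) {
  colT.zeros();
  for (int kw = 0; kw < k; ++kw) {
    for (int kh = 0; kh < k; ++kh) {
      for (int ci = 0; ci < Cg; ++ci) {
        const int col = ci + Cg * (kh + k * kw);
        double* dst0 = colT.colptr(col);
        const int c = c0 + ci;
        for (int ow = 0; ow < Wo; ++ow) {
          const int w = ow * stride - pad + kw;
          if (w < 0 || w >= W) continue;
          for (int oh = 0; oh < Ho; ++oh) {
            const int h = oh * stride - pad + kh;
            if (h < 0 || h >= H) continue;
            const double* src =
              x + (size_t)N * (c + (size_t)C * (h + (size_t)H * w));
            double* dst = dst0 + (size_t)N * (oh + (size_t)Ho * ow);
            std::memcpy(dst, src, N * sizeof(double));
          }
        }
      }
    }
  }
}

// Scatter-add of a patch-gradient matrix back onto the input gradient.
static void col2im_batch(double* gx, int N, int C, int H, int W,
                         int c0, int Cg, int k, int stride, int pad,
                         int Ho, int Wo, const arma::mat& colT) {
  for (int kw = 0; kw < k; ++kw) {
    for (int kh = 0; kh < k; ++kh) {
      for (int ci = 0; ci < Cg; ++ci) {
        const int col = ci + Cg * (kh + k * kw);
        const double* src0 = colT.colptr(col);
        const int c = c0 + ci;
        for (int ow = 0; ow < Wo; ++ow) {
          const int w = ow * stride - pad + kw;
          if (w < 0 || w >= W) continue;
          for (int oh = 0; oh < Ho; ++oh) {
            const int h = oh * stride - pad + kh;
            if (h < 0 || h >= H) continue;
            double* dst =
              gx + (size_t)N * (c + (size_t)C * (h + (size_t)H * w));
            const double* src = src0 + (size_t)N * (oh + (size_t)Ho * ow);
            for (int n = 0; n < N; ++n) dst[n] += src[n];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = "cpp_conv2d_fw")]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad, int groups) {
  int dx[4], dw[4];
  get_dims4(x, dx); get_dims4(w, dw);
  const int N = dx[0], C = dx[1], H = dx[2], W = dx[3];
  const int Co = dw[0], Cg = dw[1], k = dw[2];
  if (dw[3] != k) stop("only square kernels are supported");
  if (C != Cg * groups) stop("input channels do not match weight/groups");
  if (Co % groups != 0) stop("output channels not divisible by groups");
  const int Cog = Co / groups;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("output spatial size would be empty");

  NumericVector y((size_t)N * Co * Ho * Wo);
  y.attr("dim") = IntegerVector::create(N, Co, Ho, Wo);
  double* yp = y.begin();
  const double* xp = x.begin();
  const bool has_b = b.size() > 0;
  if (has_b && b.size() != Co) stop("bias length must equal output channels");

  // weights as a (Co) x (Cg*k*k) matrix view (column index ci + Cg*(kh+k*kw))
  arma::mat Wmat(const_cast<double*>(w.begin()), Co, (size_t)Cg * k * k,
                 false, true);
  const size_t P = (size_t)N * Ho * Wo;
  arma::mat colT(P, (size_t)Cg * k * k);
  for (int g = 0; g < groups; ++g) {
    im2col_batch(xp, N, C, H, W, g * Cg, Cg, k, stride, pad, Ho, Wo, colT);
    arma::mat Y = colT * Wmat.rows(g * Cog, (g + 1) * Cog - 1).t(); // P x Cog
    for (int r = 0; r < Cog; ++r) {
      const int co = g * Cog + r;
      const double* src = Y.colptr(r);
      const double bb = has_b ? b[co] : 0.0;
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh) {
          const double* s = src + (size_t)N * (oh + (size_t)Ho * ow);
          double* d = yp + (size_t)N * (co + (size_t)Co * (oh + (size_t)Ho * ow));
          for (int n = 0; n < N; ++n) d[n] = s[n] + bb;
        }
    }
  }
  return y;
}

// [[Rcpp::export(name = "cpp_conv2d_bw")]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
                   int stride, int pad, int groups, bool has_bias) {
  int dx[4], dw[4], dg[4];
  get_dims4(x, dx); get_dims4(w, dw); get_dims4(gy, dg);
  const int N = dx[0], C = dx[1], H = dx[2], W = dx[3];
  const int Co = dw[0], Cg = dw[1], k = dw[2];
  const int Ho = dg[2], Wo = dg[3];
  const int Cog = Co / groups;

  NumericVector gx((size_t)N * C * H * W);
  gx.attr("dim") = IntegerVector::create(N, C, H, W);
  NumericVector gw((size_t)Co * Cg * k * k);
  gw.attr("dim") = IntegerVector::create(Co, Cg, k, k);
  NumericVector gb(has_bias ? Co : 0);

  const double* xp = x.begin();
  const double* gp = gy.begin();
  double* gxp = gx.begin();

  arma::mat Wmat(const_cast<double*>(w.begin()), Co, (size_t)Cg * k * k,
                 false, true);
  arma::mat GWmat(gw.begin(), Co, (size_t)Cg * k * k, false, true);
  const size_t P = (size_t)N * Ho * Wo;
  arma::mat colT(P, (size_t)Cg * k * k);
  arma::mat G(P, Cog);

  for (int g = 0; g < groups; ++g) {
    for (int r = 0; r < Cog; ++r) {
      const int co = g * Cog + r;
      double* dst = G.colptr(r);
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh)
          std::memcpy(dst + (size_t)N * (oh + (size_t)Ho * ow),
                      gp + (size_t)N * (co + (size_t)Co * (oh + (size_t)Ho * ow)),
                      N * sizeof(double));
    }
    im2col_batch(xp, N, C, H, W, g * Cg, Cg, k, stride, pad, Ho, Wo, colT);
    GWmat.rows(g * Cog, (g + 1) * Cog - 1) += G.t() * colT;
    arma::mat colTg = G * Wmat.rows(g * Cog, (g + 1) * Cog - 1); // P x Cg*k*k
    col2im_batch(gxp, N, C, H, W, g * Cg, Cg, k, stride, pad, Ho, Wo, colTg);
    if (has_bias) {
      arma::rowvec cs = arma::sum(G, 0);
      for (int r = 0; r < Cog; ++r) gb[g * Cog + r] += cs(r);
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Channel layer normalization. For fixed (h, w) the N x C sample-by-channel
// block is contiguous in memory (batch fastest), so each spatial position is
// one column of an (N*C) x (H*W) view.

// [[Rcpp::export(name = "cpp_ln_fw")]]
List cpp_ln_fw(NumericVector x, NumericVector gamma, NumericVector beta,
               double eps) {
  int dx[4];
  get_dims4(x, dx);
  const int N = dx[0], C = dx[1];
  const size_t HW = (size_t)dx[2] * dx[3];
  NumericVector y(x.size()); y.attr("dim") = x.attr("dim");
  NumericVector xhat(x.size()); xhat.attr("dim") = x.attr("dim");
  NumericVector inv((size_t)N * HW);
  arma::vec gv(gamma.begin(), C, false), bv(beta.begin(), C, false);
  for (size_t j = 0; j < HW; ++j) {
    arma::mat B(const_cast<double*>(x.begin()) + (size_t)N * C * j, N, C,
                false, true);
    arma::mat Yj(y.begin() + (size_t)N * C * j, N, C, false, true);
    arma::mat Xh(xhat.begin() + (size_t)N * C * j, N, C, false, true);
    arma::vec mu = arma::mean(B, 1);
    arma::mat cen = B.each_col() - mu;
    arma::vec va = arma::mean(arma::square(cen), 1);
    arma::vec iv = 1.0 / arma::sqrt(va + eps);
    Xh = cen.each_col() % iv;
    Yj = Xh.each_row() % gv.t();
    Yj.each_row() += bv.t();
    std::memcpy(inv.begin() + (size_t)N * j, iv.memptr(), N * sizeof(double));
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["inv"] = inv);
}

// [[Rcpp::export(name = "cpp_ln_bw")]]
List cpp_ln_bw(NumericVector xhat, NumericVector inv, NumericVector gamma,
               NumericVector g) {
  int dx[4];
  get_dims4(xhat, dx);
  const int N = dx[0], C = dx[1];
  const size_t HW = (size_t)dx[2] * dx[3];
  NumericVector gx(xhat.size()); gx.attr("dim") = xhat.attr("dim");
  NumericVector dgamma(C), dbeta(C);
  arma::vec gv(gamma.begin(), C, false);
  arma::vec dgv(dgamma.begin(), C, false), dbv(dbeta.begin(), C, false);
  for (size_t j = 0; j < HW; ++j) {
    arma::mat Xh(const_cast<double*>(xhat.begin()) + (size_t)N * C * j, N, C,
                 false, true);
    arma::mat G(const_cast<double*>(g.begin()) + (size_t)N * C * j, N, C,
                false, true);
    arma::mat GX(gx.begin() + (size_t)N * C * j, N, C, false, true);
    arma::vec iv(const_cast<double*>(inv.begin()) + (size_t)N * j, N, false);
    dgv += arma::sum(G % Xh, 0).t();
    dbv += arma::sum(G, 0).t();
    arma::mat dxh = G.each_row() % gv.t();
    arma::vec t1 = arma::mean(dxh, 1);
    arma::vec t2 = arma::mean(dxh % Xh, 1);
    dxh.each_col() -= t1;
    dxh -= Xh.each_col() % t2;
    GX = dxh.each_col() % iv;
  }
  return List::create(_["gx"] = gx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Exact erf-based GELU: y = x * Phi(x).

// [[Rcpp::export(name = "cpp_gelu_fw")]]
NumericVector cpp_gelu_fw(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double s = M_SQRT1_2;
  for (R_xlen_t i = 0; i < x.size(); ++i)
    y[i] = x[i] * 0.5 * std::erfc(-x[i] * s);
  return y;
}

// [[Rcpp::export(name = "cpp_gelu_bw")]]
NumericVector cpp_gelu_bw(NumericVector x, NumericVector g) {
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  const double s = M_SQRT1_2;
  const double c = 0.3989422804014326779399; // 1/sqrt(2*pi)
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double phi = 0.5 * std::erfc(-x[i] * s);
    gx[i] = g[i] * (phi + x[i] * c * std::exp(-0.5 * x[i] * x[i]));
  }
  return gx;
}
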