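// Numerical core: 2-D convolution (forward, data/weight gradients) via
// im2col + GEMM, and conditionally parameterized convolution with
// per-sample aggregated expert kernels.
//
// Array layout (R, column-major): feature maps are dim (H, W, C, N);
// convolution weights are dim (k, k, Cin, Cout) with the first kernel
// axis running along H. A transposed convolution is evaluated in R as
// the adjoint of a strided convolution, so no extra kernels are needed
// here.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void dims4(const NumericVector& x, int& a, int& b, int& c, int& d) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-axis array");
  a = dm[0]; b = dm[1]; c = dm[2]; d = dm[3];
}

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Gather patches of one sample into K, a (k*k*C) x (Ho*Wo) matrix.
static void im2col(const double* x, int H, int W, int C, int k, int stride,
                   int pad, int Ho, int Wo, arma::mat& K) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      double* kc = K.colptr(ho + Ho * wo);
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < k; ++kj) {
          const int w = wo * stride - pad + kj;
          const bool win = (w >= 0 && w < W);
          for (int ki = 0; ki < k; ++ki) {
            const int h = ho * stride - pad + ki;
            kc[ki + k * (kj + k * c)] =
              (win && h >= 0 && h < H) ? x[h + H * (w + (size_t)W * c)] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add of K back onto one sample (adjoint of im2col).
static void col2im(const arma::mat& K, double* x, int H, int W, int C, int k,
                   int stride, int pad, int Ho, int Wo) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const double* kc = K.colptr(ho + Ho * wo);
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < k; ++kj) {
          const int w = wo * stride - pad + kj;
          if (w < 0 || w >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            const int h = ho * stride - pad + ki;
            if (h < 0 || h >= H) continue;
            x[h + H * (w + (size_t)W * c)] += kc[ki + k * (kj + k * c)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector nn_conv_fwd(NumericVector x, NumericVector w, int stride, int pad) {
  int H, W, C, N, k, k2, Cin, Cout;
  dims4(x, H, W, C, N);
  dims4(w, k, k2, Cin, Cout);
  if (k != k2) stop("kernel must be square");
  if (Cin != C) stop("channel mismatch: input has %d, kernel expects %d", C, Cin);
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * Cout * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  const arma::mat Wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false, true);
  arma::mat K(k * k * Cin, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad, Ho, Wo, K);
    arma::mat Yt(y.begin() + (size_t)n * Ho * Wo * Cout, Ho * Wo, Cout, false, true);
    Yt = K.t() * Wm;
  }
  return y;
}

// [[Rcpp::export]]
NumericVector nn_conv_bwd_data(NumericVector dy, NumericVector w, int stride,
                               int pad, int H, int W) {
  int Ho, Wo, Cout, N, k, k2, Cin, Cout2;
  dims4(dy, Ho, Wo, Cout, N);
  dims4(w, k, k2, Cin, Cout2);
  if (Cout != Cout2) stop("gradient/kernel channel mismatch");
  NumericVector dx(Rf_allocVector(REALSXP, (R_xlen_t)H * W * Cin * N));
  std::fill(dx.begin(), dx.end(), 0.0);
  dx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  const arma::mat Wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false, true);
  for (int n = 0; n < N; ++n) {
    const arma::mat dYt(const_cast<double*>(dy.begin()) + (size_t)n * Ho * Wo * Cout,
                        Ho * Wo, Cout, false, true);
    arma::mat dK = Wm * dYt.t();
    col2im(dK, dx.begin() + (size_t)n * H * W * Cin, H, W, Cin, k, stride, pad, Ho, Wo);
  }
  return dx;
}

// [[Rcpp::export]]
NumericVector nn_conv_bwd_weight(NumericVector x, NumericVector dy, int k,
                                 int stride, int pad) {
  int H, W, C, N, Ho, Wo, Cout, N2;
  dims4(x, H, W, C, N);
  dims4(dy, Ho, Wo, Cout, N2);
  if (N != N2) stop("batch mismatch");
  NumericVector dw(Rf_allocVector(REALSXP, (R_xlen_t)k * k * C * Cout));
  dw.attr("dim") = IntegerVector::create(k, k, C, Cout);
  arma::mat dWm(dw.begin(), k * k * C, Cout, false, true);
  dWm.zeros();
  arma::mat K(k * k * C, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad, Ho, Wo, K);
    const arma::mat dYt(const_cast<double*>(dy.begin()) + (size_t)n * Ho * Wo * Cout,
                        Ho * Wo, Cout, false, true);
    dWm += K * dYt;
  }
  return dw;
}

// Dynamic convolution: experts is (k, k, Cin, Cout, n); alphas is (N, n).
// Each sample is convolved with its own aggregated kernel sum_i alpha_i W_i.
// [[Rcpp::export]]
NumericVector nn_condconv_fwd(NumericVector x, NumericVector experts,
                              NumericMatrix alphas, int stride, int pad) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  IntegerVector ed = experts.attr("dim");
  if (ed.size() != 5) stop("experts must be a 5-axis array");
  const int k = ed[0], Cin = ed[2], Cout = ed[3], nexp = ed[4];
  if (Cin != C) stop("channel mismatch");
  if (alphas.nrow() != N || alphas.ncol() != nexp)
    stop("routing weights must be (batch x experts)");
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * Cout * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  const size_t klen = (size_t)k * k * Cin * Cout;
  const arma::mat E(const_cast<double*>(experts.begin()), klen, nexp, false, true);
  arma::mat K(k * k * Cin, Ho * Wo);
  arma::vec a(nexp), wagg(klen);
  for (int n = 0; n < N; ++n) {
    for (int i = 0; i < nexp; ++i) a[i] = alphas(n, i);
    wagg = E * a;
    const arma::mat Wm(wagg.memptr(), k * k * Cin, Cout, false, true);
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad, Ho, Wo, K);
    arma::mat Yt(y.begin() + (size_t)n * Ho * Wo * Cout, Ho * Wo, Cout, false, true);
    Yt = K.t() * Wm;
  }
  return y;
}

// [[Rcpp::export]]
List nn_condconv_bwd(NumericVector x, NumericVector experts, NumericMatrix alphas,
                     NumericVector dy, int stride, int pad) {
  int H, W, C, N, Ho, Wo, Cout, N2;
  dims4(x, H, W, C, N);
  dims4(dy, Ho, Wo, Cout, N2);
  IntegerVector ed = experts.attr("dim");
  const int k = ed[0], Cin = ed[2], nexp = ed[4];
  const size_t klen = (size_t)k * k * Cin * Cout;
  NumericVector dx(Rf_allocVector(REALSXP, (R_xlen_t)H * W * Cin * N));
  std::fill(dx.begin(), dx.end(), 0.0);
  dx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  NumericVector dexp(Rf_allocVector(REALSXP, (R_xlen_t)klen * nexp));
  dexp.attr("dim") = ed;
  NumericMatrix dalpha(N, nexp);
  const arma::mat E(const_cast<double*>(experts.begin()), klen, nexp, false, true);
  arma::mat dE(dexp.begin(), klen, nexp, false, true);
  dE.zeros();
  arma::mat K(k * k * Cin, Ho * Wo);
  arma::vec a(nexp), wagg(klen);
  for (int n = 0; n < N; ++n) {
    for (int i = 0; i < nexp; ++i) a[i] = alphas(n, i);
    wagg = E * a;
    const arma::mat Wm(wagg.memptr(), k * k * Cin, Cout, false, true);
    const arma::mat dYt(const_cast<double*>(dy.begin()) + (size_t)n * Ho * Wo * Cout,
                        Ho * Wo, Cout, false, true);
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad, Ho, Wo, K);
    // gradient w.r.t. the aggregated kernel, then chain to experts/routing
    arma::mat dWagg = K * dYt;
    const arma::vec dwv(dWagg.memptr(), klen, false, true);
    for (int i = 0; i < nexp; ++i) {
      dalpha(n, i) = arma::dot(dwv, E.col(i));
      dE.col(i) += a[i] * dwv;
    }
    arma::mat dK = Wm * dYt.t();
    col2im(dK, dx.begin() + (size_t)n * H * W * Cin, H, W, Cin, k, stride, pad, Ho, Wo);
  }
  return List::create(_["dx"] = dx, _["dexperts"] = dexp, _["dalphas"] = dalpha);
}
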