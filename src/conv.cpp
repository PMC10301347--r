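#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Batched 2-D convolution primitives (im2col + GEMM), double precision.
//
// Tensor layout follows R column-major arrays: activations [H, W, C, N],
// weights [k, k, Cin, Cout], so a (H*W) x C arma view of one sample and a
// (k*k*Cin) x Cout view of the weights need no copying.
//
// Three primitives cover both convolution and transposed convolution:
//   fwd        y = conv(x, w) + b
//   bwd_data   dx = "full" correlation of dy with w (the exact adjoint)
//   bwd_param  dw, db from (x, dy)
// A stride-2 transposed convolution is bwd_data used as the forward map.

static void im2col(const double *x, int H, int W, int C, int k, int stride,
                   int pad, arma::mat &K) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  // K is (k*k*C) x (Ho*Wo)
  K.zeros();
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int krow = ki + kj * k + c * k * k;
        for (int oj = 0; oj < Wo; ++oj) {
          const int sj = oj * stride - pad + kj;
          if (sj < 0 || sj >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int si = oi * stride - pad + ki;
            if (si < 0 || si >= H) continue;
            K(krow, oi + oj * Ho) = xc[si + (size_t)sj * H];
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat &K, int H, int W, int C, int k, int stride,
                   int pad, double *x) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  for (int c = 0; c < C; ++c) {
    double *xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int krow = ki + kj * k + c * k * k;
        for (int oj = 0; oj < Wo; ++oj) {
          const int sj = oj * stride - pad + kj;
          if (sj < 0 || sj >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int si = oi * stride - pad + ki;
            if (si < 0 || si >= H) continue;
            xc[si + (size_t)sj * H] += K(krow, oi + oj * Ho);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, IntegerVector xdim,
                           NumericVector w, int k, int cout,
                           NumericVector b, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y(Ho * Wo * (size_t)cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, cout, N);
  arma::mat Wm(const_cast<double *>(w.begin()), k * k * C, cout, false, true);
  arma::mat K(k * k * C, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad, K);
    arma::mat Y(y.begin() + (size_t)n * Ho * Wo * cout, Ho * Wo, cout, false,
                true);
    Y = K.t() * Wm;
    for (int f = 0; f < cout; ++f) Y.col(f) += b[f];
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_conv_bwd_data(NumericVector dy, IntegerVector ydim,
                                NumericVector w, int k, int cin,
                                int stride, int pad, int H, int W) {
  const int Ho = ydim[0], Wo = ydim[1], cout = ydim[2], N = ydim[3];
  NumericVector dx(H * W * (size_t)cin * N);
  dx.attr("dim") = IntegerVector::create(H, W, cin, N);
  arma::mat Wm(const_cast<double *>(w.begin()), k * k * cin, cout, false, true);
  for (int n = 0; n < N; ++n) {
    arma::mat DY(const_cast<double *>(dy.begin()) + (size_t)n * Ho * Wo * cout,
                 Ho * Wo, cout, false, true);
    arma::mat DK = Wm * DY.t();  // (k*k*cin) x (Ho*Wo)
    col2im(DK, H, W, cin, k, stride, pad,
           dx.begin() + (size_t)n * H * W * cin);
  }
  return dx;
}

// [[Rcpp::export]]
List cpp_conv_bwd_param(NumericVector x, IntegerVector xdim,
                        NumericVector dy, IntegerVector ydim,
                        int k, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = ydim[0], Wo = ydim[1], cout = ydim[2];
  NumericVector dw(k * k * (size_t)C * cout);
  dw.attr("dim") = IntegerVector::create(k, k, C, cout);
  NumericVector db(cout);
  arma::mat DW(dw.begin(), k * k * C, cout, false, true);
  arma::vec DB(db.begin(), cout, false, true);
  arma::mat K(k * k * C, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad, K);
    arma::mat DY(const_cast<double *>(dy.begin()) + (size_t)n * Ho * Wo * cout,
                 Ho * Wo, cout, false, true);
    DW += K * DY;
    DB += arma::sum(DY, 0).t();
  }
  return List::create(_["dw"] = dw, _["db"] = db);
}
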