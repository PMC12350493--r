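// Minimal 2D convolution kernels (stride 1, zero padding) used by the
// encoder-decoder. Layout follows R arrays: x is (H, W, C, B) column-major,
// weights are (K, K, C, F), outputs (H, W, F, B). Backward returns exact
// gradients (checked against finite differences in the test suite).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat pad_slice(const double* ptr, int H, int W, int p) {
  arma::mat out(H + 2 * p, W + 2 * p, arma::fill::zeros);
  out.submat(p, p, p + H - 1, p + W - 1) =
      arma::mat(const_cast<double*>(ptr), H, W, false);
  return out;
}

// Patch matrix (H*W x K*K*C) for one batch element: column ki+K*kj+K*K*c
// holds the (ki,kj)-shifted image of channel c. Column-major writes.
static arma::mat im2col_t(const arma::cube& xc, int b, int H, int W, int C,
                          int K) {
  const int p = K / 2;
  arma::mat M(H * W, K * K * C);
  for (int c = 0; c < C; ++c) {
    arma::mat xp = pad_slice(xc.slice(c + C * b).memptr(), H, W, p);
    for (int kj = 0; kj < K; ++kj)
      for (int ki = 0; ki < K; ++ki)
        M.col(ki + K * kj + K * K * c) =
            arma::vectorise(xp.submat(ki, kj, ki + H - 1, kj + W - 1));
  }
  return M;
}

// (K,K,C,F) weights as a (K*K*C x F) matrix (its natural flat layout).
static arma::mat weight_matrix(NumericVector& w, int K, int C, int F) {
  return arma::mat(w.begin(), K * K * C, F, false);
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w,
                         NumericVector bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int K = wd[0], F = wd[3];
  if (wd[2] != C) stop("conv2d_fwd: channel mismatch");
  arma::cube xc(x.begin(), H, W, C * B, false);
  arma::mat Wm = weight_matrix(w, K, C, F);
  arma::rowvec bv(bias.begin(), F, false);

  NumericVector y(H * W * F * B);
  y.attr("dim") = IntegerVector::create(H, W, F, B);
  arma::cube yc(y.begin(), H, W, F * B, false);

  for (int b = 0; b < B; ++b) {
    arma::mat M = im2col_t(xc, b, H, W, C, K);
    arma::mat Y = M * Wm;          // HW x F
    Y.each_row() += bv;
    for (int f = 0; f < F; ++f)
      yc.slice(f + F * b) = arma::reshape(Y.col(f), H, W);
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int K = wd[0], F = wd[3];
  const int p = K / 2;
  arma::cube xc(x.begin(), H, W, C * B, false);
  arma::cube dyc(dy.begin(), H, W, F * B, false);
  arma::mat Wm = weight_matrix(w, K, C, F);

  arma::mat dWm(K * K * C, F, arma::fill::zeros);
  arma::rowvec db(F, arma::fill::zeros);

  NumericVector dx(H * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  arma::cube dxc(dx.begin(), H, W, C * B, false);

  for (int b = 0; b < B; ++b) {
    arma::mat M = im2col_t(xc, b, H, W, C, K);
    arma::mat dY(H * W, F);
    for (int f = 0; f < F; ++f)
      dY.col(f) = arma::vectorise(dyc.slice(f + F * b));
    dWm += M.t() * dY;
    db += arma::sum(dY, 0);
    arma::mat dM = dY * Wm.t();    // HW x (K*K*C)
    for (int c = 0; c < C; ++c) {
      arma::mat dxp(H + 2 * p, W + 2 * p, arma::fill::zeros);
      for (int kj = 0; kj < K; ++kj)
        for (int ki = 0; ki < K; ++ki)
          dxp.submat(ki, kj, ki + H - 1, kj + W - 1) +=
              arma::reshape(dM.col(ki + K * kj + K * K * c), H, W);
      dxc.slice(c + C * b) = dxp.submat(p, p, p + H - 1, p + W - 1);
    }
  }

  NumericVector dwv(dWm.memptr(), dWm.memptr() + K * K * C * F);
  dwv.attr("dim") = IntegerVector::create(K, K, C, F);
  return List::create(Named("dx") = dx, Named("dw") = dwv,
                      Named("db") = NumericVector(db.begin(), db.end()));
}
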