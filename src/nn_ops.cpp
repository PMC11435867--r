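// Compiled kernels for the network's hot loops: im2col/col2im convolution
// and batch normalization. Activations are (N*H*W, C) matrices with row
// index n*H*W + i*W + j (0-based), matching the R-side layout. All matrix
// products go through the BLAS via Armadillo; results are bit-reproducible
// for a fixed thread count.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Gather the k*k shifted views of X (zero padding `pad`) into `cols`:
// cols(n*Ho*Wo + io*Wo + jo, m*Cin + c) = Xpad(n, io+dy, jo+dx, c),
// with m = dy*k + dx.
static void im2col_fill(const mat& X, int N, int H, int W, int k, int pad,
                        mat& cols) {
  const int Ho = H + 2 * pad - k + 1;
  const int Wo = W + 2 * pad - k + 1;
  const int Cin = X.n_cols;
  if (pad > 0) cols.zeros();
  for (int c = 0; c < Cin; ++c) {
    const double* xc = X.colptr(c);
    for (int m = 0; m < k * k; ++m) {
      const int dy = m / k, dx = m % k;
      double* oc = cols.colptr(m * Cin + c);
      const int jo_lo = std::max(0, pad - dx);
      const int jo_hi = std::min(Wo - 1, W - 1 + pad - dx);
      const int len = jo_hi - jo_lo + 1;
      if (len <= 0) continue;
      for (int n = 0; n < N; ++n) {
        for (int io = 0; io < Ho; ++io) {
          const int i_in = io + dy - pad;
          if (i_in < 0 || i_in >= H) continue;
          const double* src = xc + (std::size_t)n * H * W +
            (std::size_t)i_in * W + (jo_lo + dx - pad);
          double* dst = oc + (std::size_t)n * Ho * Wo +
            (std::size_t)io * Wo + jo_lo;
          std::memcpy(dst, src, len * sizeof(double));
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_conv_fwd(const arma::mat& X, const arma::mat& Wt,
                       int N, int H, int W, int k, int pad) {
  if (k == 1 && pad == 0) return X * Wt;
  const int Ho = H + 2 * pad - k + 1;
  const int Wo = W + 2 * pad - k + 1;
  mat cols((std::size_t)N * Ho * Wo, (std::size_t)k * k * X.n_cols);
  im2col_fill(X, N, H, W, k, pad, cols);
  return cols * Wt;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv_bwd(const arma::mat& dout, const arma::mat& X,
                        const arma::mat& Wt, int N, int H, int W,
                        int k, int pad, bool need_dx) {
  const int Cin = X.n_cols;
  if (k == 1 && pad == 0) {
    mat dW = X.t() * dout;
    if (!need_dx)
      return Rcpp::List::create(Rcpp::Named("dW") = dW,
                                Rcpp::Named("dX") = R_NilValue);
    mat dX = dout * Wt.t();
    return Rcpp::List::create(Rcpp::Named("dW") = dW,
                              Rcpp::Named("dX") = dX);
  }
  const int Ho = H + 2 * pad - k + 1;
  const int Wo = W + 2 * pad - k + 1;
  mat cols((std::size_t)N * Ho * Wo, (std::size_t)k * k * Cin);
  im2col_fill(X, N, H, W, k, pad, cols);
  mat dW = cols.t() * dout;
  if (!need_dx)
    return Rcpp::List::create(Rcpp::Named("dW") = dW,
                              Rcpp::Named("dX") = R_NilValue);
  mat dcols = dout * Wt.t();
  mat dX((std::size_t)N * H * W, Cin, fill::zeros);
  // col2im: scatter-add each shifted view back onto the input grid
  for (int c = 0; c < Cin; ++c) {
    double* xc = dX.colptr(c);
    for (int m = 0; m < k * k; ++m) {
      const int dy = m / k, dx = m % k;
      const double* oc = dcols.colptr(m * Cin + c);
      const int jo_lo = std::max(0, pad - dx);
      const int jo_hi = std::min(Wo - 1, W - 1 + pad - dx);
      const int len = jo_hi - jo_lo + 1;
      if (len <= 0) continue;
      for (int n = 0; n < N; ++n) {
        for (int io = 0; io < Ho; ++io) {
          const int i_in = io + dy - pad;
          if (i_in < 0 || i_in >= H) continue;
          double* dst = xc + (std::size_t)n * H * W +
            (std::size_t)i_in * W + (jo_lo + dx - pad);
          const double* src = oc + (std::size_t)n * Ho * Wo +
            (std::size_t)io * Wo + jo_lo;
          for (int t = 0; t < len; ++t) dst[t] += src[t];
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("dX") = dX);
}

// [[Rcpp::export]]
Rcpp::List cpp_bn_fwd_train(const arma::mat& X, const arma::vec& gamma,
                            const arma::vec& beta, double eps) {
  const int n = X.n_rows;
  rowvec mu = mean(X, 0);
  mat xhat = X.each_row() - mu;
  rowvec v = sum(square(xhat), 0) / n;   // population variance
  rowvec inv = 1.0 / sqrt(v + eps);
  xhat.each_row() %= inv;
  mat out = xhat.each_row() % gamma.t();
  out.each_row() += beta.t();
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("inv") = inv,
                            Rcpp::Named("mean") = mu,
                            Rcpp::Named("var") = v);
}

// [[Rcpp::export]]
arma::mat cpp_bn_fwd_eval(const arma::mat& X, const arma::vec& gamma,
                          const arma::vec& beta, const arma::vec& rmean,
                          const arma::vec& rvar, double eps) {
  rowvec scale = gamma.t() / sqrt(rvar.t() + eps);
  rowvec shift = beta.t() - rmean.t() % scale;
  mat out = X.each_row() % scale;
  out.each_row() += shift;
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_bn_bwd(const arma::mat& dout, const arma::mat& xhat,
                      const arma::rowvec& inv, const arma::vec& gamma) {
  rowvec dgamma = sum(dout % xhat, 0);
  rowvec dbeta = sum(dout, 0);
  mat dxhat = dout.each_row() % gamma.t();
  rowvec m1 = mean(dxhat, 0);
  rowvec m2 = sum(dxhat % xhat, 0) / dout.n_rows;
  mat dX = dxhat;
  dX.each_row() -= m1;
  dX -= xhat.each_row() % m2;
  dX.each_row() %= inv;
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}

// [[Rcpp::export]]
arma::mat cpp_relu(const arma::mat& X) {
  return clamp(X, 0.0, datum::inf);
}
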