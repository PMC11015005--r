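// 1D convolution kernels for the ResNet trunk.
// Activations are stored as (B*L) x C matrices: time runs fastest within a
// sample, samples are stacked; weights are (k*C_in) x C_out with tap index
// running fastest within input channel. Zero ("same") padding.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static mat im2col(const mat& X, int B, int L, int k, int stride, int pad) {
  const int C = X.n_cols;
  const int Lout = (L + 2 * pad - k) / stride + 1;
  mat M(B * Lout, k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = X.colptr(c);
    for (int j = 0; j < k; ++j) {
      double* col = M.colptr(c * k + j);
      for (int b = 0; b < B; ++b) {
        const int orow = b * Lout, ibase = b * L;
        for (int t = 0; t < Lout; ++t) {
          const int p = t * stride + j - pad;
          if (p >= 0 && p < L) col[orow + t] = xc[ibase + p];
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export]]
arma::mat conv1d_fwd_cpp(const arma::mat& X, const arma::mat& W,
                         int B, int L, int k, int stride, int pad) {
  return im2col(X, B, L, k, stride, pad) * W;
}

// [[Rcpp::export]]
Rcpp::List conv1d_bwd_cpp(const arma::mat& X, const arma::mat& W,
                          const arma::mat& dY,
                          int B, int L, int k, int stride, int pad) {
  const int C = X.n_cols;
  const int Lout = (L + 2 * pad - k) / stride + 1;
  mat M = im2col(X, B, L, k, stride, pad);
  mat dW = M.t() * dY;
  mat dM = dY * W.t();
  mat dX(B * L, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* xc = dX.colptr(c);
    for (int j = 0; j < k; ++j) {
      const double* col = dM.colptr(c * k + j);
      for (int b = 0; b < B; ++b) {
        const int orow = b * Lout, ibase = b * L;
        for (int t = 0; t < Lout; ++t) {
          const int p = t * stride + j - pad;
          if (p >= 0 && p < L) xc[ibase + p] += col[orow + t];
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW);
}
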