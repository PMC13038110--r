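// 1D convolution kernels for the U-Net branch.
//
// Tensors follow the R layout (channels, length, batch); a 'same'-padded
// convolution with odd kernel k is computed as k shifted matrix products
// per batch slice, which keeps all heavy arithmetic inside BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
arma::cube cpp_conv1d_fwd(const arma::cube& X, const arma::cube& W,
                          const arma::vec& b) {
  const uword L = X.n_cols, B = X.n_slices;
  const uword Cout = W.n_rows, k = W.n_slices;
  const int pad = (static_cast<int>(k) - 1) / 2;
  cube Y(Cout, L, B);
  Y.each_slice() = repmat(b, 1, L);
  for (uword s = 0; s < B; ++s) {
    const mat& Xs = X.slice(s);
    mat& Ys = Y.slice(s);
    for (uword t = 0; t < k; ++t) {
      const int off = static_cast<int>(t) - pad; // input col = output col + off
      const int lo = std::max(0, -off);
      const int hi = std::min<int>(L, static_cast<int>(L) - off) - 1;
      if (hi < lo) continue;
      Ys.cols(lo, hi) += W.slice(t) * Xs.cols(lo + off, hi + off);
    }
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv1d_bwd(const arma::cube& dY, const arma::cube& X,
                          const arma::cube& W) {
  const uword Cin = X.n_rows, L = X.n_cols, B = X.n_slices;
  const uword Cout = W.n_rows, k = W.n_slices;
  const int pad = (static_cast<int>(k) - 1) / 2;
  cube dX(Cin, L, B, fill::zeros);
  cube dW(Cout, Cin, k, fill::zeros);
  vec db(Cout, fill::zeros);
  for (uword s = 0; s < B; ++s) {
    const mat& dYs = dY.slice(s);
    const mat& Xs = X.slice(s);
    db += sum(dYs, 1);
    for (uword t = 0; t < k; ++t) {
      const int off = static_cast<int>(t) - pad;
      const int lo = std::max(0, -off);
      const int hi = std::min<int>(L, static_cast<int>(L) - off) - 1;
      if (hi < lo) continue;
      dW.slice(t) += dYs.cols(lo, hi) * Xs.cols(lo + off, hi + off).t();
      dX.slice(s).cols(lo + off, hi + off) += W.slice(t).t() * dYs.cols(lo, hi);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
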