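// 1D convolution primitives for spectra (stride 1, length-preserving padding).
//
// Layout conventions (fixed across the package):
//   activations  : cube (length L, channels C, batch B)
//   conv weights : mat  (k * C_in, C_out), row index = c * k + j for input
//                  channel c (0-based) and kernel offset j (0-based)
//   padding      : pad_left = (k - 1) / 2, pad_right = k - 1 - pad_left,
//                  so the output length equals the input length.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col1d(const mat& X, const int k, const int pad_left) {
  const int L = X.n_rows, C = X.n_cols;
  mat P(L, k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < k; ++j) {
      const int off = j - pad_left;           // source = i + off
      const int lo = std::max(0, -off);       // valid output rows
      const int hi = std::min(L, L - off);
      if (lo < hi)
        P(span(lo, hi - 1), span(c * k + j)) =
          X(span(lo + off, hi - 1 + off), span(c));
    }
  }
  return P;
}

// [[Rcpp::export]]
arma::cube conv1d_forward(const arma::cube& X, const arma::mat& W,
                          const arma::vec& b, const int k) {
  const int L = X.n_rows, B = X.n_slices, Cout = W.n_cols;
  const int pad_left = (k - 1) / 2;
  cube Y(L, Cout, B);
  for (int s = 0; s < B; ++s) {
    mat P = im2col1d(X.slice(s), k, pad_left);
    Y.slice(s) = P * W;
    Y.slice(s).each_row() += b.t();
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv1d_backward(const arma::cube& X, const arma::mat& W,
                           const arma::cube& dY, const int k) {
  const int L = X.n_rows, Cin = X.n_cols, B = X.n_slices;
  const int pad_left = (k - 1) / 2;
  cube dX(L, Cin, B, fill::zeros);
  mat dW(W.n_rows, W.n_cols, fill::zeros);
  vec db(W.n_cols, fill::zeros);
  for (int s = 0; s < B; ++s) {
    mat P = im2col1d(X.slice(s), k, pad_left);
    dW += P.t() * dY.slice(s);
    db += sum(dY.slice(s), 0).t();
    mat dP = dY.slice(s) * W.t();             // L x (k*Cin)
    for (int c = 0; c < Cin; ++c) {
      for (int j = 0; j < k; ++j) {
        const int off = j - pad_left;
        const int lo = std::max(0, -off);
        const int hi = std::min(L, L - off);
        if (lo < hi)
          dX.slice(s)(span(lo + off, hi - 1 + off), span(c)) +=
            dP(span(lo, hi - 1), span(c * k + j));
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
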