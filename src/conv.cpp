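// Valid (unpadded) 1-D convolutions over one-hot / feature-map batches.
// Layout matches R arrays: X is channels x length x batch (arma::cube).
// im2col + one GEMM per pass keeps BLAS well fed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col(const cube& X, const uword K) {
  const uword C = X.n_rows, L = X.n_cols, B = X.n_slices;
  const uword T = L - K + 1;
  mat out(C * K, T * B);
  for (uword b = 0; b < B; ++b) {
    const mat& S = X.slice(b);
    for (uword t = 0; t < T; ++t) {
      // columns t..t+K-1 of S are contiguous in memory
      std::memcpy(out.colptr(t + b * T), S.colptr(t),
                  C * K * sizeof(double));
    }
  }
  return out;
}

static mat wmat(const cube& W) {
  // W is outC x inC x K; flatten to outC x (inC*K)
  const uword outC = W.n_rows, inC = W.n_cols, K = W.n_slices;
  mat out(outC, inC * K);
  for (uword k = 0; k < K; ++k)
    out.cols(k * inC, (k + 1) * inC - 1) = W.slice(k);
  return out;
}

// [[Rcpp::export(name = ".convFwdC")]]
arma::cube convFwdC(const arma::cube& W, const arma::vec& b,
                    const arma::cube& X) {
  const uword K = W.n_slices, outC = W.n_rows;
  const uword T = X.n_cols - K + 1, B = X.n_slices;
  mat Y = wmat(W) * im2col(X, K);
  Y.each_col() += b;
  return cube(Y.memptr(), outC, T, B);
}

// [[Rcpp::export(name = ".convBwdXC")]]
arma::cube convBwdXC(const arma::cube& W, const arma::cube& dY) {
  const uword K = W.n_slices, inC = W.n_cols;
  const uword T = dY.n_cols, B = dY.n_slices;
  const uword L = T + K - 1;
  const mat dYm(const_cast<double*>(dY.memptr()), dY.n_rows, T * B,
                false, true);
  mat dXcol = wmat(W).t() * dYm;          // (inC*K) x (T*B)
  cube dX(inC, L, B, fill::zeros);
  for (uword b = 0; b < B; ++b) {
    mat& S = dX.slice(b);
    for (uword t = 0; t < T; ++t) {
      const double* src = dXcol.colptr(t + b * T);
      double* dst = S.colptr(t);
      for (uword i = 0; i < inC * K; ++i) dst[i] += src[i];
    }
  }
  return dX;
}

// [[Rcpp::export(name = ".convBwdWC")]]
Rcpp::List convBwdWC(const arma::cube& W, const arma::cube& X,
                     const arma::cube& dY) {
  const uword K = W.n_slices, outC = W.n_rows, inC = W.n_cols;
  const uword T = dY.n_cols, B = dY.n_slices;
  const mat dYm(const_cast<double*>(dY.memptr()), outC, T * B,
                false, true);
  mat g = dYm * im2col(X, K).t();         // outC x (inC*K)
  cube dW(outC, inC, K);
  for (uword k = 0; k < K; ++k)
    dW.slice(k) = g.cols(k * inC, (k + 1) * inC - 1);
  vec db = sum(dYm, 1);
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
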