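// 1D "same" convolution forward/backward for the deep CNN classifier.
//
// Batched activations are channels-first: a C x (L*B) column-major matrix
// whose column index is b*L + l (time fastest within each batch item).
// Internally the batch is laid out as one long padded signal of Lp*B
// columns (Lp = L+K-1) with K-1 zero columns between items, so every kernel
// tap contributes one contiguous dgemm over the whole batch at once -- no
// im2col materialization, no copies beyond the single padding pass.

#define USE_FC_LEN_T
#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif

// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void pad_batch(const mat& X, mat& Xp, int L, int B, int pl) {
  const int Lp = Xp.n_cols / B;
  for (int b = 0; b < B; ++b) {
    Xp.cols(b * Lp + pl, b * Lp + pl + L - 1) = X.cols(b * L, b * L + L - 1);
  }
}

static void unpad_batch(const mat& Yp, mat& Y, int L, int B, int pl) {
  const int Lp = Yp.n_cols / B;
  for (int b = 0; b < B; ++b) {
    Y.cols(b * L, b * L + L - 1) = Yp.cols(b * Lp + pl, b * Lp + pl + L - 1);
  }
}

// C(M x N) <- alpha * op(A) * op(B) + beta * C with explicit leading dims.
static void dgemm_raw(bool transA, bool transB, int M, int N, int K,
                      double alpha, const double* A, int lda,
                      const double* B, int ldb, double beta, double* C,
                      int ldc) {
  const char ta = transA ? 'T' : 'N';
  const char tb = transB ? 'T' : 'N';
  F77_CALL(dgemm)(&ta, &tb, &M, &N, &K, &alpha, A, &lda, B, &ldb, &beta, C,
                  &ldc FCONE FCONE);
}

// X: Cin x (L*B); W: cube(Cout, Cin, K); bias: vec(Cout).
// Returns Y: Cout x (L*B), the 'same' convolution with left pad (K-1)/2.
// [[Rcpp::export]]
arma::mat conv1d_fwd_cpp(const arma::mat& X, const arma::cube& W,
                         const arma::vec& bias, int L, int B) {
  const int Cin = X.n_rows;
  const int Cout = W.n_rows;
  const int K = W.n_slices;
  const int pl = (K - 1) / 2;
  const int Lp = L + K - 1;
  const int N = Lp * B;
  if ((int)W.n_cols != Cin) Rcpp::stop("weight/input channel mismatch");
  if ((int)X.n_cols != L * B) Rcpp::stop("input columns != L*B");

  mat Xp(Cin, N, fill::zeros);
  pad_batch(X, Xp, L, B, pl);
  mat Yp(Cout, N, fill::zeros);

  // Tile the batch columns so one tile of input/output stays cache-hot
  // across all K taps (the per-tap dgemms are otherwise bandwidth-bound).
  const int TILE = 4096;
  for (int t0 = 0; t0 < N; t0 += TILE) {
    const int t1 = std::min(N - 1, t0 + TILE - 1);
    for (int k = 0; k < K; ++k) {
      const int s = k - pl;
      const int a = std::max(t0, std::max(0, -s));
      const int b = std::min(t1, N - 1 - std::max(0, s));
      if (a > b) continue;
      const int M = b - a + 1;
      // Yp[, a..b] += W_k %*% Xp[, a+s..b+s]
      dgemm_raw(false, false, Cout, M, Cin, 1.0, W.slice(k).memptr(), Cout,
                Xp.colptr(a + s), Cin, 1.0, Yp.colptr(a), Cout);
    }
  }
  mat Y(Cout, L * B);
  unpad_batch(Yp, Y, L, B, pl);
  Y.each_col() += bias;
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv1d_bwd_cpp(const arma::mat& X, const arma::cube& W,
                          const arma::mat& dY, int L, int B) {
  const int Cin = X.n_rows;
  const int Cout = W.n_rows;
  const int K = W.n_slices;
  const int pl = (K - 1) / 2;
  const int Lp = L + K - 1;
  const int N = Lp * B;

  mat Xp(Cin, N, fill::zeros);
  pad_batch(X, Xp, L, B, pl);
  mat dYp(Cout, N, fill::zeros);
  pad_batch(dY, dYp, L, B, pl);

  cube dW(Cout, Cin, K, fill::zeros);
  mat dXp(Cin, N, fill::zeros);

  const int TILE = 4096;
  for (int t0 = 0; t0 < N; t0 += TILE) {
    const int t1 = std::min(N - 1, t0 + TILE - 1);
    for (int k = 0; k < K; ++k) {
      const int s = k - pl;
      const int a = std::max(t0, std::max(0, -s));
      const int b = std::min(t1, N - 1 - std::max(0, s));
      if (a > b) continue;
      const int M = b - a + 1;
      // dW_k += dYp[, a..b] %*% Xp[, a+s..b+s]^T
      dgemm_raw(false, true, Cout, Cin, M, 1.0, dYp.colptr(a), Cout,
                Xp.colptr(a + s), Cin, 1.0, dW.slice(k).memptr(), Cout);
      // dXp[, a+s..b+s] += W_k^T %*% dYp[, a..b]
      dgemm_raw(true, false, Cin, M, Cout, 1.0, W.slice(k).memptr(), Cout,
                dYp.colptr(a), Cout, 1.0, dXp.colptr(a + s), Cin);
    }
  }
  mat dX(Cin, L * B);
  unpad_batch(dXp, dX, L, B, pl);
  vec db = sum(dY, 1);
  return Rcpp::List::create(Rcpp::Named("dx") = dX, Rcpp::Named("dw") = dW,
                            Rcpp::Named("db") = db);
}
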