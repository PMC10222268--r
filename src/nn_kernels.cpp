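// Convolution and pooling kernels for the CNN engine.
//
// Feature maps arrive in the package's batched column layout: an
// (N*H*W) x C matrix whose rows are sample-major blocks of H*W grid
// positions. `big` is the cached patch-index map: (N*H*W) x (kh*kw),
// 1-based, with 1 denoting a zero-padded tap (indices are offset by one
// so that value v > 1 refers to input row v - 1).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat build_patches(const arma::mat& A, const IntegerMatrix& big,
                               int K, int cin) {
  const arma::uword n = big.nrow();
  arma::mat P(n, (arma::uword)(K * cin), arma::fill::zeros);
  for (int k = 0; k < K; ++k) {
    const int* idx = &big(0, k);           // column pointer; 1 = padded tap
    for (int c = 0; c < cin; ++c) {
      const double* src = A.colptr((arma::uword)c) - 1;  // 1-based lookup
      double* dst = P.colptr((arma::uword)(k * cin + c));
      for (arma::uword r = 0; r < n; ++r) {
        const int v = idx[r] - 1;          // 0 = padded tap
        if (v > 0) dst[r] = src[v];
      }
    }
  }
  return P;
}

// [[Rcpp::export(name = ".cpp_conv_fwd")]]
arma::mat cpp_conv_fwd(const arma::mat& A, const arma::mat& W,
                       const arma::vec& b, const IntegerMatrix& big,
                       int K, int cin) {
  arma::mat P = build_patches(A, big, K, cin);
  arma::mat Y = P * W;
  Y.each_row() += b.t();
  return Y;
}

// [[Rcpp::export(name = ".cpp_conv_bwd")]]
List cpp_conv_bwd(const arma::mat& A, const arma::mat& W,
                  const arma::mat& dY, const IntegerMatrix& big,
                  int K, int cin, bool need_input_grad) {
  arma::mat P = build_patches(A, big, K, cin);
  arma::mat dW = P.t() * dY;
  arma::rowvec db = arma::sum(dY, 0);
  if (!need_input_grad) {
    return List::create(Named("dW") = dW, Named("db") = db,
                        Named("dA") = R_NilValue);
  }
  arma::mat dP = dY * W.t();
  arma::mat dA(A.n_rows, (arma::uword)cin, arma::fill::zeros);
  const arma::uword n = big.nrow();
  for (int k = 0; k < K; ++k) {
    const int* idx = &big(0, k);
    for (int c = 0; c < cin; ++c) {
      double* dst = dA.colptr((arma::uword)c) - 1;       // 1-based scatter
      const double* g = dP.colptr((arma::uword)(k * cin + c));
      for (arma::uword r = 0; r < n; ++r) {
        const int v = idx[r] - 1;
        if (v > 0) dst[v] += g[r];
      }
    }
  }
  return List::create(Named("dW") = dW, Named("db") = db,
                      Named("dA") = dA);
}

// rows4: (N*H2*W2) x 4 1-based row indices of the four pooled taps.
// [[Rcpp::export(name = ".cpp_pool_fwd")]]
List cpp_pool_fwd(const arma::mat& A, const IntegerMatrix& rows4) {
  const arma::uword n = rows4.nrow(), C = A.n_cols;
  arma::mat Y(n, C);
  IntegerMatrix arg((int)n, (int)C);
  for (arma::uword r = 0; r < n; ++r) {
    for (arma::uword c = 0; c < C; ++c) {
      double best = A(rows4(r, 0) - 1, c);
      int which = 1;
      for (int t = 1; t < 4; ++t) {
        const double v = A(rows4(r, t) - 1, c);
        if (v > best) { best = v; which = t + 1; }
      }
      Y(r, c) = best;
      arg(r, c) = which;
    }
  }
  return List::create(Named("Y") = Y, Named("arg") = arg);
}

// [[Rcpp::export(name = ".cpp_pool_bwd")]]
arma::mat cpp_pool_bwd(const arma::mat& dY, const IntegerMatrix& arg,
                       const IntegerMatrix& rows4, int nrowA) {
  const arma::uword n = rows4.nrow(), C = dY.n_cols;
  arma::mat dA((arma::uword)nrowA, C, arma::fill::zeros);
  for (arma::uword r = 0; r < n; ++r) {
    for (arma::uword c = 0; c < C; ++c) {
      dA(rows4(r, arg(r, c) - 1) - 1, c) += dY(r, c);
    }
  }
  return dA;
}

// In-place Adam update on parameters the trainer owns privately (the
// trainer deep-copies initial weights before the first step).
// [[Rcpp::export(name = ".cpp_adam_step")]]
void cpp_adam_step(NumericVector W, NumericVector mW, NumericVector vW,
                   const NumericVector gW, double lr, double beta1,
                   double beta2, double eps, double c1, double c2) {
  const R_xlen_t n = W.size();
  double* w = REAL(W);
  double* m = REAL(mW);
  double* v = REAL(vW);
  const double* g = REAL(gW);
  for (R_xlen_t i = 0; i < n; ++i) {
    m[i] = beta1 * m[i] + (1.0 - beta1) * g[i];
    v[i] = beta2 * v[i] + (1.0 - beta2) * g[i] * g[i];
    w[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
  }
}
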