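// Multi-head self-attention core: per-sample, per-head softmax(Q K^T / sqrt(d)) V
// in single precision. Token rows of sample n are the contiguous block
// [(n-1)*T, n*T) of the (N*T) x C matrices; head h owns the contiguous
// channel block [(h-1)*dh, h*dh).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::fmat block_f(const NumericMatrix& M, int r0, int T, int c0,
                          int dh) {
  arma::fmat out(T, dh);
  for (int c = 0; c < dh; ++c) {
    const double* src = &M(r0, c0 + c);
    float* dst = out.colptr(c);
    for (int i = 0; i < T; ++i) dst[i] = (float)src[i];
  }
  return out;
}

static void softmax_rows(arma::fmat& S) {
  for (arma::uword i = 0; i < S.n_rows; ++i) {
    arma::frowvec r = S.row(i);
    r -= r.max();
    r = arma::exp(r);
    S.row(i) = r / arma::accu(r);
  }
}

// [[Rcpp::export(name = ".mhsa_core_fwd_cpp")]]
NumericMatrix mhsa_core_fwd_cpp(NumericMatrix Q, NumericMatrix K,
                                NumericMatrix V, int heads, int T) {
  const int C = Q.ncol();
  const int N = Q.nrow() / T;
  const int dh = C / heads;
  const float scale = 1.0f / std::sqrt((float)dh);
  NumericMatrix O(Q.nrow(), C);
  for (int n = 0; n < N; ++n) {
    const int r0 = n * T;
    for (int h = 0; h < heads; ++h) {
      const int c0 = h * dh;
      arma::fmat Qh = block_f(Q, r0, T, c0, dh);
      arma::fmat Kh = block_f(K, r0, T, c0, dh);
      arma::fmat Vh = block_f(V, r0, T, c0, dh);
      arma::fmat S = Qh * Kh.t() * scale;
      softmax_rows(S);
      arma::fmat Oh = S * Vh;
      for (int c = 0; c < dh; ++c) {
        double* dst = &O(r0, c0 + c);
        const float* src = Oh.colptr(c);
        for (int i = 0; i < T; ++i) dst[i] = src[i];
      }
    }
  }
  return O;
}

// backward recomputes the attention weights from Q and K
// [[Rcpp::export(name = ".mhsa_core_bwd_cpp")]]
List mhsa_core_bwd_cpp(NumericMatrix Q, NumericMatrix K, NumericMatrix V,
                       NumericMatrix dO, int heads, int T) {
  const int C = Q.ncol();
  const int N = Q.nrow() / T;
  const int dh = C / heads;
  const float scale = 1.0f / std::sqrt((float)dh);
  NumericMatrix dQ(Q.nrow(), C), dK(Q.nrow(), C), dV(Q.nrow(), C);
  for (int n = 0; n < N; ++n) {
    const int r0 = n * T;
    for (int h = 0; h < heads; ++h) {
      const int c0 = h * dh;
      arma::fmat Qh = block_f(Q, r0, T, c0, dh);
      arma::fmat Kh = block_f(K, r0, T, c0, dh);
      arma::fmat Vh = block_f(V, r0, T, c0, dh);
      arma::fmat dOh = block_f(dO, r0, T, c0, dh);
      arma::fmat A = Qh * Kh.t() * scale;
      softmax_rows(A);
      arma::fmat dA = dOh * Vh.t();
      arma::fmat dVh = A.t() * dOh;
      arma::fvec rs = arma::sum(A % dA, 1);
      arma::fmat dS = A % (dA.each_col() - rs);
      arma::fmat dQh = dS * Kh * scale;
      arma::fmat dKh = dS.t() * Qh * scale;
      for (int c = 0; c < dh; ++c) {
        double* q = &dQ(r0, c0 + c);
        double* k = &dK(r0, c0 + c);
        double* v = &dV(r0, c0 + c);
        for (int i = 0; i < T; ++i) {
          q[i] = dQh(i, c);
          k[i] = dKh(i, c);
          v[i] = dVh(i, c);
        }
      }
    }
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
}
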