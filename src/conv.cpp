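// Same-padding 2-D convolution kernels (im2col + GEMM) for feature tensors
// stored as R arrays with dim c(H, W, N, C), column-major.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col: rows ordered (i, j, n) like matrix(x, H*W*N, C); column index
// u + k*(v + k*ci) matching matrix(W, k*k*Cin, Cout) for W dim (k,k,Cin,Cout)
// single precision internally: the networks are trained at fp32 and the
// GEMMs run ~2x faster than double
static arma::fmat im2col_same(const double* x, int H, int W, int N, int C,
                              int k) {
  const int r = (k - 1) / 2;
  const long HW = (long)H * W;
  const long HWN = HW * N;
  arma::fmat out((arma::uword)HWN, (arma::uword)(k * k * C));
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + (long)ci * HWN;
    for (int v = 0; v < k; ++v) {
      const int dv = v - r;
      for (int u = 0; u < k; ++u) {
        const int du = u - r;
        float* col = out.colptr((arma::uword)(u + k * (v + k * ci)));
        for (int n = 0; n < N; ++n) {
          const double* xn = xc + (long)n * HW;
          float* coln = col + (long)n * HW;
          for (int j = 0; j < W; ++j) {
            const int sj = j + dv;
            float* cj = coln + (long)j * H;
            if (sj < 0 || sj >= W) {
              std::fill(cj, cj + H, 0.0f);
              continue;
            }
            const double* xj = xn + (long)sj * H;
            const int lo = std::max(0, -du);
            const int hi = std::min(H, H - du);
            if (lo > 0) std::fill(cj, cj + lo, 0.0f);
            for (int i = lo; i < hi; ++i) cj[i] = (float)xj[i + du];
            if (hi < H) std::fill(cj + std::max(hi, 0), cj + H, 0.0f);
          }
        }
      }
    }
  }
  return out;
}

static arma::fmat to_f(const double* p, arma::uword nr, arma::uword nc) {
  arma::fmat out(nr, nc);
  const arma::uword n = nr * nc;
  float* o = out.memptr();
  for (arma::uword i = 0; i < n; ++i) o[i] = (float)p[i];
  return out;
}

// scatter-add adjoint of im2col
static void col2im_same(const arma::fmat& cols, double* dx, int H, int W,
                        int N, int C, int k) {
  const int r = (k - 1) / 2;
  const long HW = (long)H * W;
  const long HWN = HW * N;
  for (int ci = 0; ci < C; ++ci) {
    double* xc = dx + (long)ci * HWN;
    for (int v = 0; v < k; ++v) {
      const int dv = v - r;
      for (int u = 0; u < k; ++u) {
        const int du = u - r;
        const float* col = cols.colptr((arma::uword)(u + k * (v + k * ci)));
        for (int n = 0; n < N; ++n) {
          double* xn = xc + (long)n * HW;
          const float* coln = col + (long)n * HW;
          for (int j = 0; j < W; ++j) {
            const int sj = j + dv;
            if (sj < 0 || sj >= W) continue;
            double* xj = xn + (long)sj * H;
            const float* cj = coln + (long)j * H;
            const int lo = std::max(0, -du);
            const int hi = std::min(H, H - du);
            for (int i = lo; i < hi; ++i) xj[i + du] += cj[i];
          }
        }
      }
    }
  }
}

static IntegerVector tensor_dims(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-D (H, W, N, C) tensor");
  return d;
}

// [[Rcpp::export(name = ".conv2d_same_fwd_cpp")]]
NumericVector conv2d_same_fwd_cpp(NumericVector x, NumericVector W,
                                  Nullable<NumericVector> b) {
  IntegerVector dx = tensor_dims(x);
  IntegerVector dW = W.attr("dim");
  if (dW.size() != 4 || dW[0] != dW[1]) stop("kernel must be (k, k, Cin, Cout)");
  const int k = dW[0], Cin = dW[2], Cout = dW[3];
  if (dx[3] != Cin) stop("input channels do not match the kernel");
  arma::fmat cols = im2col_same(x.begin(), dx[0], dx[1], dx[2], dx[3], k);
  arma::fmat Wm = to_f(W.begin(), (arma::uword)(k * k * Cin), (arma::uword)Cout);
  arma::fmat Y = cols * Wm;
  if (b.isNotNull()) {
    NumericVector bb(b);
    arma::frowvec bf(Cout);
    for (int c = 0; c < Cout; ++c) bf[c] = (float)bb[c];
    Y.each_row() += bf;
  }
  NumericVector out(Y.size());
  std::copy(Y.begin(), Y.end(), out.begin());
  out.attr("dim") = IntegerVector::create(dx[0], dx[1], dx[2], Cout);
  return out;
}

// [[Rcpp::export(name = ".conv2d_same_bwd_cpp")]]
List conv2d_same_bwd_cpp(NumericVector x, NumericVector W, NumericVector dy) {
  IntegerVector dx_dim = tensor_dims(x);
  IntegerVector dW_dim = W.attr("dim");
  IntegerVector dy_dim = tensor_dims(dy);
  const int k = dW_dim[0], Cin = dW_dim[2], Cout = dW_dim[3];
  const long HWN = (long)dx_dim[0] * dx_dim[1] * dx_dim[2];
  arma::fmat cols = im2col_same(x.begin(), dx_dim[0], dx_dim[1], dx_dim[2],
                                Cin, k);
  arma::fmat dYm = to_f(dy.begin(), (arma::uword)HWN, (arma::uword)Cout);
  arma::fmat gW = cols.t() * dYm;
  arma::frowvec gb = arma::sum(dYm, 0);
  arma::fmat Wm = to_f(W.begin(), (arma::uword)(k * k * Cin),
                       (arma::uword)Cout);
  arma::fmat dcols = dYm * Wm.t();
  NumericVector dxv((R_xlen_t)HWN * Cin);
  col2im_same(dcols, dxv.begin(), dx_dim[0], dx_dim[1], dx_dim[2], Cin, k);
  dxv.attr("dim") = IntegerVector::create(dx_dim[0], dx_dim[1], dx_dim[2], Cin);
  NumericVector gWv(gW.size());
  std::copy(gW.begin(), gW.end(), gWv.begin());
  gWv.attr("dim") = dW_dim;
  NumericVector gbv(Cout);
  std::copy(gb.begin(), gb.end(), gbv.begin());
  return List::create(_["dx"] = dxv, _["dW"] = gWv, _["db"] = gbv);
}
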