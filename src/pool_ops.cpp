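// Pooling, box-filter and bilinear-resampling kernels for (H, W, N, C) tensors.
#include <Rcpp.h>
using namespace Rcpp;

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-D (H, W, N, C) tensor");
  return d;
}

// 3x3 neighbourhood sum (zero outside the frame), applied per (n, c) slice
// [[Rcpp::export(name = ".box3_sum_cpp")]]
NumericVector box3_sum_cpp(NumericVector x) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1];
  const long HW = (long)H * W;
  const long S = (long)d[2] * d[3];
  NumericVector out(x.size());
  out.attr("dim") = d;
  for (long s = 0; s < S; ++s) {
    const double* xs = x.begin() + s * HW;
    double* os = out.begin() + s * HW;
    for (int j = 0; j < W; ++j) {
      const int j0 = std::max(0, j - 1), j1 = std::min(W - 1, j + 1);
      for (int i = 0; i < H; ++i) {
        const int i0 = std::max(0, i - 1), i1 = std::min(H - 1, i + 1);
        double acc = 0.0;
        for (int jj = j0; jj <= j1; ++jj) {
          const double* col = xs + (long)jj * H;
          for (int ii = i0; ii <= i1; ++ii) acc += col[ii];
        }
        os[i + (long)j * H] = acc;
      }
    }
  }
  return out;
}

// 2x2 stride-2 max pooling; returns the pooled map and the winning offset
// (0..3, column-major within the window) for the backward pass
// [[Rcpp::export(name = ".maxpool2_fwd_cpp")]]
List maxpool2_fwd_cpp(NumericVector x) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], Ho = H / 2, Wo = W / 2;
  const long HW = (long)H * W, HWo = (long)Ho * Wo;
  const long S = (long)d[2] * d[3];
  NumericVector y(HWo * S);
  IntegerVector sel(HWo * S);
  y.attr("dim") = IntegerVector::create(Ho, Wo, d[2], d[3]);
  for (long s = 0; s < S; ++s) {
    const double* xs = x.begin() + s * HW;
    double* ys = y.begin() + s * HWo;
    int* ss = sel.begin() + s * HWo;
    for (int j = 0; j < Wo; ++j) {
      const double* c0 = xs + (long)(2 * j) * H;
      const double* c1 = xs + (long)(2 * j + 1) * H;
      for (int i = 0; i < Ho; ++i) {
        const double v[4] = {c0[2 * i], c0[2 * i + 1], c1[2 * i],
                             c1[2 * i + 1]};
        int best = 0;
        for (int k = 1; k < 4; ++k) if (v[k] > v[best]) best = k;
        ys[i + (long)j * Ho] = v[best];
        ss[i + (long)j * Ho] = best;
      }
    }
  }
  return List::create(_["y"] = y, _["sel"] = sel);
}

// [[Rcpp::export(name = ".maxpool2_bwd_cpp")]]
NumericVector maxpool2_bwd_cpp(NumericVector dy, IntegerVector sel,
                               IntegerVector in_dim) {
  IntegerVector d = dims4(dy);
  const int Ho = d[0], Wo = d[1], H = in_dim[0], W = in_dim[1];
  const long HW = (long)H * W, HWo = (long)Ho * Wo;
  const long S = (long)d[2] * d[3];
  NumericVector dx(HW * S);
  dx.attr("dim") = in_dim;
  for (long s = 0; s < S; ++s) {
    const double* ds = dy.begin() + s * HWo;
    const int* ss = sel.begin() + s * HWo;
    double* xs = dx.begin() + s * HW;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int k = ss[i + (long)j * Ho];
        const int ii = 2 * i + (k & 1);
        const int jj = 2 * j + (k >> 1);
        xs[ii + (long)jj * H] = ds[i + (long)j * Ho];
      }
    }
  }
  return dx;
}

// depthwise 3x3 same-padding convolution; W dim (3, 3, C)
// [[Rcpp::export(name = ".dwconv3_fwd_cpp")]]
NumericVector dwconv3_fwd_cpp(NumericVector x, NumericVector W,
                              Nullable<NumericVector> b) {
  IntegerVector d = dims4(x);
  const int H = d[0], Wd = d[1], N = d[2], C = d[3];
  const long HW = (long)H * Wd;
  NumericVector out(x.size());
  out.attr("dim") = d;
  NumericVector bb = b.isNotNull() ? NumericVector(b) : NumericVector(C);
  for (int c = 0; c < C; ++c) {
    const double* wk = W.begin() + 9L * c;
    const double bias = bb[c];
    for (int n = 0; n < N; ++n) {
      const double* xs = x.begin() + ((long)c * N + n) * HW;
      double* os = out.begin() + ((long)c * N + n) * HW;
      for (int j = 0; j < Wd; ++j) {
        for (int i = 0; i < H; ++i) {
          double acc = bias;
          for (int v = -1; v <= 1; ++v) {
            const int sj = j + v;
            if (sj < 0 || sj >= Wd) continue;
            const double* col = xs + (long)sj * H;
            for (int u = -1; u <= 1; ++u) {
              const int si = i + u;
              if (si < 0 || si >= H) continue;
              acc += col[si] * wk[(u + 1) + 3 * (v + 1)];
            }
          }
          os[i + (long)j * H] = acc;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".dwconv3_bwd_cpp")]]
List dwconv3_bwd_cpp(NumericVector x, NumericVector W, NumericVector dy) {
  IntegerVector d = dims4(x);
  const int H = d[0], Wd = d[1], N = d[2], C = d[3];
  const long HW = (long)H * Wd;
  NumericVector dx(x.size());
  dx.attr("dim") = d;
  NumericVector gW(9L * C);
  gW.attr("dim") = IntegerVector::create(3, 3, C);
  NumericVector gb(C);
  for (int c = 0; c < C; ++c) {
    const double* wk = W.begin() + 9L * c;
    double* gwc = gW.begin() + 9L * c;
    double gbc = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xs = x.begin() + ((long)c * N + n) * HW;
      const double* ds = dy.begin() + ((long)c * N + n) * HW;
      double* xds = dx.begin() + ((long)c * N + n) * HW;
      for (int j = 0; j < Wd; ++j) {
        for (int i = 0; i < H; ++i) {
          const double g = ds[i + (long)j * H];
          gbc += g;
          for (int v = -1; v <= 1; ++v) {
            const int sj = j + v;
            if (sj < 0 || sj >= Wd) continue;
            for (int u = -1; u <= 1; ++u) {
              const int si = i + u;
              if (si < 0 || si >= H) continue;
              const double xv = xs[si + (long)sj * H];
              gwc[(u + 1) + 3 * (v + 1)] += xv * g;
              xds[si + (long)sj * H] += g * wk[(u + 1) + 3 * (v + 1)];
            }
          }
        }
      }
    }
    gb[c] = gbc;
  }
  return List::create(_["dx"] = dx, _["dW"] = gW, _["db"] = gb);
}

static void axis_weights(int n_in, int n_out, std::vector<int>& i0,
                         std::vector<int>& i1, std::vector<double>& w0) {
  i0.resize(n_out); i1.resize(n_out); w0.resize(n_out);
  for (int i = 0; i < n_out; ++i) {
    double src = (i + 0.5) * (double)n_in / n_out - 0.5;
    src = std::min(std::max(src, 0.0), (double)(n_in - 1));
    int lo = std::min((int)std::floor(src), n_in - 1);
    int hi = std::min(lo + 1, n_in - 1);
    i0[i] = lo; i1[i] = hi; w0[i] = 1.0 - (src - lo);
  }
}

// bilinear upsampling, half-pixel-centre convention
// [[Rcpp::export(name = ".bilinear_fwd_cpp")]]
NumericVector bilinear_fwd_cpp(NumericVector x, int out_h, int out_w) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1];
  const long HW = (long)H * W, HWo = (long)out_h * out_w;
  const long S = (long)d[2] * d[3];
  std::vector<int> y0, y1, x0, x1;
  std::vector<double> wy, wx;
  axis_weights(H, out_h, y0, y1, wy);
  axis_weights(W, out_w, x0, x1, wx);
  NumericVector out(HWo * S);
  out.attr("dim") = IntegerVector::create(out_h, out_w, d[2], d[3]);
  for (long s = 0; s < S; ++s) {
    const double* xs = x.begin() + s * HW;
    double* os = out.begin() + s * HWo;
    for (int j = 0; j < out_w; ++j) {
      const double* c0 = xs + (long)x0[j] * H;
      const double* c1 = xs + (long)x1[j] * H;
      const double wxj = wx[j];
      for (int i = 0; i < out_h; ++i) {
        const double a = wy[i] * c0[y0[i]] + (1 - wy[i]) * c0[y1[i]];
        const double b = wy[i] * c1[y0[i]] + (1 - wy[i]) * c1[y1[i]];
        os[i + (long)j * out_h] = wxj * a + (1 - wxj) * b;
      }
    }
  }
  return out;
}

// adjoint of bilinear upsampling
// [[Rcpp::export(name = ".bilinear_bwd_cpp")]]
NumericVector bilinear_bwd_cpp(NumericVector dy, int in_h, int in_w) {
  IntegerVector d = dims4(dy);
  const int Ho = d[0], Wo = d[1];
  const long HW = (long)in_h * in_w, HWo = (long)Ho * Wo;
  const long S = (long)d[2] * d[3];
  std::vector<int> y0, y1, x0, x1;
  std::vector<double> wy, wx;
  axis_weights(in_h, Ho, y0, y1, wy);
  axis_weights(in_w, Wo, x0, x1, wx);
  NumericVector dx(HW * S);
  dx.attr("dim") = IntegerVector::create(in_h, in_w, d[2], d[3]);
  for (long s = 0; s < S; ++s) {
    const double* ds = dy.begin() + s * HWo;
    double* xs = dx.begin() + s * HW;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const double g = ds[i + (long)j * Ho];
        xs[y0[i] + (long)x0[j] * in_h] += wy[i] * wx[j] * g;
        xs[y1[i] + (long)x0[j] * in_h] += (1 - wy[i]) * wx[j] * g;
        xs[y0[i] + (long)x1[j] * in_h] += wy[i] * (1 - wx[j]) * g;
        xs[y1[i] + (long)x1[j] * in_h] += (1 - wy[i]) * (1 - wx[j]) * g;
      }
    }
  }
  return dx;
}
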