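// 3D convolution kernels. Compute is done in single precision (the weights
// and activations are O(1); float rounding is far below training noise) with
// double in/out at the R boundary.
//
// The dominant case — kernel 3, stride 1, pad 1 — uses a shift-GEMM scheme:
// the input is padded once, then for each w-offset g one large sgemm computes
// all (a, b) kernel-offset contributions, which are accumulated into the
// output with banded strided adds. Everything stays cache-friendly instead of
// materializing a 27x-expanded im2col matrix. Other configurations fall back
// to a float im2col/col2im path.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_dim_f(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// ---- generic float im2col / col2im -----------------------------------------

static arma::fmat im2col_f(const float* x, int C, int D, int H, int W,
                           int k, int stride, int pad) {
  const int Do = out_dim_f(D, k, stride, pad);
  const int Ho = out_dim_f(H, k, stride, pad);
  const int Wo = out_dim_f(W, k, stride, pad);
  const int K3 = k * k * k;
  arma::fmat cols(C * K3, (arma::uword)Do * Ho * Wo, arma::fill::zeros);
  for (int ow = 0; ow < Wo; ++ow)
    for (int oh = 0; oh < Ho; ++oh)
      for (int od = 0; od < Do; ++od) {
        const arma::uword col = (arma::uword)od + (arma::uword)Do * (oh + (arma::uword)Ho * ow);
        float* dst = cols.colptr(col);
        for (int g = 0; g < k; ++g) {
          const int w = ow * stride - pad + g;
          for (int b = 0; b < k; ++b) {
            const int h = oh * stride - pad + b;
            for (int a = 0; a < k; ++a) {
              const int d = od * stride - pad + a;
              float* drow = dst + (arma::uword)C * (a + k * (b + k * g));
              if (d >= 0 && d < D && h >= 0 && h < H && w >= 0 && w < W) {
                const float* src = x + (arma::uword)C * (d + (arma::uword)D * (h + (arma::uword)H * w));
                for (int c = 0; c < C; ++c) drow[c] = src[c];
              }
            }
          }
        }
      }
  return cols;
}

static void col2im_f(const arma::fmat& cols, float* x, int C, int D, int H,
                     int W, int k, int stride, int pad) {
  const int Do = out_dim_f(D, k, stride, pad);
  const int Ho = out_dim_f(H, k, stride, pad);
  const int Wo = out_dim_f(W, k, stride, pad);
  std::fill(x, x + (arma::uword)C * D * H * W, 0.0f);
  for (int ow = 0; ow < Wo; ++ow)
    for (int oh = 0; oh < Ho; ++oh)
      for (int od = 0; od < Do; ++od) {
        const arma::uword col = (arma::uword)od + (arma::uword)Do * (oh + (arma::uword)Ho * ow);
        const float* src = cols.colptr(col);
        for (int g = 0; g < k; ++g) {
          const int w = ow * stride - pad + g;
          for (int b = 0; b < k; ++b) {
            const int h = oh * stride - pad + b;
            for (int a = 0; a < k; ++a) {
              const int d = od * stride - pad + a;
              if (d >= 0 && d < D && h >= 0 && h < H && w >= 0 && w < W) {
                const float* srow = src + (arma::uword)C * (a + k * (b + k * g));
                float* dst = x + (arma::uword)C * (d + (arma::uword)D * (h + (arma::uword)H * w));
                for (int c = 0; c < C; ++c) dst[c] += srow[c];
              }
            }
          }
        }
      }
}

static std::vector<float> to_float(const double* p, arma::uword n) {
  std::vector<float> out(n);
  for (arma::uword i = 0; i < n; ++i) out[i] = (float)p[i];
  return out;
}

static NumericVector to_double(const float* p, arma::uword n) {
  NumericVector out(n);
  for (arma::uword i = 0; i < n; ++i) out[i] = p[i];
  return out;
}

// reusable scratch buffers (single-threaded R session)
static std::vector<float>& scratch(int which, arma::uword n) {
  static std::vector<float> bufs[4];
  if (bufs[which].size() < n) bufs[which].resize(n);
  return bufs[which];
}

// pad a (C, D, H, W) float volume with a 1-voxel zero halo on the spatial axes
static float* pad1(const float* x, int C, int D, int H, int W, int slot) {
  const int Dp = D + 2, Hp = H + 2, Wp = W + 2;
  std::vector<float>& xp = scratch(slot, (arma::uword)C * Dp * Hp * Wp);
  std::fill(xp.begin(), xp.begin() + (arma::uword)C * Dp * Hp * Wp, 0.0f);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      const float* src = x + (arma::uword)C * ((arma::uword)D * (h + (arma::uword)H * w));
      float* dst = xp.data() + (arma::uword)C * (1 + (arma::uword)Dp * ((h + 1) + (arma::uword)Hp * (w + 1)));
      std::copy(src, src + (arma::uword)C * D, dst);
    }
  return xp.data();
}

// core of the k=3, s=1, p=1 convolution: y (Cout,D,H,W) = conv(x; W),
// weight matrix (Cout x 27*C) with column index c + C*(a + 3*(b + 3*g)).
static void conv3_core(const float* x, int C, int D, int H, int W,
                       const arma::fmat& Wm, int Cout, float* y) {
  const int Dp = D + 2, Hp = H + 2;
  float* xp = pad1(x, C, D, H, W, 0);
  std::fill(y, y + (arma::uword)Cout * D * H * W, 0.0f);
  const arma::uword ncolU = (arma::uword)Dp * Hp * W;
  arma::fmat Wg(9 * Cout, C);
  arma::fmat U(scratch(1, (arma::uword)9 * Cout * ncolU).data(),
               9 * Cout, ncolU, false, true);
  for (int g = 0; g < 3; ++g) {
    for (int b = 0; b < 3; ++b)
      for (int a = 0; a < 3; ++a)
        for (int c = 0; c < C; ++c)
          for (int co = 0; co < Cout; ++co)
            Wg(co + Cout * (a + 3 * b), c) = Wm(co, c + C * (a + 3 * (b + 3 * g)));
    // contiguous slab: wpad in [g, g+W)
    const arma::fmat S(xp + (arma::uword)C * Dp * Hp * g, C, ncolU, false, true);
    U = Wg * S;
    const arma::uword ldU = 9 * (arma::uword)Cout;
    for (int b = 0; b < 3; ++b)
      for (int a = 0; a < 3; ++a) {
        const arma::uword rowbase = Cout * (a + 3 * b);
        for (int ow = 0; ow < W; ++ow)
          for (int oh = 0; oh < H; ++oh) {
            const float* src = U.memptr() + rowbase +
              ldU * ((arma::uword)a + (arma::uword)Dp * ((oh + b) + (arma::uword)Hp * ow));
            float* dst = y + (arma::uword)Cout * ((arma::uword)D * (oh + (arma::uword)H * ow));
            for (int od = 0; od < D; ++od) {
              const float* s = src + ldU * od;
              float* d = dst + (arma::uword)Cout * od;
              for (int co = 0; co < Cout; ++co) d[co] += s[co];
            }
          }
      }
  }
}

// [[Rcpp::export]]
List cpp_conv3d_fw(NumericVector x, IntegerVector dims, NumericMatrix Wm,
                   NumericVector bias, int k, int stride, int pad) {
  const int C = dims[0], D = dims[1], H = dims[2], W = dims[3];
  const int Co = Wm.nrow();
  const int Do = out_dim_f(D, k, stride, pad), Ho = out_dim_f(H, k, stride, pad),
            Wo = out_dim_f(W, k, stride, pad);
  std::vector<float> xf = to_float(x.begin(), x.size());
  std::vector<float> Wf_store(to_float(Wm.begin(), (arma::uword)Wm.nrow() * Wm.ncol()));
  arma::fmat Wa(Wf_store.data(), Wm.nrow(), Wm.ncol(), false, true);
  NumericVector out((R_xlen_t)Co * Do * Ho * Wo);
  if (k == 3 && stride == 1 && pad == 1) {
    std::vector<float> y((arma::uword)Co * D * H * W);
    conv3_core(xf.data(), C, D, H, W, Wa, Co, y.data());
    double* op = out.begin();
    const arma::uword N = (arma::uword)D * H * W;
    for (arma::uword j = 0; j < N; ++j)
      for (int c = 0; c < Co; ++c)
        op[c + (arma::uword)Co * j] = y[c + (arma::uword)Co * j] + bias[c];
  } else {
    arma::fmat cols = im2col_f(xf.data(), C, D, H, W, k, stride, pad);
    arma::fmat y = Wa * cols;
    double* op = out.begin();
    for (arma::uword j = 0; j < y.n_cols; ++j)
      for (int c = 0; c < Co; ++c) op[c + (arma::uword)Co * j] = y(c, j) + bias[c];
  }
  out.attr("dim") = IntegerVector::create(Co, Do, Ho, Wo);
  return List::create(_["y"] = out,
                      _["dims"] = IntegerVector::create(Co, Do, Ho, Wo));
}

// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, IntegerVector dims, NumericMatrix Wm,
                   NumericVector gy, IntegerVector odims, int k, int stride,
                   int pad) {
  const int C = dims[0], D = dims[1], H = dims[2], W = dims[3];
  const int Co = odims[0];
  const arma::uword N = (arma::uword)odims[1] * odims[2] * odims[3];
  std::vector<float> xf = to_float(x.begin(), x.size());
  std::vector<float> gyf = to_float(gy.begin(), gy.size());
  std::vector<float> Wf_store(to_float(Wm.begin(), (arma::uword)Wm.nrow() * Wm.ncol()));
  arma::fmat Wa(Wf_store.data(), Wm.nrow(), Wm.ncol(), false, true);
  NumericVector gxv((R_xlen_t)C * D * H * W);
  NumericVector gWv((R_xlen_t)Wm.nrow() * Wm.ncol());
  NumericVector gb(Co);
  for (arma::uword j = 0; j < N; ++j)
    for (int c = 0; c < Co; ++c) gb[c] += gyf[c + (arma::uword)Co * j];

  if (k == 3 && stride == 1 && pad == 1) {
    // grad wrt input: convolution of gy with the offset-flipped transpose
    arma::fmat Wflip(C, 27 * Co);
    for (int g = 0; g < 3; ++g)
      for (int b = 0; b < 3; ++b)
        for (int a = 0; a < 3; ++a)
          for (int c = 0; c < C; ++c)
            for (int co = 0; co < Co; ++co)
              Wflip(c, co + Co * (a + 3 * (b + 3 * g))) =
                Wa(co, c + C * ((2 - a) + 3 * ((2 - b) + 3 * (2 - g))));
    std::vector<float> gx((arma::uword)C * D * H * W);
    conv3_core(gyf.data(), Co, D, H, W, Wflip, C, gx.data());
    for (arma::uword i = 0; i < gx.size(); ++i) gxv[i] = gx[i];

    // grad wrt weights: per-g sgemm of the scattered gy against input slabs
    const int Dp = D + 2, Hp = H + 2;
    float* xp = pad1(xf.data(), C, D, H, W, 2);
    const arma::uword ncolU = (arma::uword)Dp * Hp * W;
    arma::fmat Gs(scratch(3, (arma::uword)9 * Co * ncolU).data(),
                  9 * Co, ncolU, false, true);
    Gs.zeros();
    const arma::uword ldG = 9 * (arma::uword)Co;
    for (int b = 0; b < 3; ++b)
      for (int a = 0; a < 3; ++a) {
        const arma::uword rowbase = Co * (a + 3 * b);
        for (int ow = 0; ow < W; ++ow)
          for (int oh = 0; oh < H; ++oh) {
            float* dst = Gs.memptr() + rowbase +
              ldG * ((arma::uword)a + (arma::uword)Dp * ((oh + b) + (arma::uword)Hp * ow));
            const float* src = gyf.data() + (arma::uword)Co * ((arma::uword)D * (oh + (arma::uword)H * ow));
            for (int od = 0; od < D; ++od) {
              float* d = dst + ldG * od;
              const float* s = src + (arma::uword)Co * od;
              for (int co = 0; co < Co; ++co) d[co] = s[co];
            }
          }
      }
    arma::fmat gWs(9 * Co, C);
    for (int g = 0; g < 3; ++g) {
      const arma::fmat S(xp + (arma::uword)C * Dp * Hp * g, C, ncolU, false, true);
      gWs = Gs * S.t();
      for (int b = 0; b < 3; ++b)
        for (int a = 0; a < 3; ++a)
          for (int c = 0; c < C; ++c)
            for (int co = 0; co < Co; ++co)
              gWv[co + (R_xlen_t)Co * (c + C * (a + 3 * (b + 3 * g)))] =
                gWs(co + Co * (a + 3 * b), c);
    }
  } else {
    arma::fmat gym(gyf.data(), Co, N, false, true);
    arma::fmat cols = im2col_f(xf.data(), C, D, H, W, k, stride, pad);
    arma::fmat gW = gym * cols.t();
    arma::fmat gcols = Wa.t() * gym;
    std::vector<float> gx((arma::uword)C * D * H * W);
    col2im_f(gcols, gx.data(), C, D, H, W, k, stride, pad);
    for (arma::uword i = 0; i < gx.size(); ++i) gxv[i] = gx[i];
    for (arma::uword j = 0; j < gW.n_cols; ++j)
      for (int c = 0; c < Co; ++c)
        gWv[c + (R_xlen_t)Co * j] = gW(c, j);
  }
  gxv.attr("dim") = IntegerVector::create(C, D, H, W);
  gWv.attr("dim") = IntegerVector::create(Wm.nrow(), Wm.ncol());
  return List::create(_["gx"] = gxv, _["gW"] = gWv, _["gb"] = gb);
}

// Transposed convolution (k == stride, pad 0): output dims = stride * input.
// Weight layout (C_in x C_out*k^3).
// [[Rcpp::export]]
List cpp_convt3d_fw(NumericVector x, IntegerVector dims, NumericMatrix Wm,
                    NumericVector bias, int k, int stride) {
  const int C = dims[0], D = dims[1], H = dims[2], W = dims[3];
  const int Co = Wm.ncol() / (k * k * k);
  const int Do = D * stride, Ho = H * stride, Wo = W * stride;
  const arma::uword N = (arma::uword)D * H * W;
  std::vector<float> xf = to_float(x.begin(), x.size());
  std::vector<float> Wf_store(to_float(Wm.begin(), (arma::uword)Wm.nrow() * Wm.ncol()));
  arma::fmat Wa(Wf_store.data(), Wm.nrow(), Wm.ncol(), false, true);
  arma::fmat xm(xf.data(), C, N, false, true);
  arma::fmat ocols = Wa.t() * xm;
  std::vector<float> y((arma::uword)Co * Do * Ho * Wo);
  col2im_f(ocols, y.data(), Co, Do, Ho, Wo, k, stride, 0);
  NumericVector out((R_xlen_t)y.size());
  const arma::uword No = (arma::uword)Do * Ho * Wo;
  for (arma::uword j = 0; j < No; ++j)
    for (int c = 0; c < Co; ++c)
      out[c + (arma::uword)Co * j] = y[c + (arma::uword)Co * j] + bias[c];
  out.attr("dim") = IntegerVector::create(Co, Do, Ho, Wo);
  return List::create(_["y"] = out,
                      _["dims"] = IntegerVector::create(Co, Do, Ho, Wo));
}

// [[Rcpp::export]]
List cpp_convt3d_bw(NumericVector x, IntegerVector dims, NumericMatrix Wm,
                    NumericVector gy, int k, int stride) {
  const int C = dims[0], D = dims[1], H = dims[2], W = dims[3];
  const int Co = Wm.ncol() / (k * k * k);
  const int Do = D * stride, Ho = H * stride, Wo = W * stride;
  const arma::uword N = (arma::uword)D * H * W;
  std::vector<float> xf = to_float(x.begin(), x.size());
  std::vector<float> gyf = to_float(gy.begin(), gy.size());
  std::vector<float> Wf_store(to_float(Wm.begin(), (arma::uword)Wm.nrow() * Wm.ncol()));
  arma::fmat Wa(Wf_store.data(), Wm.nrow(), Wm.ncol(), false, true);
  arma::fmat xm(xf.data(), C, N, false, true);
  arma::fmat gcols = im2col_f(gyf.data(), Co, Do, Ho, Wo, k, stride, 0);
  arma::fmat gx = Wa * gcols;
  arma::fmat gW = xm * gcols.t();
  NumericVector gxv((R_xlen_t)C * D * H * W);
  std::copy(gx.begin(), gx.end(), gxv.begin());
  gxv.attr("dim") = IntegerVector::create(C, D, H, W);
  NumericVector gWv((R_xlen_t)Wm.nrow() * Wm.ncol());
  std::copy(gW.begin(), gW.end(), gWv.begin());
  gWv.attr("dim") = IntegerVector::create(Wm.nrow(), Wm.ncol());
  NumericVector gb(Co);
  const arma::uword No = (arma::uword)Do * Ho * Wo;
  for (arma::uword j = 0; j < No; ++j)
    for (int c = 0; c < Co; ++c) gb[c] += gyf[c + (arma::uword)Co * j];
  return List::create(_["gx"] = gxv, _["gW"] = gWv, _["gb"] = gb);
}
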