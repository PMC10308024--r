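// Trilinear factor-2 upsampling with its exact transpose, coordinate-based
// resampling, brute-force Hausdorff distance, and vote counting.
// Array layout: channel-first (C, D, H, W), column-major as stored by R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct LinW { int i0, i1; double w0, w1; };

static inline LinW lin_weights(double s, int n) {
  LinW r;
  if (s <= 0) { r.i0 = r.i1 = 0; r.w0 = 1; r.w1 = 0; return r; }
  if (s >= n - 1) { r.i0 = r.i1 = n - 1; r.w0 = 1; r.w1 = 0; return r; }
  r.i0 = (int)std::floor(s); r.i1 = r.i0 + 1;
  r.w1 = s - r.i0; r.w0 = 1.0 - r.w1;
  return r;
}

// Factor-2 trilinear upsampling (align-corners = FALSE convention):
// output voxel o samples input coordinate o/2 - 0.25, clamped at borders.
// [[Rcpp::export]]
NumericVector cpp_upsample2_fw(NumericVector x, IntegerVector dims) {
  const int C = dims[0], D = dims[1], H = dims[2], W = dims[3];
  const int Do = 2 * D, Ho = 2 * H, Wo = 2 * W;
  NumericVector y((R_xlen_t)C * Do * Ho * Wo);
  const double* xp = x.begin(); double* yp = y.begin();
  for (int ow = 0; ow < Wo; ++ow) {
    LinW lw = lin_weights(ow / 2.0 - 0.25, W);
    for (int oh = 0; oh < Ho; ++oh) {
      LinW lh = lin_weights(oh / 2.0 - 0.25, H);
      for (int od = 0; od < Do; ++od) {
        LinW ld = lin_weights(od / 2.0 - 0.25, D);
        double* dst = yp + (arma::uword)C * (od + (arma::uword)Do * (oh + (arma::uword)Ho * ow));
        for (int c = 0; c < C; ++c) {
          double acc = 0;
          for (int dw = 0; dw < 2; ++dw) {
            int iw = dw ? lw.i1 : lw.i0; double ww = dw ? lw.w1 : lw.w0;
            if (ww == 0) continue;
            for (int dh = 0; dh < 2; ++dh) {
              int ih = dh ? lh.i1 : lh.i0; double wh = dh ? lh.w1 : lh.w0;
              if (wh == 0) continue;
              for (int dd = 0; dd < 2; ++dd) {
                int id = dd ? ld.i1 : ld.i0; double wd = dd ? ld.w1 : ld.w0;
                if (wd == 0) continue;
                acc += ww * wh * wd *
                       xp[c + (arma::uword)C * (id + (arma::uword)D * (ih + (arma::uword)H * iw))];
              }
            }
          }
          dst[c] = acc;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(C, Do, Ho, Wo);
  return y;
}

// Exact transpose of cpp_upsample2_fw.
// [[Rcpp::export]]
NumericVector cpp_upsample2_bw(NumericVector gy, IntegerVector dims_in) {
  const int C = dims_in[0], D = dims_in[1], H = dims_in[2], W = dims_in[3];
  const int Do = 2 * D, Ho = 2 * H, Wo = 2 * W;
  NumericVector gx((R_xlen_t)C * D * H * W);
  const double* gp = gy.begin(); double* xp = gx.begin();
  for (int ow = 0; ow < Wo; ++ow) {
    LinW lw = lin_weights(ow / 2.0 - 0.25, W);
    for (int oh = 0; oh < Ho; ++oh) {
      LinW lh = lin_weights(oh / 2.0 - 0.25, H);
      for (int od = 0; od < Do; ++od) {
        LinW ld = lin_weights(od / 2.0 - 0.25, D);
        const double* src = gp + (arma::uword)C * (od + (arma::uword)Do * (oh + (arma::uword)Ho * ow));
        for (int c = 0; c < C; ++c) {
          double g = src[c];
          if (g == 0) continue;
          for (int dw = 0; dw < 2; ++dw) {
            int iw = dw ? lw.i1 : lw.i0; double ww = dw ? lw.w1 : lw.w0;
            if (ww == 0) continue;
            for (int dh = 0; dh < 2; ++dh) {
              int ih = dh ? lh.i1 : lh.i0; double wh = dh ? lh.w1 : lh.w0;
              if (wh == 0) continue;
              for (int dd = 0; dd < 2; ++dd) {
                int id = dd ? ld.i1 : ld.i0; double wd = dd ? ld.w1 : ld.w0;
                if (wd == 0) continue;
                xp[c + (arma::uword)C * (id + (arma::uword)D * (ih + (arma::uword)H * iw))] +=
                    g * ww * wh * wd;
              }
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(C, D, H, W);
  return gx;
}

// Sample a single 3D volume (D,H,W) at arbitrary 0-based voxel coordinates.
// coords: 3 x N matrix. method 0 = nearest, 1 = trilinear. Coordinates more
// than half a voxel outside the grid return `fill`.
// [[Rcpp::export]]
NumericVector cpp_sample_at(NumericVector x, IntegerVector dims,
                            NumericMatrix coords, int method, double fill) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const R_xlen_t N = coords.ncol();
  NumericVector out(N);
  const double* xp = x.begin();
  for (R_xlen_t j = 0; j < N; ++j) {
    const double cd = coords(0, j), ch = coords(1, j), cw = coords(2, j);
    if (cd < -0.5 || cd > D - 0.5 || ch < -0.5 || ch > H - 0.5 ||
        cw < -0.5 || cw > W - 0.5) {
      out[j] = fill;
      continue;
    }
    if (method == 0) {
      int id = (int)std::lround(cd), ih = (int)std::lround(ch),
          iw = (int)std::lround(cw);
      id = std::min(std::max(id, 0), D - 1);
      ih = std::min(std::max(ih, 0), H - 1);
      iw = std::min(std::max(iw, 0), W - 1);
      out[j] = xp[(arma::uword)id + (arma::uword)D * (ih + (arma::uword)H * iw)];
    } else {
      LinW ld = lin_weights(cd, D), lh = lin_weights(ch, H), lw = lin_weights(cw, W);
      double acc = 0;
      for (int dw = 0; dw < 2; ++dw) {
        int iw = dw ? lw.i1 : lw.i0; double ww = dw ? lw.w1 : lw.w0;
        if (ww == 0) continue;
        for (int dh = 0; dh < 2; ++dh) {
          int ih = dh ? lh.i1 : lh.i0; double wh = dh ? lh.w1 : lh.w0;
          if (wh == 0) continue;
          for (int dd = 0; dd < 2; ++dd) {
            int id = dd ? ld.i1 : ld.i0; double wd = dd ? ld.w1 : ld.w0;
            if (wd == 0) continue;
            acc += ww * wh * wd *
                   xp[(arma::uword)id + (arma::uword)D * (ih + (arma::uword)H * iw)];
          }
        }
      }
      out[j] = acc;
    }
  }
  return out;
}

// Directed Hausdorff distances between two point sets (rows = points, already
// scaled to physical units). Returns c(hd(X,Y), hd(Y,X)).
// [[Rcpp::export]]
NumericVector cpp_hausdorff(NumericMatrix X, NumericMatrix Y) {
  const R_xlen_t n = X.nrow(), m = Y.nrow(), p = X.ncol();
  double hxy = 0, hyx = 0;
  std::vector<double> miny(m, R_PosInf);
  for (R_xlen_t i = 0; i < n; ++i) {
    double mn = R_PosInf;
    for (R_xlen_t j = 0; j < m; ++j) {
      double s = 0;
      for (R_xlen_t c = 0; c < p; ++c) {
        const double d = X(i, c) - Y(j, c);
        s += d * d;
      }
      if (s < mn) mn = s;
      if (s < miny[j]) miny[j] = s;
    }
    if (mn > hxy) hxy = mn;
  }
  for (R_xlen_t j = 0; j < m; ++j)
    if (miny[j] > hyx) hyx = miny[j];
  return NumericVector::create(std::sqrt(hxy), std::sqrt(hyx));
}

// Per-class vote counts from a stack of label votes (n_votes x n_voxels).
// classes: the class ids to count. Returns (n_classes x n_voxels) matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_vote_counts(IntegerMatrix votes, IntegerVector classes) {
  const R_xlen_t nv = votes.nrow(), N = votes.ncol(), K = classes.size();
  std::map<int, int> idx;
  for (R_xlen_t k = 0; k < K; ++k) idx[classes[k]] = k;
  IntegerMatrix out(K, N);
  for (R_xlen_t j = 0; j < N; ++j)
    for (R_xlen_t i = 0; i < nv; ++i) {
      std::map<int, int>::iterator it = idx.find(votes(i, j));
      if (it != idx.end()) out(it->second, j)++;
    }
  return out;
}
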