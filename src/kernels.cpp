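#include <Rcpp.h>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// Tensor layout everywhere: column-major R array (C, D, H, W, N) with the
// channel axis fastest. 2D operations pass D = 1 and kd = 1.

// Patch matrix for convolution-as-GEMM. Rows index (cin, kd, kh, kw) with cin
// fastest; columns index (od, oh, ow, n) with od fastest. Out-of-range taps
// (zero padding) stay 0.
// [[Rcpp::export]]
NumericMatrix im2col_nd(NumericVector x, IntegerVector xdim, IntegerVector k,
                        IntegerVector stride, IntegerVector pad) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3], N = xdim[4];
  const int kd = k[0], kh = k[1], kw = k[2];
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int pd = pad[0], ph = pad[1], pw = pad[2];
  const int Do = (D + 2 * pd - kd) / sd + 1;
  const int Ho = (H + 2 * ph - kh) / sh + 1;
  const int Wo = (W + 2 * pw - kw) / sw + 1;
  const int P = C * kd * kh * kw;
  const R_xlen_t L = (R_xlen_t)Do * Ho * Wo;
  NumericMatrix col(P, L * N);
  const double *xp = REAL(x);
  double *cp = REAL(col);
  const R_xlen_t strideD = C, strideH = (R_xlen_t)C * D,
                 strideW = (R_xlen_t)C * D * H, strideN = (R_xlen_t)C * D * H * W;
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        for (int od = 0; od < Do; ++od) {
          R_xlen_t colIdx = ((R_xlen_t)n * L) + (R_xlen_t)ow * Ho * Do + (R_xlen_t)oh * Do + od;
          double *dst = cp + colIdx * P;
          for (int w = 0; w < kw; ++w) {
            int iw = ow * sw - pw + w;
            for (int h = 0; h < kh; ++h) {
              int ih = oh * sh - ph + h;
              for (int d = 0; d < kd; ++d) {
                int id = od * sd - pd + d;
                double *out = dst + ((R_xlen_t)w * kh * kd + (R_xlen_t)h * kd + d) * C;
                if (id < 0 || id >= D || ih < 0 || ih >= H || iw < 0 || iw >= W) {
                  for (int c = 0; c < C; ++c) out[c] = 0.0;
                } else {
                  const double *src = xp + (R_xlen_t)n * strideN + iw * strideW +
                                      ih * strideH + id * strideD;
                  for (int c = 0; c < C; ++c) out[c] = src[c];
                }
              }
            }
          }
        }
      }
    }
  }
  return col;
}

// Adjoint of im2col_nd: scatter-add patch gradients back onto the input grid.
// [[Rcpp::export]]
NumericVector col2im_nd(NumericMatrix dcol, IntegerVector xdim, IntegerVector k,
                        IntegerVector stride, IntegerVector pad) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3], N = xdim[4];
  const int kd = k[0], kh = k[1], kw = k[2];
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int pd = pad[0], ph = pad[1], pw = pad[2];
  const int Do = (D + 2 * pd - kd) / sd + 1;
  const int Ho = (H + 2 * ph - kh) / sh + 1;
  const int Wo = (W + 2 * pw - kw) / sw + 1;
  const int P = C * kd * kh * kw;
  const R_xlen_t L = (R_xlen_t)Do * Ho * Wo;
  NumericVector dx((R_xlen_t)C * D * H * W * N);
  double *xp = REAL(dx);
  const double *cp = REAL(dcol);
  const R_xlen_t strideD = C, strideH = (R_xlen_t)C * D,
                 strideW = (R_xlen_t)C * D * H, strideN = (R_xlen_t)C * D * H * W;
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        for (int od = 0; od < Do; ++od) {
          R_xlen_t colIdx = ((R_xlen_t)n * L) + (R_xlen_t)ow * Ho * Do + (R_xlen_t)oh * Do + od;
          const double *src0 = cp + colIdx * P;
          for (int w = 0; w < kw; ++w) {
            int iw = ow * sw - pw + w;
            if (iw < 0 || iw >= W) continue;
            for (int h = 0; h < kh; ++h) {
              int ih = oh * sh - ph + h;
              if (ih < 0 || ih >= H) continue;
              for (int d = 0; d < kd; ++d) {
                int id = od * sd - pd + d;
                if (id < 0 || id >= D) continue;
                const double *src = src0 + ((R_xlen_t)w * kh * kd + (R_xlen_t)h * kd + d) * C;
                double *out = xp + (R_xlen_t)n * strideN + iw * strideW +
                              ih * strideH + id * strideD;
                for (int c = 0; c < C; ++c) out[c] += src[c];
              }
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = xdim;
  return dx;
}

// Group normalization over a channel-first tensor (C, spatial..., N):
// per sample, contiguous channel groups standardized by their own mean and
// population variance over (group channels x spatial), then per-channel
// affine. Returns y, xhat and the per-(group, sample) inverse sd.
// [[Rcpp::export]]
List gn_forward(NumericVector x, int C, double Sd, int N, int groups,
                NumericVector gamma, NumericVector beta, double eps) {
  const R_xlen_t S = (R_xlen_t)Sd;
  const int cg = C / groups;
  const R_xlen_t m = (R_xlen_t)cg * S;
  NumericVector y(x.size()), xhat(x.size());
  NumericMatrix inv(groups, N), mu(groups, N);
  const double *xp = REAL(x);
  double *yp = REAL(y), *hp = REAL(xhat);
  for (int n = 0; n < N; ++n) {
    const R_xlen_t base_n = (R_xlen_t)n * C * S;
    for (int g = 0; g < groups; ++g) {
      const int c0 = g * cg;
      double s1 = 0, s2 = 0;
      for (R_xlen_t s = 0; s < S; ++s) {
        const double *p = xp + base_n + s * C + c0;
        for (int c = 0; c < cg; ++c) { s1 += p[c]; s2 += p[c] * p[c]; }
      }
      const double mean = s1 / m;
      double var = s2 / m - mean * mean;
      if (var < 0) var = 0;
      const double isd = 1.0 / std::sqrt(var + eps);
      mu(g, n) = mean; inv(g, n) = isd;
      for (R_xlen_t s = 0; s < S; ++s) {
        const R_xlen_t off = base_n + s * C + c0;
        for (int c = 0; c < cg; ++c) {
          const double h = (xp[off + c] - mean) * isd;
          hp[off + c] = h;
          yp[off + c] = gamma[c0 + c] * h + beta[c0 + c];
        }
      }
    }
  }
  y.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["xhat"] = xhat, _["inv"] = inv, _["mu"] = mu);
}

// [[Rcpp::export]]
List gn_backward(NumericVector dy, NumericVector xhat, NumericMatrix inv,
                 int C, double Sd, int N, int groups, NumericVector gamma) {
  const R_xlen_t S = (R_xlen_t)Sd;
  const int cg = C / groups;
  const R_xlen_t m = (R_xlen_t)cg * S;
  NumericVector dx(dy.size()), dgamma(C), dbeta(C);
  const double *dp = REAL(dy), *hp = REAL(xhat);
  double *xp = REAL(dx), *dgp = REAL(dgamma), *dbp = REAL(dbeta);
  for (int n = 0; n < N; ++n) {
    const R_xlen_t base_n = (R_xlen_t)n * C * S;
    for (int g = 0; g < groups; ++g) {
      const int c0 = g * cg;
      double s1 = 0, s2 = 0;
      for (R_xlen_t s = 0; s < S; ++s) {
        const R_xlen_t off = base_n + s * C + c0;
        for (int c = 0; c < cg; ++c) {
          const double dxh = dp[off + c] * gamma[c0 + c];
          s1 += dxh;
          s2 += dxh * hp[off + c];
          dgp[c0 + c] += dp[off + c] * hp[off + c];
          dbp[c0 + c] += dp[off + c];
        }
      }
      const double isd = inv(g, n), a1 = s1 / m, a2 = s2 / m;
      for (R_xlen_t s = 0; s < S; ++s) {
        const R_xlen_t off = base_n + s * C + c0;
        for (int c = 0; c < cg; ++c) {
          const double dxh = dp[off + c] * gamma[c0 + c];
          xp[off + c] = isd * (dxh - a1 - hp[off + c] * a2);
        }
      }
    }
  }
  dx.attr("dim") = dy.attr("dim");
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Max pooling over the three spatial axes (per channel, per sample), VALID
// windows: out = floor((in - k)/s) + 1. Returns pooled values and the 1-based
// linear argmax index into x for the backward pass.
// [[Rcpp::export]]
List maxpool_fwd(NumericVector x, IntegerVector xdim, IntegerVector k,
                 IntegerVector stride) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3], N = xdim[4];
  const int kd = k[0], kh = k[1], kw = k[2];
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int Do = (D - kd) / sd + 1;
  const int Ho = (H - kh) / sh + 1;
  const int Wo = (W - kw) / sw + 1;
  const R_xlen_t ylen = (R_xlen_t)C * Do * Ho * Wo * N;
  NumericVector y(ylen);
  NumericVector amax(ylen);  // store as double to allow > 2^31 inputs
  const double *xp = REAL(x);
  double *yp = REAL(y), *ap = REAL(amax);
  const R_xlen_t sD = C, sH = (R_xlen_t)C * D, sW = (R_xlen_t)C * D * H,
                 sN = (R_xlen_t)C * D * H * W;
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh)
        for (int od = 0; od < Do; ++od)
          for (int c = 0; c < C; ++c) {
            double best = R_NegInf; R_xlen_t bidx = -1;
            for (int w = 0; w < kw; ++w)
              for (int h = 0; h < kh; ++h)
                for (int d = 0; d < kd; ++d) {
                  R_xlen_t idx = (R_xlen_t)n * sN + (ow * sw + w) * sW +
                                 (oh * sh + h) * sH + (od * sd + d) * sD + c;
                  if (xp[idx] > best) { best = xp[idx]; bidx = idx; }
                }
            yp[o] = best; ap[o] = (double)(bidx + 1); ++o;
          }
  // reorder output index: we filled with c fastest inside od/oh/ow/n, but the
  // canonical layout needs (C, Do, Ho, Wo, N) with C fastest -- that is what
  // the fill order above produces already.
  y.attr("dim") = IntegerVector::create(C, Do, Ho, Wo, N);
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd(NumericVector dy, NumericVector argmax, double xlen) {
  NumericVector dx((R_xlen_t)xlen);
  const double *dp = REAL(dy), *ap = REAL(argmax);
  double *xp = REAL(dx);
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) xp[(R_xlen_t)ap[i] - 1] += dp[i];
  return dx;
}

// Rasterize a waveform trace onto an n x n binary pixel grid and area-average
// down to side x side in one pass (the full grid is never materialized).
// ypix: 0-based pixel row per sample (row 0 = top). Consecutive samples are
// joined by a discrete (Bresenham, midpoint-split) line: each segment spans
// two adjacent columns; within a column the covered rows form one contiguous
// run, so runs are accumulated as intervals. Output value = covered area of
// the block / block area, in [0, 1].
// [[Rcpp::export]]
NumericMatrix rasterize_trace(IntegerVector ypix, int side) {
  const int n = ypix.size();
  NumericMatrix out(side, side);
  const double sc = (double)side / (double)n;
  std::vector<int> rbin; std::vector<double> rw;  // scratch per run
  for (int j = 0; j < n; ++j) {
    int lo = ypix[j], hi = ypix[j];
    if (j > 0) {  // tail of incoming segment (j-1 -> j)
      int dy = ypix[j] - ypix[j - 1];
      int npix = std::abs(dy) + 1;
      int nhead = (npix + 1) / 2;           // pixels kept in column j-1
      int ntail = npix - nhead;             // pixels landing in column j
      if (ntail > 0) {
        int s = dy > 0 ? 1 : (dy < 0 ? -1 : 0);
        int start = ypix[j] - s * (ntail - 1);
        lo = std::min(lo, std::min(start, ypix[j]));
        hi = std::max(hi, std::max(start, ypix[j]));
      }
    }
    if (j < n - 1) {  // head of outgoing segment (j -> j+1)
      int dy = ypix[j + 1] - ypix[j];
      int npix = std::abs(dy) + 1;
      int nhead = (npix + 1) / 2;
      int s = dy > 0 ? 1 : (dy < 0 ? -1 : 0);
      int end = ypix[j] + s * (nhead - 1);
      lo = std::min(lo, std::min(end, ypix[j]));
      hi = std::max(hi, std::max(end, ypix[j]));
    }
    if (lo < 0) lo = 0;
    if (hi > n - 1) hi = n - 1;
    // column j overlaps output columns [c0, c1] with fractional weights
    int c0 = (int)std::floor(j * sc);
    int c1 = (int)std::floor(((j + 1) * sc) * (1 - 1e-15));
    if (c1 >= side) c1 = side - 1;
    for (int y = lo; y <= hi; ++y) {
      int r0 = (int)std::floor(y * sc);
      int r1 = (int)std::floor(((y + 1) * sc) * (1 - 1e-15));
      if (r1 >= side) r1 = side - 1;
      for (int r = r0; r <= r1; ++r) {
        double ov_r = std::min((double)(r + 1) / sc, (double)(y + 1)) -
                      std::max((double)r / sc, (double)y);
        for (int c = c0; c <= c1; ++c) {
          double ov_c = std::min((double)(c + 1) / sc, (double)(j + 1)) -
                        std::max((double)c / sc, (double)j);
          out(r, c) += ov_r * ov_c;
        }
      }
    }
  }
  const double a = sc * sc;
  for (int i = 0; i < side * side; ++i) out[i] *= a;
  // clamp tiny float overshoot
  for (int i = 0; i < side * side; ++i) {
    if (out[i] > 1.0) out[i] = 1.0;
    if (out[i] < 0.0) out[i] = 0.0;
  }
  return out;
}
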