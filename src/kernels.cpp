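#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Volumetric tensors are R arrays with dim (D, H, W, C, N), column-major.
// Convolution weights have dim (k, k, k, Cin, Cout).

static inline R_xlen_t off5(int d, int h, int w, int c, int n,
                            int D, int H, int W, int C) {
  return d + (R_xlen_t)D * (h + (R_xlen_t)H * (w + (R_xlen_t)W * (c + (R_xlen_t)C * n)));
}

static void dims5(const NumericVector& x, int* d) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 5) stop("expected a 5-d array (D,H,W,C,N)");
  for (int i = 0; i < 5; ++i) d[i] = dm[i];
}

static inline int out_len(int D, int k, int s, int p) {
  return (D + 2 * p - k) / s + 1;
}

// Valid output range [o0, o1] such that o*stride + koff - pad stays inside
// [0, L): koff is the kernel offset along that axis.
static inline void orange(int L, int Lo, int koff, int stride, int pad,
                          int* o0, int* o1) {
  int lo = pad - koff;               // need o*stride >= pad - koff
  int q0 = (lo <= 0) ? 0 : (lo + stride - 1) / stride;
  int hi = L - 1 + pad - koff;       // need o*stride <= L-1+pad-koff
  int q1 = (hi < 0) ? -1 : hi / stride;
  if (q1 > Lo - 1) q1 = Lo - 1;
  *o0 = q0; *o1 = q1;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad) {
  int xd[5]; dims5(x, xd);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 5) stop("weight must be 5-d (k,k,k,Cin,Cout)");
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3], N = xd[4];
  const int k = wd[0], Ci = wd[3], Co = wd[4];
  if (Ci != C) stop("input channels do not match weight");
  const int Do = out_len(D, k, stride, pad), Ho = out_len(H, k, stride, pad),
            Wo = out_len(W, k, stride, pad);
  if (Do <= 0 || Ho <= 0 || Wo <= 0) stop("convolution output would be empty");
  NumericVector out((R_xlen_t)Do * Ho * Wo * Co * N);
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, Co, N);
  const double* xp = REAL(x);
  const double* wp = REAL(w);
  const double* bp = REAL(b);
  double* op = REAL(out);
  const R_xlen_t oslab = (R_xlen_t)Do * Ho * Wo;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      double* obase = op + oslab * (co + (R_xlen_t)Co * n);
      const double bias = bp[co];
      for (R_xlen_t i = 0; i < oslab; ++i) obase[i] = bias;
      for (int ci = 0; ci < C; ++ci) {
        const double* xbase = xp + (R_xlen_t)D * H * W * (ci + (R_xlen_t)C * n);
        const double* wbase = wp + (R_xlen_t)k * k * k * (ci + (R_xlen_t)Ci * co);
        for (int kw = 0; kw < k; ++kw) {
          int w0, w1; orange(W, Wo, kw, stride, pad, &w0, &w1);
          for (int kh = 0; kh < k; ++kh) {
            int h0, h1; orange(H, Ho, kh, stride, pad, &h0, &h1);
            for (int kd = 0; kd < k; ++kd) {
              int d0, d1; orange(D, Do, kd, stride, pad, &d0, &d1);
              const double wv = wbase[kd + k * (kh + k * kw)];
              if (wv == 0.0) continue;
              for (int wo = w0; wo <= w1; ++wo) {
                const int wi = wo * stride + kw - pad;
                for (int ho = h0; ho <= h1; ++ho) {
                  const int hi = ho * stride + kh - pad;
                  const double* xrow = xbase + (R_xlen_t)D * (hi + (R_xlen_t)H * wi) + kd - pad;
                  double* orow = obase + (R_xlen_t)Do * (ho + (R_xlen_t)Ho * wo);
                  if (stride == 1) {
                    for (int dz = d0; dz <= d1; ++dz) orow[dz] += wv * xrow[dz];
                  } else {
                    for (int dz = d0; dz <= d1; ++dz) orow[dz] += wv * xrow[dz * stride];
                  }
                }
              }
            }
          }
        }
      }
    }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_bwd_input(NumericVector gout, NumericVector w,
                                   IntegerVector xdim, int stride, int pad) {
  int gd[5]; dims5(gout, gd);
  IntegerVector wd = w.attr("dim");
  const int Do = gd[0], Ho = gd[1], Wo = gd[2], Co = gd[3], N = gd[4];
  const int k = wd[0], Ci = wd[3];
  const int D = xdim[0], H = xdim[1], W = xdim[2];
  NumericVector gx((R_xlen_t)D * H * W * Ci * N);
  gx.attr("dim") = IntegerVector::create(D, H, W, Ci, N);
  const double* gp = REAL(gout);
  const double* wp = REAL(w);
  double* xp = REAL(gx);
  const R_xlen_t oslab = (R_xlen_t)Do * Ho * Wo;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      const double* gbase = gp + oslab * (co + (R_xlen_t)Co * n);
      for (int ci = 0; ci < Ci; ++ci) {
        double* xbase = xp + (R_xlen_t)D * H * W * (ci + (R_xlen_t)Ci * n);
        const double* wbase = wp + (R_xlen_t)k * k * k * (ci + (R_xlen_t)Ci * co);
        for (int kw = 0; kw < k; ++kw) {
          int w0, w1; orange(W, Wo, kw, stride, pad, &w0, &w1);
          for (int kh = 0; kh < k; ++kh) {
            int h0, h1; orange(H, Ho, kh, stride, pad, &h0, &h1);
            for (int kd = 0; kd < k; ++kd) {
              int d0, d1; orange(D, Do, kd, stride, pad, &d0, &d1);
              const double wv = wbase[kd + k * (kh + k * kw)];
              if (wv == 0.0) continue;
              for (int wo = w0; wo <= w1; ++wo) {
                const int wi = wo * stride + kw - pad;
                for (int ho = h0; ho <= h1; ++ho) {
                  const int hi = ho * stride + kh - pad;
                  double* xrow = xbase + (R_xlen_t)D * (hi + (R_xlen_t)H * wi) + kd - pad;
                  const double* grow = gbase + (R_xlen_t)Do * (ho + (R_xlen_t)Ho * wo);
                  if (stride == 1) {
                    for (int dz = d0; dz <= d1; ++dz) xrow[dz] += wv * grow[dz];
                  } else {
                    for (int dz = d0; dz <= d1; ++dz) xrow[dz * stride] += wv * grow[dz];
                  }
                }
              }
            }
          }
        }
      }
    }
  return gx;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd_weight(NumericVector gout, NumericVector x,
                           IntegerVector wdim, int stride, int pad) {
  int gd[5]; dims5(gout, gd);
  int xd[5]; dims5(x, xd);
  const int Do = gd[0], Ho = gd[1], Wo = gd[2], Co = gd[3], N = gd[4];
  const int D = xd[0], H = xd[1], W = xd[2], Ci = xd[3];
  const int k = wdim[0];
  NumericVector gw((R_xlen_t)k * k * k * Ci * Co);
  gw.attr("dim") = wdim;
  NumericVector gb(Co);
  const double* gp = REAL(gout);
  const double* xp = REAL(x);
  double* wp = REAL(gw);
  double* bp = REAL(gb);
  const R_xlen_t oslab = (R_xlen_t)Do * Ho * Wo;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      const double* gbase = gp + oslab * (co + (R_xlen_t)Co * n);
      double bacc = 0.0;
      for (R_xlen_t i = 0; i < oslab; ++i) bacc += gbase[i];
      bp[co] += bacc;
      for (int ci = 0; ci < Ci; ++ci) {
        const double* xbase = xp + (R_xlen_t)D * H * W * (ci + (R_xlen_t)Ci * n);
        double* wbase = wp + (R_xlen_t)k * k * k * (ci + (R_xlen_t)Ci * co);
        for (int kw = 0; kw < k; ++kw) {
          int w0, w1; orange(W, Wo, kw, stride, pad, &w0, &w1);
          for (int kh = 0; kh < k; ++kh) {
            int h0, h1; orange(H, Ho, kh, stride, pad, &h0, &h1);
            for (int kd = 0; kd < k; ++kd) {
              int d0, d1; orange(D, Do, kd, stride, pad, &d0, &d1);
              double acc = 0.0;
              for (int wo = w0; wo <= w1; ++wo) {
                const int wi = wo * stride + kw - pad;
                for (int ho = h0; ho <= h1; ++ho) {
                  const int hi = ho * stride + kh - pad;
                  const double* xrow = xbase + (R_xlen_t)D * (hi + (R_xlen_t)H * wi) + kd - pad;
                  const double* grow = gbase + (R_xlen_t)Do * (ho + (R_xlen_t)Ho * wo);
                  if (stride == 1) {
                    for (int dz = d0; dz <= d1; ++dz) acc += grow[dz] * xrow[dz];
                  } else {
                    for (int dz = d0; dz <= d1; ++dz) acc += grow[dz] * xrow[dz * stride];
                  }
                }
              }
              wbase[kd + k * (kh + k * kw)] += acc;
            }
          }
        }
      }
    }
  return List::create(_["gw"] = gw, _["gb"] = gb);
}

// Trilinear upsampling by an integer factor, half-pixel centre alignment
// (align_corners = FALSE convention). Source coordinate of output voxel z is
// (z + 0.5)/f - 0.5, clamped to the valid range.
static inline void lin_coef(int zo, int f, int D, int* z0, int* z1, double* t) {
  double src = (zo + 0.5) / (double)f - 0.5;
  if (src < 0) src = 0;
  if (src > D - 1) src = D - 1;
  *z0 = (int)std::floor(src);
  *z1 = std::min(*z0 + 1, D - 1);
  *t = src - *z0;
}

// [[Rcpp::export]]
NumericVector cpp_upsample3d_fwd(NumericVector x, int factor) {
  int xd[5]; dims5(x, xd);
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3], N = xd[4];
  const int Do = D * factor, Ho = H * factor, Wo = W * factor;
  NumericVector out((R_xlen_t)Do * Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, C, N);
  const double* xp = REAL(x);
  double* op = REAL(out);
  std::vector<int> d0(Do), d1(Do), h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> td(Do), th(Ho), tw(Wo);
  for (int i = 0; i < Do; ++i) lin_coef(i, factor, D, &d0[i], &d1[i], &td[i]);
  for (int i = 0; i < Ho; ++i) lin_coef(i, factor, H, &h0[i], &h1[i], &th[i]);
  for (int i = 0; i < Wo; ++i) lin_coef(i, factor, W, &w0[i], &w1[i], &tw[i]);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h)
          for (int d = 0; d < Do; ++d) {
            const double a = td[d], b = th[h], g = tw[w];
            double v =
              (1-a)*(1-b)*(1-g) * xp[off5(d0[d], h0[h], w0[w], c, n, D, H, W, C)] +
              a*(1-b)*(1-g)     * xp[off5(d1[d], h0[h], w0[w], c, n, D, H, W, C)] +
              (1-a)*b*(1-g)     * xp[off5(d0[d], h1[h], w0[w], c, n, D, H, W, C)] +
              a*b*(1-g)         * xp[off5(d1[d], h1[h], w0[w], c, n, D, H, W, C)] +
              (1-a)*(1-b)*g     * xp[off5(d0[d], h0[h], w1[w], c, n, D, H, W, C)] +
              a*(1-b)*g         * xp[off5(d1[d], h0[h], w1[w], c, n, D, H, W, C)] +
              (1-a)*b*g         * xp[off5(d0[d], h1[h], w1[w], c, n, D, H, W, C)] +
              a*b*g             * xp[off5(d1[d], h1[h], w1[w], c, n, D, H, W, C)];
            op[off5(d, h, w, c, n, Do, Ho, Wo, C)] = v;
          }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample3d_bwd(NumericVector gout, IntegerVector xdim, int factor) {
  int gd[5]; dims5(gout, gd);
  const int Do = gd[0], Ho = gd[1], Wo = gd[2], C = gd[3], N = gd[4];
  const int D = xdim[0], H = xdim[1], W = xdim[2];
  NumericVector gx((R_xlen_t)D * H * W * C * N);
  gx.attr("dim") = IntegerVector::create(D, H, W, C, N);
  const double* gp = REAL(gout);
  double* xp = REAL(gx);
  std::vector<int> d0(Do), d1(Do), h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> td(Do), th(Ho), tw(Wo);
  for (int i = 0; i < Do; ++i) lin_coef(i, factor, D, &d0[i], &d1[i], &td[i]);
  for (int i = 0; i < Ho; ++i) lin_coef(i, factor, H, &h0[i], &h1[i], &th[i]);
  for (int i = 0; i < Wo; ++i) lin_coef(i, factor, W, &w0[i], &w1[i], &tw[i]);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h)
          for (int d = 0; d < Do; ++d) {
            const double g = gp[off5(d, h, w, c, n, Do, Ho, Wo, C)];
            if (g == 0.0) continue;
            const double a = td[d], b = th[h], gg = tw[w];
            xp[off5(d0[d], h0[h], w0[w], c, n, D, H, W, C)] += (1-a)*(1-b)*(1-gg)*g;
            xp[off5(d1[d], h0[h], w0[w], c, n, D, H, W, C)] += a*(1-b)*(1-gg)*g;
            xp[off5(d0[d], h1[h], w0[w], c, n, D, H, W, C)] += (1-a)*b*(1-gg)*g;
            xp[off5(d1[d], h1[h], w0[w], c, n, D, H, W, C)] += a*b*(1-gg)*g;
            xp[off5(d0[d], h0[h], w1[w], c, n, D, H, W, C)] += (1-a)*(1-b)*gg*g;
            xp[off5(d1[d], h0[h], w1[w], c, n, D, H, W, C)] += a*(1-b)*gg*g;
            xp[off5(d0[d], h1[h], w1[w], c, n, D, H, W, C)] += (1-a)*b*gg*g;
            xp[off5(d1[d], h1[h], w1[w], c, n, D, H, W, C)] += a*b*gg*g;
          }
  return gx;
}

// 3D median filter with reflect padding (index -1 maps to 0, index D to D-1).
// [[Rcpp::export]]
NumericVector cpp_median_filter3d(NumericVector x, int kernel) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 3) stop("expected a 3-d array");
  const int D = dm[0], H = dm[1], W = dm[2];
  const int r = kernel / 2;
  NumericVector out((R_xlen_t)D * H * W);
  out.attr("dim") = dm;
  const double* xp = REAL(x);
  double* op = REAL(out);
  const int m = kernel * kernel * kernel;
  std::vector<double> buf(m);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        int q = 0;
        for (int kw = -r; kw <= r; ++kw) {
          int wi = w + kw;
          if (wi < 0) wi = -wi - 1;
          if (wi >= W) wi = 2 * W - wi - 1;
          for (int kh = -r; kh <= r; ++kh) {
            int hi = h + kh;
            if (hi < 0) hi = -hi - 1;
            if (hi >= H) hi = 2 * H - hi - 1;
            for (int kd = -r; kd <= r; ++kd) {
              int di = d + kd;
              if (di < 0) di = -di - 1;
              if (di >= D) di = 2 * D - di - 1;
              buf[q++] = xp[di + (R_xlen_t)D * (hi + (R_xlen_t)H * wi)];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
        op[d + (R_xlen_t)D * (h + (R_xlen_t)H * w)] = buf[m / 2];
      }
  return out;
}
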