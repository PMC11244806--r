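#include <Rcpp.h>
using namespace Rcpp;

// Dense n-dimensional convolution kernels for small-volume microscopy work.
// All tensors are R arrays in column-major order with dims (D, H, W, C);
// 2D data travels as D == 1 with a kernel depth of 1. Batch size is always 1
// (the training protocol uses batch size 1), so no batch axis exists.
//
// Spatial padding is applied in R before calling (reflection / replication /
// zero), so the forward pass here is always a "valid" convolution.
//
// Loop structure: one kernel weight is hoisted per (co, ci, kz, ky, kx) and
// swept across the whole output with strided row-inner loops, which keeps
// the inner loops branch-free and lets the compiler vectorize them.

// [[Rcpp::export]]
NumericVector cpp_conv_fw(NumericVector x, NumericVector wt, NumericVector b,
                          IntegerVector stride) {
  IntegerVector xd = x.attr("dim");   // D, H, W, Ci
  IntegerVector wd = wt.attr("dim");  // kd, kh, kw, Ci, Co
  const int D = xd[0], H = xd[1], W = xd[2], Ci = xd[3];
  const int kd = wd[0], kh = wd[1], kw = wd[2], Co = wd[4];
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int Do = (D - kd) / sd + 1, Ho = (H - kh) / sh + 1, Wo = (W - kw) / sw + 1;
  const int out_plane = Do * Ho * Wo;

  NumericVector y(out_plane * Co);
  const double *px = x.begin(), *pw = wt.begin();
  double *py = y.begin();

  for (int co = 0; co < Co; ++co) {
    double *yc = py + (size_t)out_plane * co;
    const double bias = b[co % b.size()];
    for (int i = 0; i < out_plane; ++i) yc[i] = bias;
    for (int ci = 0; ci < Ci; ++ci) {
      const double *xc = px + (size_t)D * H * W * ci;
      for (int kz = 0; kz < kw; ++kz)
        for (int ky = 0; ky < kh; ++ky)
          for (int kx = 0; kx < kd; ++kx) {
            const double wv = pw[kx + kd * (ky + kh * (kz + kw * (ci + (size_t)Ci * co)))];
            if (wv == 0.0) continue;
            for (int wo = 0; wo < Wo; ++wo) {
              const double *xrow0 = xc + (size_t)D * H * (wo * sw + kz) + (size_t)D * ky + kx;
              double *yrow0 = yc + (size_t)Do * Ho * wo;
              if (D == 1 && sh == 1) {        // 2D fast path: contiguous axpy
                for (int ho = 0; ho < Ho; ++ho) yrow0[ho] += wv * xrow0[ho];
              } else if (D == 1) {
                for (int ho = 0; ho < Ho; ++ho) yrow0[ho] += wv * xrow0[(size_t)sh * ho];
              } else {
                for (int ho = 0; ho < Ho; ++ho) {
                  const double *xr = xrow0 + (size_t)D * sh * ho;
                  double *yr = yrow0 + (size_t)Do * ho;
                  for (int dd = 0; dd < Do; ++dd) yr[dd] += wv * xr[dd * sd];
                }
              }
            }
          }
    }
  }
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, Co);
  return y;
}

// Gradient w.r.t. the (padded) input of cpp_conv_fw.
// [[Rcpp::export]]
NumericVector cpp_conv_bw_input(NumericVector gy, NumericVector wt,
                                IntegerVector stride, IntegerVector xdim) {
  IntegerVector gd = gy.attr("dim");  // Do, Ho, Wo, Co
  IntegerVector wd = wt.attr("dim");
  const int Do = gd[0], Ho = gd[1], Wo = gd[2], Co = gd[3];
  const int kd = wd[0], kh = wd[1], kw = wd[2], Ci = wd[3];
  const int D = xdim[0], H = xdim[1], W = xdim[2];
  const int sd = stride[0], sh = stride[1], sw = stride[2];

  NumericVector gx((size_t)D * H * W * Ci);
  const double *pg = gy.begin(), *pw = wt.begin();
  double *px = gx.begin();

  for (int co = 0; co < Co; ++co) {
    const double *gc = pg + (size_t)Do * Ho * Wo * co;
    for (int ci = 0; ci < Ci; ++ci) {
      double *xc = px + (size_t)D * H * W * ci;
      for (int kz = 0; kz < kw; ++kz)
        for (int ky = 0; ky < kh; ++ky)
          for (int kx = 0; kx < kd; ++kx) {
            const double wv = pw[kx + kd * (ky + kh * (kz + kw * (ci + (size_t)Ci * co)))];
            if (wv == 0.0) continue;
            for (int wo = 0; wo < Wo; ++wo) {
              double *xrow0 = xc + (size_t)D * H * (wo * sw + kz) + (size_t)D * ky + kx;
              const double *grow0 = gc + (size_t)Do * Ho * wo;
              if (D == 1 && sh == 1) {
                for (int ho = 0; ho < Ho; ++ho) xrow0[ho] += wv * grow0[ho];
              } else if (D == 1) {
                for (int ho = 0; ho < Ho; ++ho) xrow0[(size_t)sh * ho] += wv * grow0[ho];
              } else {
                for (int ho = 0; ho < Ho; ++ho) {
                  double *xr = xrow0 + (size_t)D * sh * ho;
                  const double *gr = grow0 + (size_t)Do * ho;
                  for (int dd = 0; dd < Do; ++dd) xr[dd * sd] += wv * gr[dd];
                }
              }
            }
          }
    }
  }
  gx.attr("dim") = IntegerVector::create(D, H, W, Ci);
  return gx;
}

// Gradient w.r.t. the kernel of cpp_conv_fw.
// [[Rcpp::export]]
NumericVector cpp_conv_bw_weight(NumericVector x, NumericVector gy,
                                 IntegerVector kdim, IntegerVector stride) {
  IntegerVector xd = x.attr("dim");
  IntegerVector gd = gy.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], Ci = xd[3];
  const int Do = gd[0], Ho = gd[1], Wo = gd[2], Co = gd[3];
  const int kd = kdim[0], kh = kdim[1], kw = kdim[2];
  const int sd = stride[0], sh = stride[1], sw = stride[2];

  NumericVector gw((size_t)kd * kh * kw * Ci * Co);
  const double *px = x.begin(), *pg = gy.begin();
  double *pw = gw.begin();

  for (int co = 0; co < Co; ++co) {
    const double *gc = pg + (size_t)Do * Ho * Wo * co;
    for (int ci = 0; ci < Ci; ++ci) {
      const double *xc = px + (size_t)D * H * W * ci;
      for (int kz = 0; kz < kw; ++kz)
        for (int ky = 0; ky < kh; ++ky)
          for (int kx = 0; kx < kd; ++kx) {
            double acc = 0.0;
            for (int wo = 0; wo < Wo; ++wo) {
              const double *xrow0 = xc + (size_t)D * H * (wo * sw + kz) + (size_t)D * ky + kx;
              const double *grow0 = gc + (size_t)Do * Ho * wo;
              if (D == 1 && sh == 1) {
                for (int ho = 0; ho < Ho; ++ho) acc += xrow0[ho] * grow0[ho];
              } else if (D == 1) {
                for (int ho = 0; ho < Ho; ++ho) acc += xrow0[(size_t)sh * ho] * grow0[ho];
              } else {
                for (int ho = 0; ho < Ho; ++ho) {
                  const double *xr = xrow0 + (size_t)D * sh * ho;
                  const double *gr = grow0 + (size_t)Do * ho;
                  for (int dd = 0; dd < Do; ++dd) acc += xr[dd * sd] * gr[dd];
                }
              }
            }
            pw[kx + kd * (ky + kh * (kz + kw * (ci + (size_t)Ci * co)))] += acc;
          }
    }
  }
  gw.attr("dim") = IntegerVector::create(kd, kh, kw, Ci, Co);
  return gw;
}

// valid input range [lo, hi) for a transposed-conv kernel offset q = k - p:
// output index o = v * s + q must lie in [0, Out)
static inline void tc_range(int q, int s, int In, int Out, int& lo, int& hi) {
  lo = 0;
  if (q < 0) lo = (-q + s - 1) / s;
  int top = Out - 1 - q;
  hi = top < 0 ? 0 : top / s + 1;
  if (hi > In) hi = In;
  if (lo > hi) lo = hi;
}

// Transposed convolution, forward: out = (in - 1) * s - 2 p + k + op.
// [[Rcpp::export]]
NumericVector cpp_tconv_fw(NumericVector x, NumericVector wt, NumericVector b,
                           IntegerVector stride, IntegerVector pad,
                           IntegerVector opad) {
  IntegerVector xd = x.attr("dim");   // D, H, W, Ci
  IntegerVector wd = wt.attr("dim");  // kd, kh, kw, Ci, Co
  const int D = xd[0], H = xd[1], W = xd[2], Ci = xd[3];
  const int kd = wd[0], kh = wd[1], kw = wd[2], Co = wd[4];
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int pd = pad[0], ph = pad[1], pw_ = pad[2];
  const int Do = (D - 1) * sd - 2 * pd + kd + opad[0];
  const int Ho = (H - 1) * sh - 2 * ph + kh + opad[1];
  const int Wo = (W - 1) * sw - 2 * pw_ + kw + opad[2];
  const int out_plane = Do * Ho * Wo;

  NumericVector y((size_t)out_plane * Co);
  const double *px = x.begin(), *pwv = wt.begin();
  double *py = y.begin();

  for (int co = 0; co < Co; ++co) {
    double *yc = py + (size_t)out_plane * co;
    const double bias = b[co % b.size()];
    for (int i = 0; i < out_plane; ++i) yc[i] = bias;
    for (int ci = 0; ci < Ci; ++ci) {
      const double *xc = px + (size_t)D * H * W * ci;
      for (int kz = 0; kz < kw; ++kz) {
        const int qw = kz - pw_;
        int wlo, whi; tc_range(qw, sw, W, Wo, wlo, whi);
        for (int ky = 0; ky < kh; ++ky) {
          const int qh = ky - ph;
          int hlo, hhi; tc_range(qh, sh, H, Ho, hlo, hhi);
          for (int kx = 0; kx < kd; ++kx) {
            const int qd = kx - pd;
            int dlo, dhi; tc_range(qd, sd, D, Do, dlo, dhi);
            const double wv = pwv[kx + kd * (ky + kh * (kz + kw * (ci + (size_t)Ci * co)))];
            if (wv == 0.0) continue;
            for (int wv_i = wlo; wv_i < whi; ++wv_i) {
              const int wo = wv_i * sw + qw;
              for (int hv = hlo; hv < hhi; ++hv) {
                const int ho = hv * sh + qh;
                const double *xr = xc + (size_t)D * (hv + (size_t)H * wv_i);
                double *yr = yc + (size_t)Do * (ho + (size_t)Ho * wo) + qd;
                for (int dv = dlo; dv < dhi; ++dv) yr[dv * sd] += wv * xr[dv];
              }
            }
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, Co);
  return y;
}

// Gradient w.r.t. input of cpp_tconv_fw (a strided gather).
// [[Rcpp::export]]
NumericVector cpp_tconv_bw_input(NumericVector gy, NumericVector wt,
                                 IntegerVector stride, IntegerVector pad,
                                 IntegerVector xdim) {
  IntegerVector gd = gy.attr("dim");
  IntegerVector wd = wt.attr("dim");
  const int Do = gd[0], Ho = gd[1], Wo = gd[2], Co = gd[3];
  const int kd = wd[0], kh = wd[1], kw = wd[2], Ci = wd[3];
  const int D = xdim[0], H = xdim[1], W = xdim[2];
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int pd = pad[0], ph = pad[1], pw_ = pad[2];

  NumericVector gx((size_t)D * H * W * Ci);
  const double *pg = gy.begin(), *pwv = wt.begin();
  double *px = gx.begin();

  for (int co = 0; co < Co; ++co) {
    const double *gc = pg + (size_t)Do * Ho * Wo * co;
    for (int ci = 0; ci < Ci; ++ci) {
      double *xc = px + (size_t)D * H * W * ci;
      for (int kz = 0; kz < kw; ++kz) {
        const int qw = kz - pw_;
        int wlo, whi; tc_range(qw, sw, W, Wo, wlo, whi);
        for (int ky = 0; ky < kh; ++ky) {
          const int qh = ky - ph;
          int hlo, hhi; tc_range(qh, sh, H, Ho, hlo, hhi);
          for (int kx = 0; kx < kd; ++kx) {
            const int qd = kx - pd;
            int dlo, dhi; tc_range(qd, sd, D, Do, dlo, dhi);
            const double wv = pwv[kx + kd * (ky + kh * (kz + kw * (ci + (size_t)Ci * co)))];
            if (wv == 0.0) continue;
            for (int wv_i = wlo; wv_i < whi; ++wv_i) {
              const int wo = wv_i * sw + qw;
              for (int hv = hlo; hv < hhi; ++hv) {
                const int ho = hv * sh + qh;
                double *xr = xc + (size_t)D * (hv + (size_t)H * wv_i);
                const double *gr = gc + (size_t)Do * (ho + (size_t)Ho * wo) + qd;
                for (int dv = dlo; dv < dhi; ++dv) xr[dv] += wv * gr[dv * sd];
              }
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(D, H, W, Ci);
  return gx;
}

// Gradient w.r.t. kernel of cpp_tconv_fw.
// [[Rcpp::export]]
NumericVector cpp_tconv_bw_weight(NumericVector x, NumericVector gy,
                                  IntegerVector kdim, IntegerVector stride,
                                  IntegerVector pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector gd = gy.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], Ci = xd[3];
  const int Do = gd[0], Ho = gd[1], Wo = gd[2], Co = gd[3];
  const int kd = kdim[0], kh = kdim[1], kw = kdim[2];
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int pd = pad[0], ph = pad[1], pw_ = pad[2];

  NumericVector gw((size_t)kd * kh * kw * Ci * Co);
  const double *px = x.begin(), *pg = gy.begin();
  double *pw = gw.begin();

  for (int co = 0; co < Co; ++co) {
    const double *gc = pg + (size_t)Do * Ho * Wo * co;
    for (int ci = 0; ci < Ci; ++ci) {
      const double *xc = px + (size_t)D * H * W * ci;
      for (int kz = 0; kz < kw; ++kz) {
        const int qw = kz - pw_;
        int wlo, whi; tc_range(qw, sw, W, Wo, wlo, whi);
        for (int ky = 0; ky < kh; ++ky) {
          const int qh = ky - ph;
          int hlo, hhi; tc_range(qh, sh, H, Ho, hlo, hhi);
          for (int kx = 0; kx < kd; ++kx) {
            const int qd = kx - pd;
            int dlo, dhi; tc_range(qd, sd, D, Do, dlo, dhi);
            double acc = 0.0;
            for (int wv_i = wlo; wv_i < whi; ++wv_i) {
              const int wo = wv_i * sw + qw;
              for (int hv = hlo; hv < hhi; ++hv) {
                const int ho = hv * sh + qh;
                const double *xr = xc + (size_t)D * (hv + (size_t)H * wv_i);
                const double *gr = gc + (size_t)Do * (ho + (size_t)Ho * wo) + qd;
                for (int dv = dlo; dv < dhi; ++dv) acc += xr[dv] * gr[dv * sd];
              }
            }
            pw[kx + kd * (ky + kh * (kz + kw * (ci + (size_t)Ci * co)))] += acc;
          }
        }
      }
    }
  }
  gw.attr("dim") = IntegerVector::create(kd, kh, kw, Ci, Co);
  return gw;
}
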