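// GEMM-backed 2-D convolution kernels (im2col / col2im).
//
// Tensor layout everywhere: feature maps are (H, W, C, N) column-major
// doubles, weights are (kh, kw, Cin, Cout).  Padding is asymmetric
// "same"-style and precomputed on the R side (pad_top / pad_left only;
// the bottom/right overhang is implied by the output size).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void im2col(const double* x, int H, int W, int Cin,
                          int kh, int kw, int stride, int dilh, int dilw,
                          int pad_top, int pad_left, int Hout, int Wout,
                          arma::mat& col) {
  // col: (kh*kw*Cin) x (Hout*Wout), row index r = ih + kh*(iw + kw*ic)
  for (int wo = 0; wo < Wout; ++wo) {
    for (int ho = 0; ho < Hout; ++ho) {
      double* dst = col.colptr(ho + Hout * wo);
      const int h0 = ho * stride - pad_top;
      const int w0 = wo * stride - pad_left;
      for (int ic = 0; ic < Cin; ++ic) {
        const double* plane = x + (size_t)H * W * ic;
        for (int iw = 0; iw < kw; ++iw) {
          const int wi = w0 + iw * dilw;
          const bool win = (wi >= 0 && wi < W);
          for (int ih = 0; ih < kh; ++ih) {
            const int hi = h0 + ih * dilh;
            const int r = ih + kh * (iw + kw * ic);
            dst[r] = (win && hi >= 0 && hi < H) ? plane[hi + (size_t)H * wi] : 0.0;
          }
        }
      }
    }
  }
}


// Direct tap-loop kernels for stride-1 same-size convolutions with a large
// spatial extent: image planes are cache-resident there, so per-tap
// contiguous axpy / dot loops beat materialising the im2col matrix.
static const size_t DIRECT_MIN_PIXELS = 1024;

#if defined(__x86_64__) && defined(__GNUC__) && !defined(__clang__)
#define MUNET_CLONES __attribute__((target_clones("arch=haswell", "default"), noinline))
#else
#define MUNET_CLONES
#endif

MUNET_CLONES
static void conv_direct_fw(const double* x, const double* w,
                           const double* b, int H, int W, int Cin,
                           int Cout, int kh, int kw, int dilh, int dilw,
                           int pad_top, int pad_left, double* y) {
  const size_t HW = (size_t)H * W;
  for (int co = 0; co < Cout; ++co)
    std::fill(y + HW * co, y + HW * (co + 1), b[co]);
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xp = x + HW * ci;
    for (int co = 0; co < Cout; ++co) {
      double* yp = y + HW * co;
      for (int iw = 0; iw < kw; ++iw) {
        const int sw = iw * dilw - pad_left;
        for (int ih = 0; ih < kh; ++ih) {
          const int sh = ih * dilh - pad_top;
          const double wgt = w[ih + kh * (iw + kw * (ci + (size_t)Cin * co))];
          if (wgt == 0.0) continue;
          const int ho0 = std::max(0, -sh), ho1 = std::min(H, H - sh);
          if (ho1 <= ho0) continue;
          for (int wo = 0; wo < W; ++wo) {
            const int wi = wo + sw;
            if (wi < 0 || wi >= W) continue;
            double* __restrict__ dst = yp + (size_t)H * wo + ho0;
            const double* __restrict__ src = xp + (size_t)H * wi + ho0 + sh;
            const int len = ho1 - ho0;
            for (int i = 0; i < len; ++i) dst[i] += wgt * src[i];
          }
        }
      }
    }
  }
}

MUNET_CLONES
static void conv_direct_bw(const double* x, const double* w,
                           const double* dy, int H, int W, int Cin,
                           int Cout, int kh, int kw, int dilh, int dilw,
                           int pad_top, int pad_left,
                           double* dx, double* dw, double* db) {
  const size_t HW = (size_t)H * W;
  for (int co = 0; co < Cout; ++co) {
    const double* dyp = dy + HW * co;
    double s = 0;
    for (size_t i = 0; i < HW; ++i) s += dyp[i];
    db[co] += s;
  }
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xp = x + HW * ci;
    double* dxp = dx + HW * ci;
    for (int co = 0; co < Cout; ++co) {
      const double* dyp = dy + HW * co;
      for (int iw = 0; iw < kw; ++iw) {
        const int sw = iw * dilw - pad_left;
        for (int ih = 0; ih < kh; ++ih) {
          const int sh = ih * dilh - pad_top;
          const size_t widx = ih + kh * (iw + kw * (ci + (size_t)Cin * co));
          const double wgt = w[widx];
          const int ho0 = std::max(0, -sh), ho1 = std::min(H, H - sh);
          if (ho1 <= ho0) continue;
          double acc = 0;
          for (int wo = 0; wo < W; ++wo) {
            const int wi = wo + sw;
            if (wi < 0 || wi >= W) continue;
            const double* __restrict__ pdy = dyp + (size_t)H * wo + ho0;
            const double* __restrict__ px = xp + (size_t)H * wi + ho0 + sh;
            double* __restrict__ pdx = dxp + (size_t)H * wi + ho0 + sh;
            const int len = ho1 - ho0;
            for (int i = 0; i < len; ++i) {
              acc += px[i] * pdy[i];
              pdx[i] += wgt * pdy[i];
            }
          }
          dw[widx] += acc;
        }
      }
    }
  }
}

static inline void col2im_add(const arma::mat& col, int H, int W, int Cin,
                              int kh, int kw, int stride, int dilh, int dilw,
                              int pad_top, int pad_left, int Hout, int Wout,
                              double* dx) {
  for (int wo = 0; wo < Wout; ++wo) {
    for (int ho = 0; ho < Hout; ++ho) {
      const double* src = col.colptr(ho + Hout * wo);
      const int h0 = ho * stride - pad_top;
      const int w0 = wo * stride - pad_left;
      for (int ic = 0; ic < Cin; ++ic) {
        double* plane = dx + (size_t)H * W * ic;
        for (int iw = 0; iw < kw; ++iw) {
          const int wi = w0 + iw * dilw;
          if (wi < 0 || wi >= W) continue;
          for (int ih = 0; ih < kh; ++ih) {
            const int hi = h0 + ih * dilh;
            if (hi < 0 || hi >= H) continue;
            plane[hi + (size_t)H * wi] += src[ih + kh * (iw + kw * ic)];
          }
        }
      }
    }
  }
}

// Forward pass.  1x1 stride-1 convolutions skip im2col entirely (each
// sample is already a (H*W) x Cin matrix in memory); for other kernels the
// im2col matrices of all samples can be cached and handed back to the
// backward pass via want_col.
// float32 mirrors of the direct kernels: the large-spatial path is
// memory/loop bound, so single precision roughly doubles throughput.
// Inputs and outputs stay double on the R side; accumulation happens in
// float, which is standard practice for CNN training.
static std::vector<float>& scratch_f32(int slot, size_t n) {
  static std::vector<float> buf[4];
  if (buf[slot].size() < n) buf[slot].resize(n);
  return buf[slot];
}

MUNET_CLONES
static void conv_direct_fw_f32(const float* x, const float* w,
                               const float* b, int H, int W, int Cin,
                               int Cout, int kh, int kw, int dilh, int dilw,
                               int pad_top, int pad_left, float* y) {
  const size_t HW = (size_t)H * W;
  for (int co = 0; co < Cout; ++co)
    std::fill(y + HW * co, y + HW * (co + 1), b[co]);
  for (int co = 0; co < Cout; ++co) {
    float* yp = y + HW * co;
    for (int ci0 = 0; ci0 < Cin; ci0 += 4) {
      const int cb = std::min(4, Cin - ci0);
      const float* xp0 = x + HW * ci0;
      const float* xp1 = x + HW * (ci0 + (cb > 1 ? 1 : 0));
      const float* xp2 = x + HW * (ci0 + (cb > 2 ? 2 : 0));
      const float* xp3 = x + HW * (ci0 + (cb > 3 ? 3 : 0));
      for (int iw = 0; iw < kw; ++iw) {
        const int sw = iw * dilw - pad_left;
        for (int ih = 0; ih < kh; ++ih) {
          const int sh = ih * dilh - pad_top;
          const size_t wbase = ih + kh * (iw + (size_t)kw * (ci0 + (size_t)Cin * co));
          const size_t wstep = (size_t)kh * kw;
          const float w0 = w[wbase];
          const float w1 = cb > 1 ? w[wbase + wstep] : 0.0f;
          const float w2 = cb > 2 ? w[wbase + 2 * wstep] : 0.0f;
          const float w3 = cb > 3 ? w[wbase + 3 * wstep] : 0.0f;
          if (w0 == 0.0f && w1 == 0.0f && w2 == 0.0f && w3 == 0.0f) continue;
          const int ho0 = std::max(0, -sh), ho1 = std::min(H, H - sh);
          if (ho1 <= ho0) continue;
          for (int wo = 0; wo < W; ++wo) {
            const int wi = wo + sw;
            if (wi < 0 || wi >= W) continue;
            const size_t so = (size_t)H * wi + ho0 + sh;
            float* __restrict__ dst = yp + (size_t)H * wo + ho0;
            const float* __restrict__ s0 = xp0 + so;
            const float* __restrict__ s1 = xp1 + so;
            const float* __restrict__ s2 = xp2 + so;
            const float* __restrict__ s3 = xp3 + so;
            const int len = ho1 - ho0;
            for (int i = 0; i < len; ++i)
              dst[i] += w0 * s0[i] + w1 * s1[i] + w2 * s2[i] + w3 * s3[i];
          }
        }
      }
    }
  }
}

MUNET_CLONES
static void conv_direct_bw_f32(const float* x, const float* w,
                               const float* dy, int H, int W, int Cin,
                               int Cout, int kh, int kw, int dilh, int dilw,
                               int pad_top, int pad_left,
                               float* dx, double* dw, double* db) {
  const size_t HW = (size_t)H * W;
  const size_t wstep = (size_t)kh * kw;
  for (int co = 0; co < Cout; ++co) {
    const float* dyp = dy + HW * co;
    double s = 0;
    for (size_t i = 0; i < HW; ++i) s += dyp[i];
    db[co] += s;
  }
  // input gradient: co blocked by 4
  for (int ci = 0; ci < Cin; ++ci) {
    float* dxp = dx + HW * ci;
    for (int co0 = 0; co0 < Cout; co0 += 4) {
      const int cb = std::min(4, Cout - co0);
      const float* dy0 = dy + HW * co0;
      const float* dy1 = dy + HW * (co0 + (cb > 1 ? 1 : 0));
      const float* dy2 = dy + HW * (co0 + (cb > 2 ? 2 : 0));
      const float* dy3 = dy + HW * (co0 + (cb > 3 ? 3 : 0));
      for (int iw = 0; iw < kw; ++iw) {
        const int sw = iw * dilw - pad_left;
        for (int ih = 0; ih < kh; ++ih) {
          const int sh = ih * dilh - pad_top;
          const size_t wbase = ih + kh * (iw + (size_t)kw * (ci + (size_t)Cin * co0));
          const size_t cstep = (size_t)kh * kw * Cin;
          const float w0 = w[wbase];
          const float w1 = cb > 1 ? w[wbase + cstep] : 0.0f;
          const float w2 = cb > 2 ? w[wbase + 2 * cstep] : 0.0f;
          const float w3 = cb > 3 ? w[wbase + 3 * cstep] : 0.0f;
          const int ho0 = std::max(0, -sh), ho1 = std::min(H, H - sh);
          if (ho1 <= ho0) continue;
          for (int wo = 0; wo < W; ++wo) {
            const int wi = wo + sw;
            if (wi < 0 || wi >= W) continue;
            const size_t oo = (size_t)H * wo + ho0;
            float* __restrict__ pdx = dxp + (size_t)H * wi + ho0 + sh;
            const float* __restrict__ p0 = dy0 + oo;
            const float* __restrict__ p1 = dy1 + oo;
            const float* __restrict__ p2 = dy2 + oo;
            const float* __restrict__ p3 = dy3 + oo;
            const int len = ho1 - ho0;
            for (int i = 0; i < len; ++i)
              pdx[i] += w0 * p0[i] + w1 * p1[i] + w2 * p2[i] + w3 * p3[i];
          }
        }
      }
    }
  }
  // weight gradient: ci blocked by 4, four dot products per dy pass
  for (int co = 0; co < Cout; ++co) {
    const float* dyp = dy + HW * co;
    for (int ci0 = 0; ci0 < Cin; ci0 += 4) {
      const int cb = std::min(4, Cin - ci0);
      const float* xp0 = x + HW * ci0;
      const float* xp1 = x + HW * (ci0 + (cb > 1 ? 1 : 0));
      const float* xp2 = x + HW * (ci0 + (cb > 2 ? 2 : 0));
      const float* xp3 = x + HW * (ci0 + (cb > 3 ? 3 : 0));
      for (int iw = 0; iw < kw; ++iw) {
        const int sw = iw * dilw - pad_left;
        for (int ih = 0; ih < kh; ++ih) {
          const int sh = ih * dilh - pad_top;
          const int ho0 = std::max(0, -sh), ho1 = std::min(H, H - sh);
          if (ho1 <= ho0) continue;
          float a0[4] = {0,0,0,0}, a1[4] = {0,0,0,0},
                a2[4] = {0,0,0,0}, a3[4] = {0,0,0,0};
          for (int wo = 0; wo < W; ++wo) {
            const int wi = wo + sw;
            if (wi < 0 || wi >= W) continue;
            const size_t so = (size_t)H * wi + ho0 + sh;
            const float* __restrict__ pdy = dyp + (size_t)H * wo + ho0;
            const float* __restrict__ s0 = xp0 + so;
            const float* __restrict__ s1 = xp1 + so;
            const float* __restrict__ s2 = xp2 + so;
            const float* __restrict__ s3 = xp3 + so;
            const int len = ho1 - ho0;
            int i = 0;
            for (; i + 4 <= len; i += 4)
              for (int j = 0; j < 4; ++j) {
                a0[j] += s0[i + j] * pdy[i + j];
                a1[j] += s1[i + j] * pdy[i + j];
                a2[j] += s2[i + j] * pdy[i + j];
                a3[j] += s3[i + j] * pdy[i + j];
              }
            for (; i < len; ++i) {
              a0[0] += s0[i] * pdy[i];
              a1[0] += s1[i] * pdy[i];
              a2[0] += s2[i] * pdy[i];
              a3[0] += s3[i] * pdy[i];
            }
          }
          const size_t wbase = ih + kh * (iw + (size_t)kw * (ci0 + (size_t)Cin * co));
          dw[wbase] += a0[0] + a0[1] + a0[2] + a0[3];
          if (cb > 1) dw[wbase + wstep] += a1[0] + a1[1] + a1[2] + a1[3];
          if (cb > 2) dw[wbase + 2 * wstep] += a2[0] + a2[1] + a2[2] + a2[3];
          if (cb > 3) dw[wbase + 3 * wstep] += a3[0] + a3[1] + a3[2] + a3[3];
        }
      }
    }
  }
}

static inline void d2f(const double* src, float* dst, size_t n) {
  for (size_t i = 0; i < n; ++i) dst[i] = (float)src[i];
}

// single-precision cutover for the im2col/GEMM path: large problems are
// memory bound, small ones keep full double precision (the exact-arithmetic
// oracles all live there)
static const size_t GEMM_F32_MIN = 32768;

static inline void im2col_f32(const float* x, int H, int W, int Cin,
                              int kh, int kw, int stride, int dilh, int dilw,
                              int pad_top, int pad_left, int Hout, int Wout,
                              arma::fmat& col) {
  for (int wo = 0; wo < Wout; ++wo) {
    for (int ho = 0; ho < Hout; ++ho) {
      float* dst = col.colptr(ho + Hout * wo);
      const int h0 = ho * stride - pad_top;
      const int w0 = wo * stride - pad_left;
      for (int ic = 0; ic < Cin; ++ic) {
        const float* plane = x + (size_t)H * W * ic;
        for (int iw = 0; iw < kw; ++iw) {
          const int wi = w0 + iw * dilw;
          const bool win = (wi >= 0 && wi < W);
          for (int ih = 0; ih < kh; ++ih) {
            const int hi = h0 + ih * dilh;
            const int r = ih + kh * (iw + kw * ic);
            dst[r] = (win && hi >= 0 && hi < H) ? plane[hi + (size_t)H * wi] : 0.0f;
          }
        }
      }
    }
  }
}

static inline void col2im_add_f32(const arma::fmat& col, int H, int W, int Cin,
                                  int kh, int kw, int stride, int dilh, int dilw,
                                  int pad_top, int pad_left, int Hout, int Wout,
                                  float* dx) {
  for (int wo = 0; wo < Wout; ++wo) {
    for (int ho = 0; ho < Hout; ++ho) {
      const float* src = col.colptr(ho + Hout * wo);
      const int h0 = ho * stride - pad_top;
      const int w0 = wo * stride - pad_left;
      for (int ic = 0; ic < Cin; ++ic) {
        float* plane = dx + (size_t)H * W * ic;
        for (int iw = 0; iw < kw; ++iw) {
          const int wi = w0 + iw * dilw;
          if (wi < 0 || wi >= W) continue;
          for (int ih = 0; ih < kh; ++ih) {
            const int hi = h0 + ih * dilh;
            if (hi < 0 || hi >= H) continue;
            plane[hi + (size_t)H * wi] += src[ih + kh * (iw + kw * ic)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List conv2d_fw_cpp(NumericVector x, NumericVector w, NumericVector b,
                   int stride, int dilh, int dilw,
                   int pad_top, int pad_left, int Hout, int Wout,
                   bool want_col) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("conv2d: weight Cin mismatch");
  const int R = kh * kw * Cin, P = Hout * Wout;
  const bool one_by_one = (kh == 1 && kw == 1 && stride == 1);
  const bool direct = (stride == 1 && Hout == H && Wout == W &&
                       !one_by_one && (size_t)P >= DIRECT_MIN_PIXELS);

  NumericVector y((size_t)Hout * Wout * Cout * N);
  y.attr("dim") = IntegerVector::create(Hout, Wout, Cout, N);
  const arma::mat Wm(const_cast<double*>(w.begin()), R, Cout, false, true);
  const arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);

  if (direct) {
    std::vector<float>& xf = scratch_f32(0, (size_t)P * Cin);
    std::vector<float>& wf = scratch_f32(1, (size_t)R * Cout);
    std::vector<float>& bf = scratch_f32(2, (size_t)Cout);
    std::vector<float>& yf = scratch_f32(3, (size_t)P * Cout);
    d2f(w.begin(), wf.data(), (size_t)R * Cout);
    d2f(b.begin(), bf.data(), (size_t)Cout);
    for (int n = 0; n < N; ++n) {
      d2f(x.begin() + (size_t)P * Cin * n, xf.data(), (size_t)P * Cin);
      conv_direct_fw_f32(xf.data(), wf.data(), bf.data(), H, W, Cin, Cout,
                         kh, kw, dilh, dilw, pad_top, pad_left, yf.data());
      double* yp = y.begin() + (size_t)P * Cout * n;
      for (size_t i = 0; i < (size_t)P * Cout; ++i) yp[i] = yf[i];
    }
    return List::create(_["y"] = y);
  }

  if (one_by_one) {
    for (int n = 0; n < N; ++n) {
      const arma::mat X(const_cast<double*>(x.begin()) + (size_t)P * Cin * n,
                        P, Cin, false, true);
      arma::mat Y(y.begin() + (size_t)P * Cout * n, P, Cout, false, true);
      Y = X * Wm;
      Y.each_row() += bv;
    }
    return List::create(_["y"] = y);
  }

  if ((size_t)R * P >= GEMM_F32_MIN) {
    std::vector<float>& xf = scratch_f32(0, (size_t)H * W * Cin);
    std::vector<float>& wf = scratch_f32(1, (size_t)R * Cout);
    std::vector<float>& yf = scratch_f32(2, (size_t)P * Cout);
    std::vector<float>& cf = scratch_f32(3, (size_t)R * P);
    d2f(w.begin(), wf.data(), (size_t)R * Cout);
    const arma::fmat Wmf(wf.data(), R, Cout, false, true);
    arma::fmat col(cf.data(), R, P, false, true);
    for (int n = 0; n < N; ++n) {
      d2f(x.begin() + (size_t)H * W * Cin * n, xf.data(), (size_t)H * W * Cin);
      im2col_f32(xf.data(), H, W, Cin, kh, kw, stride, dilh, dilw,
                 pad_top, pad_left, Hout, Wout, col);
      arma::fmat Yf(yf.data(), P, Cout, false, true);
      Yf = col.t() * Wmf;
      double* yp = y.begin() + (size_t)P * Cout * n;
      for (int c = 0; c < Cout; ++c) {
        const double bb = b[c];
        const float* src = yf.data() + (size_t)P * c;
        for (int j = 0; j < P; ++j) yp[j + (size_t)P * c] = src[j] + bb;
      }
    }
    return List::create(_["y"] = y);
  }

  NumericMatrix colstore(want_col ? R : 0, want_col ? P * N : 0);
  arma::mat scratch;
  if (!want_col) scratch.set_size(R, P);
  for (int n = 0; n < N; ++n) {
    arma::mat col = want_col
      ? arma::mat(colstore.begin() + (size_t)R * P * n, R, P, false, true)
      : arma::mat(scratch.memptr(), R, P, false, true);
    im2col(x.begin() + (size_t)H * W * Cin * n, H, W, Cin, kh, kw, stride,
           dilh, dilw, pad_top, pad_left, Hout, Wout, col);
    arma::mat Y(y.begin() + (size_t)P * Cout * n, P, Cout, false, true);
    Y = col.t() * Wm;
    Y.each_row() += bv;
  }
  if (want_col) return List::create(_["y"] = y, _["col"] = colstore);
  return List::create(_["y"] = y);
}

// Gradient w.r.t. input is returned; weight/bias gradients are accumulated
// in place into dw / db (preallocated by the caller).  `colcache` is the
// im2col store returned by the forward pass (size-0 matrix = recompute).
// [[Rcpp::export]]
NumericVector conv2d_bw_cpp(NumericVector x, NumericVector w, NumericVector dy,
                            int stride, int dilh, int dilw,
                            int pad_top, int pad_left,
                            NumericVector dw, NumericVector db,
                            NumericMatrix colcache) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Hout = yd[0], Wout = yd[1];
  const int R = kh * kw * Cin, P = Hout * Wout;
  const bool one_by_one = (kh == 1 && kw == 1 && stride == 1);
  const bool direct = (stride == 1 && Hout == H && Wout == W &&
                       !one_by_one && (size_t)P >= DIRECT_MIN_PIXELS);

  NumericVector dx((size_t)H * W * Cin * N);
  dx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  const arma::mat Wm(const_cast<double*>(w.begin()), R, Cout, false, true);
  arma::mat dWm(dw.begin(), R, Cout, false, true);
  arma::rowvec dbv(db.begin(), Cout, false, true);

  if (direct) {
    std::vector<float>& xf = scratch_f32(0, (size_t)P * Cin);
    std::vector<float>& wf = scratch_f32(1, (size_t)R * Cout);
    std::vector<float>& dyf = scratch_f32(2, (size_t)P * Cout);
    std::vector<float>& dxf = scratch_f32(3, (size_t)P * Cin);
    d2f(w.begin(), wf.data(), (size_t)R * Cout);
    for (int n = 0; n < N; ++n) {
      d2f(x.begin() + (size_t)P * Cin * n, xf.data(), (size_t)P * Cin);
      d2f(dy.begin() + (size_t)P * Cout * n, dyf.data(), (size_t)P * Cout);
      std::fill(dxf.begin(), dxf.begin() + (size_t)P * Cin, 0.0f);
      conv_direct_bw_f32(xf.data(), wf.data(), dyf.data(), H, W, Cin, Cout,
                         kh, kw, dilh, dilw, pad_top, pad_left,
                         dxf.data(), dw.begin(), db.begin());
      double* dxp = dx.begin() + (size_t)P * Cin * n;
      for (size_t i = 0; i < (size_t)P * Cin; ++i) dxp[i] = dxf[i];
    }
    return dx;
  }

  if (one_by_one) {
    for (int n = 0; n < N; ++n) {
      const arma::mat X(const_cast<double*>(x.begin()) + (size_t)P * Cin * n,
                        P, Cin, false, true);
      const arma::mat dYm(const_cast<double*>(dy.begin()) + (size_t)P * Cout * n,
                          P, Cout, false, true);
      arma::mat dX(dx.begin() + (size_t)P * Cin * n, P, Cin, false, true);
      dX = dYm * Wm.t();
      dWm += X.t() * dYm;
      dbv += arma::sum(dYm, 0);
    }
    return dx;
  }

  if ((size_t)R * P >= GEMM_F32_MIN) {
    std::vector<float>& xf = scratch_f32(0, (size_t)H * W * Cin);
    std::vector<float>& wf = scratch_f32(1, (size_t)R * Cout * 2);
    std::vector<float>& dyf = scratch_f32(2, (size_t)P * Cout);
    std::vector<float>& cf = scratch_f32(3, (size_t)R * P * 2 +
                                             (size_t)H * W * Cin);
    d2f(w.begin(), wf.data(), (size_t)R * Cout);
    const arma::fmat Wmf(wf.data(), R, Cout, false, true);
    arma::fmat dWf(wf.data() + (size_t)R * Cout, R, Cout, false, true);
    dWf.zeros();
    arma::fmat col(cf.data(), R, P, false, true);
    arma::fmat dcol(cf.data() + (size_t)R * P, R, P, false, true);
    float* dxf = cf.data() + (size_t)R * P * 2;
    for (int n = 0; n < N; ++n) {
      d2f(x.begin() + (size_t)H * W * Cin * n, xf.data(), (size_t)H * W * Cin);
      d2f(dy.begin() + (size_t)P * Cout * n, dyf.data(), (size_t)P * Cout);
      const arma::fmat dYf(dyf.data(), P, Cout, false, true);
      im2col_f32(xf.data(), H, W, Cin, kh, kw, stride, dilh, dilw,
                 pad_top, pad_left, Hout, Wout, col);
      dWf += col * dYf;
      dbv += arma::conv_to<arma::rowvec>::from(arma::sum(dYf, 0));
      dcol = Wmf * dYf.t();
      std::fill(dxf, dxf + (size_t)H * W * Cin, 0.0f);
      col2im_add_f32(dcol, H, W, Cin, kh, kw, stride, dilh, dilw,
                     pad_top, pad_left, Hout, Wout, dxf);
      double* dxp = dx.begin() + (size_t)H * W * Cin * n;
      for (size_t i = 0; i < (size_t)H * W * Cin; ++i) dxp[i] = dxf[i];
    }
    for (size_t i = 0; i < (size_t)R * Cout; ++i) dw[i] += dWf.memptr()[i];
    return dx;
  }

  const bool have_cache = colcache.nrow() == R;
  arma::mat scratch;
  if (!have_cache) scratch.set_size(R, P);
  for (int n = 0; n < N; ++n) {
    const arma::mat dYm(const_cast<double*>(dy.begin()) + (size_t)P * Cout * n,
                        P, Cout, false, true);
    arma::mat col = have_cache
      ? arma::mat(colcache.begin() + (size_t)R * P * n, R, P, false, true)
      : arma::mat(scratch.memptr(), R, P, false, true);
    if (!have_cache)
      im2col(x.begin() + (size_t)H * W * Cin * n, H, W, Cin, kh, kw, stride,
             dilh, dilw, pad_top, pad_left, Hout, Wout, col);
    dWm += col * dYm;
    dbv += arma::sum(dYm, 0);
    arma::mat dcol = Wm * dYm.t();
    col2im_add(dcol, H, W, Cin, kh, kw, stride, dilh, dilw,
               pad_top, pad_left, Hout, Wout,
               dx.begin() + (size_t)H * W * Cin * n);
  }
  return dx;
}
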