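// Hot-path kernels for the network core: batch norm, CBAM pooling /
// broadcasting, in-place gradient accumulation and the AdamW update.
// Layout everywhere: activations (H, W, C, N) column-major doubles.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

#if defined(__x86_64__) && defined(__GNUC__) && !defined(__clang__)
#define MUNET_CLONES __attribute__((target_clones("arch=haswell", "default"), noinline))
#else
#define MUNET_CLONES
#endif

MUNET_CLONES
static void mean_sq_seg(const double* p, size_t n, double& s_out, double& s2_out) {
  double a[4] = {0, 0, 0, 0}, b[4] = {0, 0, 0, 0};
  size_t i = 0;
  for (; i + 4 <= n; i += 4)
    for (int j = 0; j < 4; ++j) {
      a[j] += p[i + j];
      b[j] += p[i + j] * p[i + j];
    }
  double s = a[0] + a[1] + a[2] + a[3], s2 = b[0] + b[1] + b[2] + b[3];
  for (; i < n; ++i) { s += p[i]; s2 += p[i] * p[i]; }
  s_out += s; s2_out += s2;
}

MUNET_CLONES
static void dot2_seg(const double* p, const double* q, size_t n,
                     double& s_out, double& s2_out) {
  double a[4] = {0, 0, 0, 0}, b[4] = {0, 0, 0, 0};
  size_t i = 0;
  for (; i + 4 <= n; i += 4)
    for (int j = 0; j < 4; ++j) {
      a[j] += p[i + j];
      b[j] += p[i + j] * q[i + j];
    }
  double s = a[0] + a[1] + a[2] + a[3], s2 = b[0] + b[1] + b[2] + b[3];
  for (; i < n; ++i) { s += p[i]; s2 += p[i] * q[i]; }
  s_out += s; s2_out += s2;
}

// ---- batch normalisation ---------------------------------------------------

MUNET_CLONES
static void dot2_centered_seg(const double* pdy, const double* px, size_t n,
                              double mu, double is, double& s1_out,
                              double& s2_out) {
  double a[4] = {0, 0, 0, 0}, b[4] = {0, 0, 0, 0};
  size_t i = 0;
  for (; i + 4 <= n; i += 4)
    for (int j = 0; j < 4; ++j) {
      a[j] += pdy[i + j];
      b[j] += pdy[i + j] * (px[i + j] - mu);
    }
  double s1 = a[0] + a[1] + a[2] + a[3], s2 = b[0] + b[1] + b[2] + b[3];
  for (; i < n; ++i) { s1 += pdy[i]; s2 += pdy[i] * (px[i] - mu); }
  s1_out += s1; s2_out += s2 * is;
}

// The backward pass recomputes the normalised activations from the cached
// input (one fused multiply) instead of storing them in the forward pass.
// [[Rcpp::export]]
List bn_fw_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
               bool training, NumericVector rm, NumericVector rv,
               double momentum, double eps, bool want_cache) {
  IntegerVector d = x.attr("dim");
  const int HW = d[0] * d[1], C = d[2], N = d[3];
  NumericVector y(x.size()); y.attr("dim") = d;
  NumericVector invstd(C), muv(C);
  const double m = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    double mu, var;
    if (training) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n)
        mean_sq_seg(x.begin() + (size_t)HW * (c + (size_t)C * n), HW, s, s2);
      mu = s / m;
      var = s2 / m - mu * mu;
      rm[c] = momentum * rm[c] + (1 - momentum) * mu;
      rv[c] = momentum * rv[c] + (1 - momentum) * var;
    } else {
      mu = rm[c]; var = rv[c];
    }
    const double is = 1.0 / std::sqrt(var + eps);
    invstd[c] = is;
    muv[c] = mu;
    const double a = gamma[c] * is, b = beta[c] - gamma[c] * is * mu;
    for (int n = 0; n < N; ++n) {
      const size_t off = (size_t)HW * (c + (size_t)C * n);
      const double* p = x.begin() + off;
      double* q = y.begin() + off;
      for (int i = 0; i < HW; ++i) q[i] = a * p[i] + b;
    }
  }
  return List::create(_["y"] = y, _["mu"] = muv, _["invstd"] = invstd);
}

// [[Rcpp::export]]
NumericVector bn_bw_cpp(NumericVector dy, NumericVector x, NumericVector mu,
                        NumericVector invstd, NumericVector gamma,
                        bool batch_stats, NumericVector dgamma,
                        NumericVector dbeta) {
  IntegerVector d = dy.attr("dim");
  const int HW = d[0] * d[1], C = d[2], N = d[3];
  NumericVector dx(dy.size()); dx.attr("dim") = d;
  const double m = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    double s1 = 0, s2 = 0;
    const double is = invstd[c], cmu = mu[c];
    for (int n = 0; n < N; ++n) {
      const size_t off = (size_t)HW * (c + (size_t)C * n);
      dot2_centered_seg(dy.begin() + off, x.begin() + off, HW, cmu, is,
                        s1, s2);
    }
    dgamma[c] += s2;
    dbeta[c] += s1;
    const double g = gamma[c];
    for (int n = 0; n < N; ++n) {
      const size_t off = (size_t)HW * (c + (size_t)C * n);
      const double* pdy = dy.begin() + off;
      const double* px = x.begin() + off;
      double* pdx = dx.begin() + off;
      if (batch_stats) {
        const double k1 = g * is, k2 = g * is * s1 / m,
                     k3 = g * is * is * s2 / m;
        for (int i = 0; i < HW; ++i)
          pdx[i] = k1 * pdy[i] - k2 - k3 * (px[i] - cmu);
      } else {
        const double k1 = g * is;
        for (int i = 0; i < HW; ++i) pdx[i] = k1 * pdy[i];
      }
    }
  }
  return dx;
}

// ---- channel attention helpers --------------------------------------------

// [[Rcpp::export]]
List channel_pool_cpp(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int HW = d[0] * d[1], C = d[2], N = d[3];
  NumericMatrix avg(C, N), mx(C, N);
  IntegerMatrix amax(C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + (size_t)HW * (c + (size_t)C * n);
      double s = 0, best = p[0]; int bi = 0;
      for (int i = 0; i < HW; ++i) {
        s += p[i];
        if (p[i] > best) { best = p[i]; bi = i; }
      }
      avg(c, n) = s / HW; mx(c, n) = best; amax(c, n) = bi;
    }
  return List::create(_["avg"] = avg, _["mx"] = mx, _["amax"] = amax);
}

// y = x * s[c, n]
// [[Rcpp::export]]
NumericVector channel_scale_cpp(NumericVector x, NumericMatrix s) {
  IntegerVector d = x.attr("dim");
  const int HW = d[0] * d[1], C = d[2], N = d[3];
  NumericVector y(x.size()); y.attr("dim") = d;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)HW * (c + (size_t)C * n);
      const double* p = x.begin() + off;
      double* q = y.begin() + off;
      const double f = s(c, n);
      for (int i = 0; i < HW; ++i) q[i] = p[i] * f;
    }
  return y;
}

// per-(channel, sample) sum of a * b
// [[Rcpp::export]]
NumericMatrix channel_dot_cpp(NumericVector a, NumericVector b) {
  IntegerVector d = a.attr("dim");
  const int HW = d[0] * d[1], C = d[2], N = d[3];
  NumericMatrix out(C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)HW * (c + (size_t)C * n);
      const double* pa = a.begin() + off;
      const double* pb = b.begin() + off;
      double s = 0;
      for (int i = 0; i < HW; ++i) s += pa[i] * pb[i];
      out(c, n) = s;
    }
  return out;
}

// dst += v[c, n] broadcast over spatial positions (in place)
// [[Rcpp::export]]
void channel_axpy_cpp(NumericVector dst, NumericMatrix v) {
  IntegerVector d = dst.attr("dim");
  const int HW = d[0] * d[1], C = d[2], N = d[3];
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* q = dst.begin() + (size_t)HW * (c + (size_t)C * n);
      const double f = v(c, n);
      for (int i = 0; i < HW; ++i) q[i] += f;
    }
}

// dst[amax(c,n)] += v(c,n) within each (c, n) spatial plane (in place)
// [[Rcpp::export]]
void channel_max_scatter_cpp(NumericVector dst, NumericMatrix v,
                             IntegerMatrix amax) {
  IntegerVector d = dst.attr("dim");
  const int HW = d[0] * d[1], C = d[2], N = d[3];
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      dst[(size_t)HW * (c + (size_t)C * n) + amax(c, n)] += v(c, n);
}

// ---- spatial attention helpers --------------------------------------------

// stacked channel-wise [mean; max] map (H, W, 2, N) plus argmax channel
// [[Rcpp::export]]
List spatial_pool_cpp(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int HW = d[0] * d[1], C = d[2], N = d[3];
  NumericVector st((size_t)HW * 2 * N);
  st.attr("dim") = IntegerVector::create(d[0], d[1], 2, N);
  IntegerVector amax((size_t)HW * N);
  for (int n = 0; n < N; ++n) {
    const double* base = x.begin() + (size_t)HW * C * n;
    double* pm = st.begin() + (size_t)HW * 2 * n;
    double* px = pm + HW;
    int* pa = amax.begin() + (size_t)HW * n;
    for (int i = 0; i < HW; ++i) {
      double s = 0, best = base[i]; int bc = 0;
      for (int c = 0; c < C; ++c) {
        const double val = base[i + (size_t)HW * c];
        s += val;
        if (val > best) { best = val; bc = c; }
      }
      pm[i] = s / C; px[i] = best; pa[i] = bc;
    }
  }
  return List::create(_["st"] = st, _["amax"] = amax);
}

// y = x * ss (ss: (H, W, 1, N), broadcast over channels)
// [[Rcpp::export]]
NumericVector spatial_scale_cpp(NumericVector x, NumericVector ss) {
  IntegerVector d = x.attr("dim");
  const int HW = d[0] * d[1], C = d[2], N = d[3];
  NumericVector y(x.size()); y.attr("dim") = d;
  for (int n = 0; n < N; ++n) {
    const double* ps = ss.begin() + (size_t)HW * n;
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)HW * (c + (size_t)C * n);
      const double* p = x.begin() + off;
      double* q = y.begin() + off;
      for (int i = 0; i < HW; ++i) q[i] = p[i] * ps[i];
    }
  }
  return y;
}

// per-position sum over channels of a * b -> (H, W, 1, N)
// [[Rcpp::export]]
NumericVector spatial_dot_cpp(NumericVector a, NumericVector b) {
  IntegerVector d = a.attr("dim");
  const int HW = d[0] * d[1], C = d[2], N = d[3];
  NumericVector out((size_t)HW * N);
  out.attr("dim") = IntegerVector::create(d[0], d[1], 1, N);
  for (int n = 0; n < N; ++n) {
    double* q = out.begin() + (size_t)HW * n;
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)HW * (c + (size_t)C * n);
      const double* pa = a.begin() + off;
      const double* pb = b.begin() + off;
      for (int i = 0; i < HW; ++i) q[i] += pa[i] * pb[i];
    }
  }
  return out;
}

// dst += scale * v broadcast over channels (in place)
// [[Rcpp::export]]
void spatial_axpy_cpp(NumericVector dst, NumericVector v, double scale) {
  IntegerVector d = dst.attr("dim");
  const int HW = d[0] * d[1], C = d[2], N = d[3];
  for (int n = 0; n < N; ++n) {
    const double* ps = v.begin() + (size_t)HW * n;
    for (int c = 0; c < C; ++c) {
      double* q = dst.begin() + (size_t)HW * (c + (size_t)C * n);
      for (int i = 0; i < HW; ++i) q[i] += scale * ps[i];
    }
  }
}

// dst[i, amax(i)] += v(i) at the argmax channel of each position (in place)
// [[Rcpp::export]]
void spatial_max_scatter_cpp(NumericVector dst, NumericVector v,
                             IntegerVector amax) {
  IntegerVector d = dst.attr("dim");
  const int HW = d[0] * d[1], C = d[2], N = d[3];
  (void)C;
  for (int n = 0; n < N; ++n) {
    const double* pv = v.begin() + (size_t)HW * n;
    const int* pa = amax.begin() + (size_t)HW * n;
    double* base = dst.begin() + (size_t)HW * d[2] * n;
    for (int i = 0; i < HW; ++i) base[i + (size_t)HW * pa[i]] += pv[i];
  }
}

// ---- pointwise / structural helpers ---------------------------------------

// [[Rcpp::export]]
NumericVector relu_fw_cpp(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* p = x.begin();
  double* q = y.begin();
  const size_t n = x.size();
  for (size_t i = 0; i < n; ++i) q[i] = p[i] > 0 ? p[i] : 0;
  return y;
}

// [[Rcpp::export]]
NumericVector relu_bw_cpp(NumericVector dy, NumericVector y) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  const double* p = dy.begin();
  const double* py = y.begin();
  double* q = dx.begin();
  const size_t n = dy.size();
  for (size_t i = 0; i < n; ++i) q[i] = py[i] > 0 ? p[i] : 0;
  return dx;
}

// Concatenate feature maps along the channel axis.
// [[Rcpp::export]]
NumericVector concat_channels_cpp(List parts) {
  const int K = parts.size();
  std::vector<NumericVector> xs(K);
  int Ctot = 0, H = 0, W = 0, N = 0;
  for (int k = 0; k < K; ++k) {
    xs[k] = as<NumericVector>(parts[k]);
    IntegerVector d = xs[k].attr("dim");
    if (k == 0) { H = d[0]; W = d[1]; N = d[3]; }
    Ctot += d[2];
  }
  NumericVector y((size_t)H * W * Ctot * N);
  y.attr("dim") = IntegerVector::create(H, W, Ctot, N);
  const size_t HW = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    double* dst = y.begin() + HW * Ctot * n;
    for (int k = 0; k < K; ++k) {
      IntegerVector d = xs[k].attr("dim");
      const size_t blk = HW * d[2];
      std::copy(xs[k].begin() + blk * n, xs[k].begin() + blk * (n + 1), dst);
      dst += blk;
    }
  }
  return y;
}

// Slice channels [from, from+len) (1-based from).
// [[Rcpp::export]]
NumericVector slice_channels_cpp(NumericVector x, int from, int len) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t HW = (size_t)H * W;
  NumericVector y(HW * len * N);
  y.attr("dim") = IntegerVector::create(H, W, len, N);
  for (int n = 0; n < N; ++n)
    std::copy(x.begin() + HW * ((size_t)C * n + from - 1),
              x.begin() + HW * ((size_t)C * n + from - 1 + len),
              y.begin() + HW * (size_t)len * n);
  return y;
}

// ---- misc ------------------------------------------------------------------

// [[Rcpp::export]]
void fill_zero_cpp(NumericVector x) { std::fill(x.begin(), x.end(), 0.0); }

// dst += src (in place)
// [[Rcpp::export]]
void axpy_cpp(NumericVector dst, NumericVector src) {
  const size_t n = dst.size();
  const double* s = src.begin();
  double* q = dst.begin();
  for (size_t i = 0; i < n; ++i) q[i] += s[i];
}

// Decoupled-weight-decay Adam update, all vectors modified in place.
// [[Rcpp::export]]
void adamw_update_cpp(NumericVector p, NumericVector g, NumericVector m,
                      NumericVector v, double lr, double wd, double b1,
                      double b2, double eps, double bc1, double bc2) {
  const size_t n = p.size();
  double* pp = p.begin(); const double* pg = g.begin();
  double* pm = m.begin(); double* pv = v.begin();
  for (size_t i = 0; i < n; ++i) {
    pm[i] = b1 * pm[i] + (1 - b1) * pg[i];
    pv[i] = b2 * pv[i] + (1 - b2) * pg[i] * pg[i];
    pp[i] -= lr * ((pm[i] / bc1) / (std::sqrt(pv[i] / bc2) + eps) + wd * pp[i]);
  }
}
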