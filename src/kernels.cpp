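// Dense 3D tensor kernels for the network and the resampling pipeline.
// Tensor layout throughout: R numeric array with dim = c(D, H, W, C),
// column-major, so the first (axial) index varies fastest and channels are
// outermost. Convolution weights: dim = c(k, k, k, Cin, Cout), so the first
// four dimensions flatten to the im2col row index.

#include <RcppArmadillo.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int conv_outdim(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// im2col with an (N x K) layout, N = Do*Ho*Wo output voxels, K = k^3*Cin
// kernel-offset rows ordered (kd, kh, kw, ci) to match the weight flattening.
// Compute is single precision: the fill converts on the fly and GEMM runs on
// float matrices, which roughly doubles throughput on these memory-bound
// shapes; parameters and activations stay double on the R side.
static thread_local std::vector<float> g_colbuf, g_buf2, g_buf3;
// forward-pass col matrices kept for the matching backward pass (training)
static thread_local std::map<std::string, std::vector<float>> g_colcache;

static inline float* grow(std::vector<float>& v, size_t n) {
  if (v.size() < n) v.resize(n);
  return v.data();
}

static void im2col_nk(const double* x, const int* xd, const int* kd,
                      int stride, int pad, float* col, int N) {
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const int k1 = kd[0], k2 = kd[1], k3 = kd[2];
  const int Do = conv_outdim(D, k1, stride, pad);
  const int Ho = conv_outdim(H, k2, stride, pad);
  const int Wo = conv_outdim(W, k3, stride, pad);
  const int K = k1 * k2 * k3 * C;
  std::memset(col, 0, sizeof(float) * (size_t)N * K);
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + (size_t)ci * D * H * W;
    for (int c3 = 0; c3 < k3; ++c3)
      for (int c2 = 0; c2 < k2; ++c2)
        for (int c1 = 0; c1 < k1; ++c1) {
          const int k = c1 + k1 * (c2 + k2 * (c3 + k3 * ci));
          float* dstk = col + (size_t)k * N;
          int od_lo = 0;
          if (pad - c1 > 0) od_lo = (pad - c1 + stride - 1) / stride;
          int od_hi = (D - 1 + pad - c1) / stride;
          if (od_hi > Do - 1) od_hi = Do - 1;
          if (od_lo > od_hi) continue;
          const int len = od_hi - od_lo + 1;
          for (int ow = 0; ow < Wo; ++ow) {
            const int iw = ow * stride - pad + c3;
            if (iw < 0 || iw >= W) continue;
            for (int oh = 0; oh < Ho; ++oh) {
              const int ih = oh * stride - pad + c2;
              if (ih < 0 || ih >= H) continue;
              const double* src = xc + (od_lo * stride - pad + c1)
                                + (size_t)D * (ih + (size_t)H * iw);
              float* dst = dstk + od_lo + (size_t)Do * (oh + (size_t)Ho * ow);
              if (stride == 1)
                for (int i = 0; i < len; ++i) dst[i] = (float)src[i];
              else
                for (int i = 0; i < len; ++i) dst[i] = (float)src[i * stride];
            }
          }
        }
  }
}

static void col2im_nk(const float* col, const int* xd, const int* kd,
                      int stride, int pad, double* dx, int N) {
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const int k1 = kd[0], k2 = kd[1], k3 = kd[2];
  const int Do = conv_outdim(D, k1, stride, pad);
  const int Ho = conv_outdim(H, k2, stride, pad);
  const int Wo = conv_outdim(W, k3, stride, pad);
  for (int ci = 0; ci < C; ++ci) {
    double* xc = dx + (size_t)ci * D * H * W;
    for (int c3 = 0; c3 < k3; ++c3)
      for (int c2 = 0; c2 < k2; ++c2)
        for (int c1 = 0; c1 < k1; ++c1) {
          const int k = c1 + k1 * (c2 + k2 * (c3 + k3 * ci));
          const float* srck = col + (size_t)k * N;
          int od_lo = 0;
          if (pad - c1 > 0) od_lo = (pad - c1 + stride - 1) / stride;
          int od_hi = (D - 1 + pad - c1) / stride;
          if (od_hi > Do - 1) od_hi = Do - 1;
          if (od_lo > od_hi) continue;
          const int len = od_hi - od_lo + 1;
          for (int ow = 0; ow < Wo; ++ow) {
            const int iw = ow * stride - pad + c3;
            if (iw < 0 || iw >= W) continue;
            for (int oh = 0; oh < Ho; ++oh) {
              const int ih = oh * stride - pad + c2;
              if (ih < 0 || ih >= H) continue;
              double* dst = xc + (od_lo * stride - pad + c1)
                          + (size_t)D * (ih + (size_t)H * iw);
              const float* src = srck + od_lo
                               + (size_t)Do * (oh + (size_t)Ho * ow);
              if (stride == 1)
                for (int i = 0; i < len; ++i) dst[i] += (double)src[i];
              else
                for (int i = 0; i < len; ++i)
                  dst[i * stride] += (double)src[i];
            }
          }
        }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector kdim,
                             int stride, int pad,
                             Nullable<NumericVector> bias,
                             Nullable<CharacterVector> cache_key) {
  const int* xd = xdim.begin();
  const int* kd = kdim.begin();
  const int Cin = kd[3], Cout = kd[4];
  if (xd[3] != Cin) stop("conv3d: channel mismatch");
  const int K = kd[0] * kd[1] * kd[2] * Cin;
  const int Do = conv_outdim(xd[0], kd[0], stride, pad);
  const int Ho = conv_outdim(xd[1], kd[1], stride, pad);
  const int Wo = conv_outdim(xd[2], kd[2], stride, pad);
  const int N = Do * Ho * Wo;
  float* colp;
  if (cache_key.isNotNull()) {
    std::string key = Rcpp::as<std::string>(CharacterVector(cache_key)[0]);
    colp = grow(g_colcache[key], (size_t)N * K);
  } else {
    colp = grow(g_colbuf, (size_t)N * K);
  }
  im2col_nk(x.begin(), xd, kd, stride, pad, colp, N);
  arma::fmat col(colp, N, K, false, true);
  arma::fmat Wf(K, Cout);
  std::copy(w.begin(), w.end(), Wf.memptr());
  arma::fmat Yf = col * Wf;
  NumericVector out((size_t)N * Cout);
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (int c = 0; c < Cout; ++c) {
      const float* yc = Yf.colptr(c);
      double* oc = out.begin() + (size_t)c * N;
      const double bc = b[c];
      for (int i = 0; i < N; ++i) oc[i] = (double)yc[i] + bc;
    }
  } else {
    const float* yp = Yf.memptr();
    double* op = out.begin();
    for (size_t i = 0; i < (size_t)N * Cout; ++i) op[i] = (double)yp[i];
  }
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, Cout);
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector xdim,
                    NumericVector w, IntegerVector kdim,
                    NumericVector dy, int stride, int pad, bool has_bias,
                    bool need_dx, Nullable<CharacterVector> cache_key) {
  const int* xd = xdim.begin();
  const int* kd = kdim.begin();
  const int Cin = kd[3], Cout = kd[4];
  const int K = kd[0] * kd[1] * kd[2] * Cin;
  const int Do = conv_outdim(xd[0], kd[0], stride, pad);
  const int Ho = conv_outdim(xd[1], kd[1], stride, pad);
  const int Wo = conv_outdim(xd[2], kd[2], stride, pad);
  const int N = Do * Ho * Wo;
  float* colp = NULL;
  if (cache_key.isNotNull()) {
    std::string key = Rcpp::as<std::string>(CharacterVector(cache_key)[0]);
    auto it = g_colcache.find(key);
    if (it != g_colcache.end() && it->second.size() >= (size_t)N * K)
      colp = it->second.data();
  }
  if (colp == NULL) {
    colp = grow(g_colbuf, (size_t)N * K);
    im2col_nk(x.begin(), xd, kd, stride, pad, colp, N);
  }
  arma::fmat col(colp, N, K, false, true);
  float* dyp = grow(g_buf2, (size_t)N * Cout);
  for (size_t i = 0; i < (size_t)N * Cout; ++i) dyp[i] = (float)dy[i];
  arma::fmat dYf(dyp, N, Cout, false, true);
  arma::fmat dWf = col.t() * dYf;                 // K x Cout
  NumericVector dwv((size_t)K * Cout);
  const float* dwp = dWf.memptr();
  for (size_t i = 0; i < (size_t)K * Cout; ++i) dwv[i] = (double)dwp[i];
  dwv.attr("dim") = kdim;
  List res = List::create(Named("dw") = dwv);
  if (need_dx) {
    arma::fmat Wf(K, Cout);
    std::copy(w.begin(), w.end(), Wf.memptr());
    float* dcolp = grow(g_buf3, (size_t)N * K);
    arma::fmat dcol(dcolp, N, K, false, true);
    dcol = dYf * Wf.t();                          // N x K
    NumericVector dxv((size_t)xd[0] * xd[1] * xd[2] * xd[3]);
    col2im_nk(dcolp, xd, kd, stride, pad, dxv.begin(), N);
    dxv.attr("dim") = IntegerVector::create(xd[0], xd[1], xd[2], xd[3]);
    res["dx"] = dxv;
  }
  if (has_bias) {
    NumericVector db(Cout);
    for (int c = 0; c < Cout; ++c) {
      double sum_ = 0;
      const double* dc = dy.begin() + (size_t)c * N;
      for (int i = 0; i < N; ++i) sum_ += dc[i];
      db[c] = sum_;
    }
    res["db"] = db;
  }
  return res;
}

// [[Rcpp::export]]
List cpp_maxpool3d_fwd(NumericVector x, IntegerVector xdim,
                       int k, int stride, int pad) {
  const int* xd = xdim.begin();
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const int Do = conv_outdim(D, k, stride, pad);
  const int Ho = conv_outdim(H, k, stride, pad);
  const int Wo = conv_outdim(W, k, stride, pad);
  const size_t N = (size_t)Do * Ho * Wo * C;
  NumericVector out(N);
  IntegerVector idx(N);
  const double* xp = x.begin();
  size_t o = 0;
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)c * D * H * W;
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh)
        for (int od = 0; od < Do; ++od) {
          double best = -HUGE_VAL; int bi = -1;
          for (int c3 = 0; c3 < k; ++c3) {
            const int iw = ow * stride - pad + c3;
            if (iw < 0 || iw >= W) continue;
            for (int c2 = 0; c2 < k; ++c2) {
              const int ih = oh * stride - pad + c2;
              if (ih < 0 || ih >= H) continue;
              for (int c1 = 0; c1 < k; ++c1) {
                const int id = od * stride - pad + c1;
                if (id < 0 || id >= D) continue;
                const size_t li = id + (size_t)D * (ih + (size_t)H * iw);
                if (xc[li] > best) { best = xc[li]; bi = (int)li; }
              }
            }
          }
          // out voxel order must be (Do,Ho,Wo,C): index od + Do*(oh + Ho*(ow + Wo*c))
          const size_t oo = od + (size_t)Do * (oh + (size_t)Ho * (ow + (size_t)Wo * c));
          out[oo] = best;
          idx[oo] = bi + c * D * H * W;  // linear index into full input
          (void)o;
        }
  }
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, C);
  return List::create(Named("y") = out, Named("idx") = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bwd(IntegerVector idx, NumericVector dy,
                                IntegerVector xdim) {
  const size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  dx.attr("dim") = xdim;
  return dx;
}

// batch-norm forward over spatial voxels per channel (training statistics
// supplied by the caller); returns y and caches xhat for the backward pass
// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, IntegerVector xdim, NumericVector gamma,
                NumericVector beta, NumericVector mu, NumericVector invstd) {
  const size_t nv = (size_t)xdim[0] * xdim[1] * xdim[2];
  const int C = xdim[3];
  NumericVector y(nv * C), xhat(nv * C);
  for (int c = 0; c < C; ++c) {
    const double m = mu[c], is = invstd[c], g = gamma[c], b = beta[c];
    const double* xc = x.begin() + nv * c;
    double* yc = y.begin() + nv * c;
    double* hc = xhat.begin() + nv * c;
    for (size_t i = 0; i < nv; ++i) {
      const double h = (xc[i] - m) * is;
      hc[i] = h;
      yc[i] = g * h + b;
    }
  }
  y.attr("dim") = xdim;
  return List::create(Named("y") = y, Named("xhat") = xhat);
}

// [[Rcpp::export]]
NumericVector cpp_bn_stats(NumericVector x, IntegerVector xdim) {
  const size_t nv = (size_t)xdim[0] * xdim[1] * xdim[2];
  const int C = xdim[3];
  NumericVector out(2 * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + nv * c;
    double s = 0, s2 = 0;
    for (size_t i = 0; i < nv; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    const double m = s / nv;
    out[c] = m;
    out[C + c] = s2 / nv - m * m;
  }
  return out;  // first C entries mean, next C biased variance
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector dy, NumericVector xhat, IntegerVector xdim,
                NumericVector gamma, NumericVector invstd) {
  const size_t nv = (size_t)xdim[0] * xdim[1] * xdim[2];
  const int C = xdim[3];
  NumericVector dx(nv * C), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* dyc = dy.begin() + nv * c;
    const double* hc = xhat.begin() + nv * c;
    double sd = 0, sdh = 0;
    for (size_t i = 0; i < nv; ++i) { sd += dyc[i]; sdh += dyc[i] * hc[i]; }
    dgamma[c] = sdh;
    dbeta[c] = sd;
    const double mdy = sd / nv, mdyh = sdh / nv;
    const double gis = gamma[c] * invstd[c];
    double* dxc = dx.begin() + nv * c;
    for (size_t i = 0; i < nv; ++i)
      dxc[i] = gis * (dyc[i] - mdy - hc[i] * mdyh);
  }
  dx.attr("dim") = xdim;
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}

// 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher)
static void edt1d(const double* f, double* d, int n,
                  std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0; z[0] = -HUGE_VAL; z[1] = HUGE_VAL;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k]))
               / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k]))
          / (2.0 * q - 2.0 * v[k]);
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = HUGE_VAL;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Euclidean distance (in voxels) from each nonzero voxel to the nearest zero
// voxel; voxels outside the array border count as background.
// [[Rcpp::export]]
NumericVector cpp_edt3d(NumericVector mask, IntegerVector mdim) {
  const int D = mdim[0], H = mdim[1], W = mdim[2];
  const size_t n = (size_t)D * H * W;
  std::vector<double> g(n);
  const double INF = 1e18;
  for (size_t i = 0; i < n; ++i) g[i] = mask[i] != 0 ? INF : 0.0;
  const int nmax = std::max(D, std::max(H, W));
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1), f(nmax), d(nmax);
  // pass along D (contiguous)
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      double* col = g.data() + (size_t)D * (h + (size_t)H * w);
      // border behaves as background: cap by distance to the array edge
      edt1d(col, d.data(), D, v, z);
      for (int i = 0; i < D; ++i) {
        double edge = (double)std::min(i + 1, D - i);
        col[i] = std::min(d[i], edge * edge);
      }
    }
  // pass along H
  for (int w = 0; w < W; ++w)
    for (int dd = 0; dd < D; ++dd) {
      for (int h = 0; h < H; ++h) f[h] = g[dd + (size_t)D * (h + (size_t)H * w)];
      edt1d(f.data(), d.data(), H, v, z);
      for (int h = 0; h < H; ++h) {
        double edge = (double)std::min(h + 1, H - h);
        g[dd + (size_t)D * (h + (size_t)H * w)] = std::min(d[h], edge * edge);
      }
    }
  // pass along W
  for (int h = 0; h < H; ++h)
    for (int dd = 0; dd < D; ++dd) {
      for (int w = 0; w < W; ++w) f[w] = g[dd + (size_t)D * (h + (size_t)H * w)];
      edt1d(f.data(), d.data(), W, v, z);
      for (int w = 0; w < W; ++w) {
        double edge = (double)std::min(w + 1, W - w);
        g[dd + (size_t)D * (h + (size_t)H * w)] = std::min(d[w], edge * edge);
      }
    }
  NumericVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  out.attr("dim") = mdim;
  return out;
}

struct AxisMap {
  std::vector<int> i0, i1;
  std::vector<double> f;  // weight of i1
};

// half-pixel-centre sampling (align_corners = FALSE), clamped at the edges
static AxisMap axis_map(int nin, int nout) {
  AxisMap m;
  m.i0.resize(nout); m.i1.resize(nout); m.f.resize(nout);
  const double scale = (double)nin / nout;
  for (int i = 0; i < nout; ++i) {
    double s = (i + 0.5) * scale - 0.5;
    if (s < 0) s = 0;
    if (s > nin - 1) s = nin - 1;
    int i0 = (int)std::floor(s);
    int i1 = std::min(i0 + 1, nin - 1);
    m.i0[i] = i0; m.i1[i] = i1; m.f[i] = s - i0;
  }
  return m;
}

// [[Rcpp::export]]
NumericVector cpp_resize3d(NumericVector x, IntegerVector xdim,
                           IntegerVector odim) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  const int Do = odim[0], Ho = odim[1], Wo = odim[2];
  AxisMap md = axis_map(D, Do), mh = axis_map(H, Ho), mw = axis_map(W, Wo);
  NumericVector out((size_t)Do * Ho * Wo * C);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)c * D * H * W;
    double* oc = op + (size_t)c * Do * Ho * Wo;
    for (int ow = 0; ow < Wo; ++ow) {
      const int w0 = mw.i0[ow], w1 = mw.i1[ow]; const double fw = mw.f[ow];
      for (int oh = 0; oh < Ho; ++oh) {
        const int h0 = mh.i0[oh], h1 = mh.i1[oh]; const double fh = mh.f[oh];
        const double* p00 = xc + (size_t)D * (h0 + (size_t)H * w0);
        const double* p10 = xc + (size_t)D * (h1 + (size_t)H * w0);
        const double* p01 = xc + (size_t)D * (h0 + (size_t)H * w1);
        const double* p11 = xc + (size_t)D * (h1 + (size_t)H * w1);
        double* orow = oc + (size_t)Do * (oh + (size_t)Ho * ow);
        for (int od = 0; od < Do; ++od) {
          const int d0 = md.i0[od], d1 = md.i1[od]; const double fd = md.f[od];
          const double v00 = p00[d0] * (1 - fd) + p00[d1] * fd;
          const double v10 = p10[d0] * (1 - fd) + p10[d1] * fd;
          const double v01 = p01[d0] * (1 - fd) + p01[d1] * fd;
          const double v11 = p11[d0] * (1 - fd) + p11[d1] * fd;
          orow[od] = (v00 * (1 - fh) + v10 * fh) * (1 - fw)
                   + (v01 * (1 - fh) + v11 * fh) * fw;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, C);
  return out;
}

// Adjoint of cpp_resize3d: scatter output-grid gradients back to the input grid.
// [[Rcpp::export]]
NumericVector cpp_resize3d_adjoint(NumericVector dy, IntegerVector odim,
                                   IntegerVector xdim) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  const int Do = odim[0], Ho = odim[1], Wo = odim[2];
  AxisMap md = axis_map(D, Do), mh = axis_map(H, Ho), mw = axis_map(W, Wo);
  NumericVector dx((size_t)D * H * W * C);
  const double* gp = dy.begin();
  double* xp = dx.begin();
  for (int c = 0; c < C; ++c) {
    double* xc = xp + (size_t)c * D * H * W;
    const double* gc = gp + (size_t)c * Do * Ho * Wo;
    for (int ow = 0; ow < Wo; ++ow) {
      const int w0 = mw.i0[ow], w1 = mw.i1[ow]; const double fw = mw.f[ow];
      for (int oh = 0; oh < Ho; ++oh) {
        const int h0 = mh.i0[oh], h1 = mh.i1[oh]; const double fh = mh.f[oh];
        const double* grow = gc + (size_t)Do * (oh + (size_t)Ho * ow);
        for (int od = 0; od < Do; ++od) {
          const int d0 = md.i0[od], d1 = md.i1[od]; const double fd = md.f[od];
          const double g = grow[od];
          const double wd0 = 1 - fd, wd1 = fd;
          const double wh0 = 1 - fh, wh1 = fh;
          const double ww0 = 1 - fw, ww1 = fw;
          xc[d0 + (size_t)D * (h0 + (size_t)H * w0)] += g * wd0 * wh0 * ww0;
          xc[d1 + (size_t)D * (h0 + (size_t)H * w0)] += g * wd1 * wh0 * ww0;
          xc[d0 + (size_t)D * (h1 + (size_t)H * w0)] += g * wd0 * wh1 * ww0;
          xc[d1 + (size_t)D * (h1 + (size_t)H * w0)] += g * wd1 * wh1 * ww0;
          xc[d0 + (size_t)D * (h0 + (size_t)H * w1)] += g * wd0 * wh0 * ww1;
          xc[d1 + (size_t)D * (h0 + (size_t)H * w1)] += g * wd1 * wh0 * ww1;
          xc[d0 + (size_t)D * (h1 + (size_t)H * w1)] += g * wd0 * wh1 * ww1;
          xc[d1 + (size_t)D * (h1 + (size_t)H * w1)] += g * wd1 * wh1 * ww1;
        }
      }
    }
  }
  dx.attr("dim") = xdim;
  return dx;
}
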