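// Low-level numeric kernels for the network.
//
// Feature maps are dense matrices with one row per channel and one column
// per pixel; the column index of pixel (x, y) of batch item n is
// s = n*H*W + y*W + x (0-based, x fastest). Matrices are column-major, so
// one pixel's channel vector is contiguous and a row of pixels is one long
// contiguous span; the kernels below turn every hot loop into flat spans
// over such contiguous memory, with per-channel coefficients pre-tiled
// along the span. The toolchain targets a baseline ISA, so the flat loops
// are multi-versioned (target_clones) and dispatch to AVX2+FMA at run time
// where available.

#include <Rcpp.h>
#include <cstring>
#if defined(__GLIBC__)
#include <malloc.h>
#endif
using namespace Rcpp;

// The training loop churns through many MB-sized activation buffers per
// step. glibc serves such blocks with mmap/munmap by default, which makes
// every allocation fault its pages back in; keeping them on the free list
// removes that cost.
namespace {
struct MallocTuner {
  MallocTuner() {
#if defined(__GLIBC__)
    mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
    mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
  }
};
MallocTuner malloc_tuner_;
}

#define RSTRCT __restrict__

#if defined(__GNUC__) && !defined(__clang__) && defined(__x86_64__)
#define CLONES __attribute__((target_clones("avx2,fma", "default")))
#else
#define CLONES
#endif

// uninitialized allocations for pure-write outputs (accumulating kernels
// still use the zero-filled constructors)
static inline NumericMatrix alloc_mat(int nr, int nc) {
  return NumericMatrix(Rf_allocMatrix(REALSXP, nr, nc));
}

// ---------------------------------------------------------------------------
// flat span helpers (the only compute-heavy loops)

CLONES static void span_fma(double* RSTRCT y, const double* RSTRCT x,
                            const double* RSTRCT w, size_t n) {
  for (size_t i = 0; i < n; ++i) y[i] += w[i] * x[i];
}

CLONES static void span_fma2(double* RSTRCT dx, double* RSTRCT acc,
                             const double* RSTRCT g, const double* RSTRCT x,
                             const double* RSTRCT w, size_t n) {
  for (size_t i = 0; i < n; ++i) {
    dx[i] += w[i] * g[i];
    acc[i] += g[i] * x[i];
  }
}

CLONES static void span_add(double* RSTRCT y, const double* RSTRCT x,
                            size_t n) {
  for (size_t i = 0; i < n; ++i) y[i] += x[i];
}

CLONES static void span_moments(double* RSTRCT s1, double* RSTRCT s2,
                                const double* RSTRCT x, size_t n) {
  for (size_t i = 0; i < n; ++i) {
    s1[i] += x[i];
    s2[i] += x[i] * x[i];
  }
}

CLONES static void span_bn_lrelu(double* RSTRCT q, const double* RSTRCT p,
                                 const double* RSTRCT a,
                                 const double* RSTRCT b, double slope,
                                 size_t n) {
  for (size_t i = 0; i < n; ++i) {
    const double z = p[i] * a[i] + b[i];
    q[i] = std::max(z, 0.0) + slope * std::min(z, 0.0);
  }
}

CLONES static void span_bn_lrelu_acc(double* RSTRCT dg, double* RSTRCT db,
                                     const double* RSTRCT g,
                                     const double* RSTRCT y,
                                     const double* RSTRCT bt,
                                     const double* RSTRCT ig, double islope,
                                     double slope, size_t n) {
  const double zf = 1.0 - islope, df = 1.0 - slope;
  for (size_t i = 0; i < n; ++i) {
    // branchless strict indicator of y > 0 (exact for non-subnormal y)
    const double f = std::max(0.0, std::min(1.0, y[i] * 1e300));
    const double z = y[i] * (islope + zf * f);
    const double d = g[i] * (slope + df * f);
    dg[i] += d * (z - bt[i]) * ig[i];
    db[i] += d;
  }
}

CLONES static void span_bn_lrelu_dx(double* RSTRCT out,
                                    const double* RSTRCT g,
                                    const double* RSTRCT y,
                                    const double* RSTRCT bt,
                                    const double* RSTRCT ig,
                                    const double* RSTRCT is,
                                    const double* RSTRCT gm,
                                    const double* RSTRCT mg,
                                    const double* RSTRCT mgh, double islope,
                                    double slope, size_t n) {
  const double zf = 1.0 - islope, df = 1.0 - slope;
  for (size_t i = 0; i < n; ++i) {
    const double f = std::max(0.0, std::min(1.0, y[i] * 1e300));
    const double z = y[i] * (islope + zf * f);
    const double dz = g[i] * (slope + df * f);
    const double xh = (z - bt[i]) * ig[i];
    out[i] = is[i] * (gm[i] * dz - mg[i] - xh * mgh[i]);
  }
}

CLONES static void span_lrelu(double* RSTRCT y, const double* RSTRCT x,
                              double slope, size_t n) {
  for (size_t i = 0; i < n; ++i)
    y[i] = std::max(x[i], 0.0) + slope * std::min(x[i], 0.0);
}

CLONES static void span_lrelu_bwd(double* RSTRCT d, const double* RSTRCT g,
                                  const double* RSTRCT y, double slope,
                                  size_t n) {
  const double df = 1.0 - slope;
  for (size_t i = 0; i < n; ++i) {
    const double f = std::max(0.0, std::min(1.0, y[i] * 1e300));
    d[i] = g[i] * (slope + df * f);
  }
}

CLONES static void span_bn_apply(double* RSTRCT h, double* RSTRCT q,
                                 const double* RSTRCT p,
                                 const double* RSTRCT iv,
                                 const double* RSTRCT mu,
                                 const double* RSTRCT gm,
                                 const double* RSTRCT bt, size_t n) {
  for (size_t i = 0; i < n; ++i) {
    h[i] = (p[i] - mu[i]) * iv[i];
    q[i] = h[i] * gm[i] + bt[i];
  }
}

CLONES static void span_bn_bwd_acc(double* RSTRCT dg, double* RSTRCT db,
                                   const double* RSTRCT g,
                                   const double* RSTRCT h, size_t n) {
  for (size_t i = 0; i < n; ++i) {
    dg[i] += g[i] * h[i];
    db[i] += g[i];
  }
}

CLONES static void span_bn_bwd_dx(double* RSTRCT d, const double* RSTRCT g,
                                  const double* RSTRCT h,
                                  const double* RSTRCT iv,
                                  const double* RSTRCT gm,
                                  const double* RSTRCT mg,
                                  const double* RSTRCT mgh, size_t n) {
  for (size_t i = 0; i < n; ++i)
    d[i] = iv[i] * (gm[i] * g[i] - mg[i] - h[i] * mgh[i]);
}

// tile a length-C coefficient vector along a span of L = G*C entries
static void tile_coef(std::vector<double>& dst, const double* src, int C,
                      size_t L) {
  for (int c = 0; c < C; ++c) dst[c] = src[c];
  for (size_t i = C; i < L; ++i) dst[i] = dst[i - C];
}

static inline size_t tile_len(int C) {
  const int G = std::max<int>(1, 512 / C);
  return (size_t)G * C;
}

// ---------------------------------------------------------------------------
// depth-wise 3x3 convolution, zero padding 1, stride 1.
// W9: one 3x3 kernel per channel, stored C x 9 with k = (ky+1)*3 + (kx+1).

// [[Rcpp::export]]
NumericMatrix cpp_dw3_fwd(const NumericMatrix& X, const NumericMatrix& W9,
                          int H, int W, int N) {
  const int C = X.nrow();
  NumericMatrix Y(C, X.ncol());
  const double* RSTRCT Xp = X.begin();
  const double* RSTRCT Wp = W9.begin();
  double* RSTRCT Yp = Y.begin();
  // tile each tap's per-channel weights across a full row of pixels
  std::vector<double> wt((size_t)9 * W * C);
  int ylo[9], yhi[9], xlo[9], xhi[9];
  for (int k = 0; k < 9; ++k) {
    const int dy = k / 3 - 1, dx = k % 3 - 1;
    ylo[k] = std::max(0, -dy); yhi[k] = std::min(H, H - dy);
    xlo[k] = std::max(0, -dx); xhi[k] = std::min(W, W - dx);
    for (int j = 0; j < W; ++j)
      std::memcpy(wt.data() + ((size_t)k * W + j) * C, Wp + (size_t)k * C,
                  C * sizeof(double));
  }
  // row-blocked: one output row stays cache-hot across all nine taps
  for (int n = 0; n < N; ++n) {
    const size_t base = (size_t)n * H * W;
    for (int y = 0; y < H; ++y) {
      double* RSTRCT yrow = Yp + (base + (size_t)y * W) * C;
      for (int k = 0; k < 9; ++k) {
        if (y < ylo[k] || y >= yhi[k]) continue;
        const int dy = k / 3 - 1, dx = k % 3 - 1;
        const size_t len = (size_t)(xhi[k] - xlo[k]) * C;
        if (!len) continue;
        span_fma(yrow + (size_t)xlo[k] * C,
                 Xp + (base + (size_t)(y + dy) * W + (xlo[k] + dx)) * C,
                 wt.data() + (size_t)k * W * C, len);
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
List cpp_dw3_bwd(const NumericMatrix& dY, const NumericMatrix& X,
                 const NumericMatrix& W9, int H, int W, int N) {
  const int C = X.nrow();
  NumericMatrix dX(C, X.ncol());
  NumericMatrix dW(C, 9);
  const double* RSTRCT Xp = X.begin();
  const double* RSTRCT Wp = W9.begin();
  const double* RSTRCT dYp = dY.begin();
  double* RSTRCT dXp = dX.begin();
  double* RSTRCT dWp = dW.begin();
  std::vector<double> wt((size_t)9 * W * C);
  std::vector<double> ga((size_t)9 * W * C, 0.0);
  int ylo[9], yhi[9], xlo[9], xhi[9];
  for (int k = 0; k < 9; ++k) {
    const int dy = k / 3 - 1, dx = k % 3 - 1;
    ylo[k] = std::max(0, -dy); yhi[k] = std::min(H, H - dy);
    xlo[k] = std::max(0, -dx); xhi[k] = std::min(W, W - dx);
    for (int j = 0; j < W; ++j)
      std::memcpy(wt.data() + ((size_t)k * W + j) * C, Wp + (size_t)k * C,
                  C * sizeof(double));
  }
  for (int n = 0; n < N; ++n) {
    const size_t base = (size_t)n * H * W;
    for (int y = 0; y < H; ++y) {
      const double* RSTRCT grow = dYp + (base + (size_t)y * W) * C;
      for (int k = 0; k < 9; ++k) {
        if (y < ylo[k] || y >= yhi[k]) continue;
        const int dy = k / 3 - 1, dx = k % 3 - 1;
        const size_t len = (size_t)(xhi[k] - xlo[k]) * C;
        if (!len) continue;
        const size_t si0 = (base + (size_t)(y + dy) * W + (xlo[k] + dx)) * C;
        span_fma2(dXp + si0, ga.data() + (size_t)k * W * C,
                  grow + (size_t)xlo[k] * C, Xp + si0,
                  wt.data() + (size_t)k * W * C, len);
      }
    }
  }
  for (int k = 0; k < 9; ++k) {
    double* RSTRCT dwk = dWp + (size_t)k * C;
    const double* RSTRCT gak = ga.data() + (size_t)k * W * C;
    for (int j = 0; j < W; ++j)
      for (int c = 0; c < C; ++c) dwk[c] += gak[(size_t)j * C + c];
  }
  return List::create(_["dX"] = dX, _["dW"] = dW);
}

// ---------------------------------------------------------------------------
// im2col for a 3x3 kernel with dilation, zero padding dil, stride 1.
// Output row index r = k*C + c so the weight matrix is Cout x (9*C) with
// column index k*C + c.

// [[Rcpp::export]]
NumericMatrix cpp_im2col3(const NumericMatrix& X, int H, int W, int N,
                          int dil) {
  const int C = X.nrow();
  NumericMatrix cols(9 * C, X.ncol());
  const double* RSTRCT Xp = X.begin();
  double* RSTRCT Cp = cols.begin();
  const size_t R = 9 * (size_t)C;
  for (int k = 0; k < 9; ++k) {
    const int dy = (k / 3 - 1) * dil, dx = (k % 3 - 1) * dil;
    const int ylo = std::max(0, -dy), yhi = std::min(H, H - dy);
    const int xlo = std::max(0, -dx), xhi = std::min(W, W - dx);
    for (int n = 0; n < N; ++n) {
      const size_t base = (size_t)n * H * W;
      for (int y = ylo; y < yhi; ++y) {
        size_t so = base + (size_t)y * W + xlo;
        size_t si = base + (size_t)(y + dy) * W + (xlo + dx);
        for (int x = xlo; x < xhi; ++x, ++so, ++si)
          std::memcpy(Cp + so * R + (size_t)k * C, Xp + si * C,
                      C * sizeof(double));
      }
    }
  }
  return cols;
}

// adjoint of cpp_im2col3 (scatter-add back to the input layout)
// [[Rcpp::export]]
NumericMatrix cpp_col2im3(const NumericMatrix& cols, int C, int H, int W,
                          int N, int dil) {
  NumericMatrix dX(C, N * H * W);
  const double* RSTRCT Cp = cols.begin();
  double* RSTRCT dXp = dX.begin();
  const size_t R = 9 * (size_t)C;
  for (int k = 0; k < 9; ++k) {
    const int dy = (k / 3 - 1) * dil, dx = (k % 3 - 1) * dil;
    const int ylo = std::max(0, -dy), yhi = std::min(H, H - dy);
    const int xlo = std::max(0, -dx), xhi = std::min(W, W - dx);
    for (int n = 0; n < N; ++n) {
      const size_t base = (size_t)n * H * W;
      for (int y = ylo; y < yhi; ++y) {
        size_t so = base + (size_t)y * W + xlo;
        size_t si = base + (size_t)(y + dy) * W + (xlo + dx);
        for (int x = xlo; x < xhi; ++x, ++so, ++si)
          span_add(dXp + si * C, Cp + so * R + (size_t)k * C, C);
      }
    }
  }
  return dX;
}

// ---------------------------------------------------------------------------
// 2x2 max pooling, stride 2. Returns pooled map and 0-based argmax source
// columns (first occurrence in row-major window order on ties).

// [[Rcpp::export]]
List cpp_maxpool2_fwd(const NumericMatrix& X, int H, int W, int N) {
  const int C = X.nrow();
  const int Ho = H / 2, Wo = W / 2;
  NumericMatrix Y = alloc_mat(C, N * Ho * Wo);
  IntegerMatrix idx(Rf_allocMatrix(INTSXP, C, N * Ho * Wo));
  const double* RSTRCT Xp = X.begin();
  double* RSTRCT Yp = Y.begin();
  int* RSTRCT Ip = idx.begin();
  for (int n = 0; n < N; ++n) {
    const size_t base = (size_t)n * H * W;
    const size_t baseo = (size_t)n * Ho * Wo;
    for (int y = 0; y < Ho; ++y) {
      for (int x = 0; x < Wo; ++x) {
        const size_t so = baseo + (size_t)y * Wo + x;
        const size_t s00 = base + (size_t)(2 * y) * W + 2 * x;
        const size_t cand[4] = {s00, s00 + 1, s00 + W, s00 + W + 1};
        double* RSTRCT yp = Yp + so * C;
        int* RSTRCT ip = Ip + so * C;
        for (int c = 0; c < C; ++c) {
          double best = Xp[cand[0] * C + c];
          int besti = 0;
          for (int q = 1; q < 4; ++q) {
            const double v = Xp[cand[q] * C + c];
            besti = v > best ? q : besti;
            best = v > best ? v : best;
          }
          yp[c] = best;
          ip[c] = (int)cand[besti];
        }
      }
    }
  }
  return List::create(_["y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool2_bwd(const NumericMatrix& dY,
                               const IntegerMatrix& idx, int Pin) {
  const int C = dY.nrow();
  NumericMatrix dX(C, Pin);
  const double* RSTRCT gp = dY.begin();
  const int* RSTRCT ip = idx.begin();
  double* RSTRCT dp = dX.begin();
  const size_t ncol = dY.ncol();
  for (size_t s = 0; s < ncol; ++s)
    for (int c = 0; c < C; ++c)
      dp[(size_t)ip[s * C + c] * C + c] += gp[s * C + c];
  return dX;
}

// ---------------------------------------------------------------------------
// bilinear resize of every batch item from H x W to Ho x Wo
// (half-pixel-centre source mapping, edges clamped)

static inline void bilin_coef(int o, int in, int out, int& i0, int& i1,
                              double& w1) {
  double s = (o + 0.5) * (double)in / out - 0.5;
  if (s < 0) s = 0;
  if (s > in - 1) s = in - 1;
  i0 = (int)std::floor(s);
  i1 = i0 + 1 < in ? i0 + 1 : i0;
  w1 = s - i0;
}

// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(const NumericMatrix& X, int H, int W,
                                  int N, int Ho, int Wo) {
  const int C = X.nrow();
  NumericMatrix Y = alloc_mat(C, N * Ho * Wo);
  std::vector<int> x0(Wo), x1(Wo), y0(Ho), y1(Ho);
  std::vector<double> wx(Wo), wy(Ho);
  for (int x = 0; x < Wo; ++x) bilin_coef(x, W, Wo, x0[x], x1[x], wx[x]);
  for (int y = 0; y < Ho; ++y) bilin_coef(y, H, Ho, y0[y], y1[y], wy[y]);
  const double* RSTRCT Xp = X.begin();
  double* RSTRCT Yp = Y.begin();
  for (int n = 0; n < N; ++n) {
    const size_t base = (size_t)n * H * W;
    const size_t baseo = (size_t)n * Ho * Wo;
    for (int y = 0; y < Ho; ++y) {
      for (int x = 0; x < Wo; ++x) {
        const size_t so = baseo + (size_t)y * Wo + x;
        const double* RSTRCT p00 = Xp + (base + (size_t)y0[y] * W + x0[x]) * C;
        const double* RSTRCT p01 = Xp + (base + (size_t)y0[y] * W + x1[x]) * C;
        const double* RSTRCT p10 = Xp + (base + (size_t)y1[y] * W + x0[x]) * C;
        const double* RSTRCT p11 = Xp + (base + (size_t)y1[y] * W + x1[x]) * C;
        const double a = wy[y], b = wx[x];
        const double w00 = (1 - a) * (1 - b), w01 = (1 - a) * b;
        const double w10 = a * (1 - b), w11 = a * b;
        double* RSTRCT yp = Yp + so * C;
        for (int c = 0; c < C; ++c)
          yp[c] = w00 * p00[c] + w01 * p01[c] + w10 * p10[c] + w11 * p11[c];
      }
    }
  }
  return Y;
}

// exact adjoint of cpp_resize_bilinear (gradients at Ho x Wo scattered back
// to H x W)
// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear_adj(const NumericMatrix& dY, int H, int W,
                                      int N, int Ho, int Wo) {
  const int C = dY.nrow();
  NumericMatrix dX(C, N * H * W);
  std::vector<int> x0(Wo), x1(Wo), y0(Ho), y1(Ho);
  std::vector<double> wx(Wo), wy(Ho);
  for (int x = 0; x < Wo; ++x) bilin_coef(x, W, Wo, x0[x], x1[x], wx[x]);
  for (int y = 0; y < Ho; ++y) bilin_coef(y, H, Ho, y0[y], y1[y], wy[y]);
  const double* RSTRCT dYp = dY.begin();
  double* RSTRCT dXp = dX.begin();
  for (int n = 0; n < N; ++n) {
    const size_t base = (size_t)n * H * W;
    const size_t baseo = (size_t)n * Ho * Wo;
    for (int y = 0; y < Ho; ++y) {
      for (int x = 0; x < Wo; ++x) {
        const size_t so = baseo + (size_t)y * Wo + x;
        double* RSTRCT p00 = dXp + (base + (size_t)y0[y] * W + x0[x]) * C;
        double* RSTRCT p01 = dXp + (base + (size_t)y0[y] * W + x1[x]) * C;
        double* RSTRCT p10 = dXp + (base + (size_t)y1[y] * W + x0[x]) * C;
        double* RSTRCT p11 = dXp + (base + (size_t)y1[y] * W + x1[x]) * C;
        const double a = wy[y], b = wx[x];
        const double w00 = (1 - a) * (1 - b), w01 = (1 - a) * b;
        const double w10 = a * (1 - b), w11 = a * b;
        const double* RSTRCT gp = dYp + so * C;
        for (int c = 0; c < C; ++c) {
          p00[c] += w00 * gp[c];
          p01[c] += w01 * gp[c];
          p10[c] += w10 * gp[c];
          p11[c] += w11 * gp[c];
        }
      }
    }
  }
  return dX;
}

// ---------------------------------------------------------------------------
// activations and batch normalization

// leaky ReLU; backward reads the sign of the stored output (same sign as
// the input for any slope in [0, 1))
// [[Rcpp::export]]
NumericMatrix cpp_lrelu_fwd(const NumericMatrix& X, double slope) {
  NumericMatrix Y = alloc_mat(X.nrow(), X.ncol());
  span_lrelu(Y.begin(), X.begin(), slope, (size_t)X.nrow() * X.ncol());
  return Y;
}

// [[Rcpp::export]]
NumericMatrix cpp_lrelu_bwd(const NumericMatrix& dY, const NumericMatrix& Y,
                            double slope) {
  NumericMatrix dX = alloc_mat(dY.nrow(), dY.ncol());
  span_lrelu_bwd(dX.begin(), dY.begin(), Y.begin(), slope,
                 (size_t)dY.nrow() * dY.ncol());
  return dX;
}

// per-channel (row) mean and biased variance in one pass
// [[Rcpp::export]]
List cpp_row_moments(const NumericMatrix& X) {
  const int C = X.nrow();
  const size_t P = X.ncol();
  const size_t total = (size_t)C * P;
  NumericVector mu(C), m2(C);
  const size_t L = tile_len(C);
  std::vector<double> a1(L, 0.0), a2(L, 0.0);
  const double* RSTRCT xp = X.begin();
  size_t i0 = 0;
  for (; i0 + L <= total; i0 += L)
    span_moments(a1.data(), a2.data(), xp + i0, L);
  if (i0 < total) span_moments(a1.data(), a2.data(), xp + i0, total - i0);
  for (size_t i = 0; i < L; ++i) {
    mu[i % C] += a1[i];
    m2[i % C] += a2[i];
  }
  for (int c = 0; c < C; ++c) {
    mu[c] /= (double)P;
    m2[c] = m2[c] / (double)P - mu[c] * mu[c];
  }
  return List::create(_["mean"] = mu, _["var"] = m2);
}

// xhat = (X - mu) * invstd ; y = xhat * gamma + beta (unfused path, used by
// the global branch whose rectification is a plain ReLU)
// [[Rcpp::export]]
List cpp_bn_apply(const NumericMatrix& X, const NumericVector& mu,
                  const NumericVector& invstd, const NumericVector& gamma,
                  const NumericVector& beta) {
  const int C = X.nrow();
  const size_t P = X.ncol();
  const size_t total = (size_t)C * P;
  NumericMatrix xhat = alloc_mat(C, (int)P), y = alloc_mat(C, (int)P);
  const size_t L = tile_len(C);
  std::vector<double> ivt(L), mut(L), gmt(L), btt(L);
  tile_coef(ivt, invstd.begin(), C, L);
  tile_coef(mut, mu.begin(), C, L);
  tile_coef(gmt, gamma.begin(), C, L);
  tile_coef(btt, beta.begin(), C, L);
  const double* RSTRCT xp = X.begin();
  double* RSTRCT hp = xhat.begin();
  double* RSTRCT yp = y.begin();
  size_t i0 = 0;
  for (; i0 + L <= total; i0 += L)
    span_bn_apply(hp + i0, yp + i0, xp + i0, ivt.data(), mut.data(),
                  gmt.data(), btt.data(), L);
  if (i0 < total)
    span_bn_apply(hp + i0, yp + i0, xp + i0, ivt.data(), mut.data(),
                  gmt.data(), btt.data(), total - i0);
  return List::create(_["xhat"] = xhat, _["y"] = y);
}

// batch-norm backward from a stored xhat:
// dX = invstd * (dY*g - rowmean(dY*g) - xhat * rowmean(dY*g*xhat))
// [[Rcpp::export]]
List cpp_bn_bwd(const NumericMatrix& dY, const NumericMatrix& xhat,
                const NumericVector& invstd, const NumericVector& gamma) {
  const int C = dY.nrow();
  const size_t P = dY.ncol();
  const size_t total = (size_t)C * P;
  NumericVector dgamma(C), dbeta(C);
  const size_t L = tile_len(C);
  std::vector<double> dgt(L, 0.0), dbt(L, 0.0);
  const double* RSTRCT gp = dY.begin();
  const double* RSTRCT hp = xhat.begin();
  size_t i0 = 0;
  for (; i0 + L <= total; i0 += L)
    span_bn_bwd_acc(dgt.data(), dbt.data(), gp + i0, hp + i0, L);
  if (i0 < total)
    span_bn_bwd_acc(dgt.data(), dbt.data(), gp + i0, hp + i0, total - i0);
  for (size_t i = 0; i < L; ++i) {
    dgamma[i % C] += dgt[i];
    dbeta[i % C] += dbt[i];
  }
  std::vector<double> mg(C), mgh(C);
  for (int c = 0; c < C; ++c) {
    mg[c] = gamma[c] * dbeta[c] / (double)P;
    mgh[c] = gamma[c] * dgamma[c] / (double)P;
  }
  std::vector<double> ivt(L), gmt(L), mgt(L), mght(L);
  tile_coef(ivt, invstd.begin(), C, L);
  tile_coef(gmt, gamma.begin(), C, L);
  tile_coef(mgt, mg.data(), C, L);
  tile_coef(mght, mgh.data(), C, L);
  NumericMatrix dX = alloc_mat(C, (int)P);
  double* RSTRCT dp = dX.begin();
  i0 = 0;
  for (; i0 + L <= total; i0 += L)
    span_bn_bwd_dx(dp + i0, gp + i0, hp + i0, ivt.data(), gmt.data(),
                   mgt.data(), mght.data(), L);
  if (i0 < total)
    span_bn_bwd_dx(dp + i0, gp + i0, hp + i0, ivt.data(), gmt.data(),
                   mgt.data(), mght.data(), total - i0);
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// fused batch-norm + leaky ReLU forward (slope must be > 0 so the backward
// pass can reconstruct the pre-activation from the stored output)
// [[Rcpp::export]]
NumericMatrix cpp_bn_lrelu_fwd(const NumericMatrix& X,
                               const NumericVector& mu,
                               const NumericVector& invstd,
                               const NumericVector& gamma,
                               const NumericVector& beta, double slope) {
  const int C = X.nrow();
  const size_t P = X.ncol();
  const size_t total = (size_t)C * P;
  NumericMatrix Y = alloc_mat(C, (int)P);
  const size_t L = tile_len(C);
  std::vector<double> av(L), bv(L);
  for (int c = 0; c < C; ++c) {
    av[c] = invstd[c] * gamma[c];
    bv[c] = beta[c] - mu[c] * av[c];
  }
  for (size_t i = C; i < L; ++i) {
    av[i] = av[i - C];
    bv[i] = bv[i - C];
  }
  const double* RSTRCT xp = X.begin();
  double* RSTRCT yp = Y.begin();
  size_t i0 = 0;
  for (; i0 + L <= total; i0 += L)
    span_bn_lrelu(yp + i0, xp + i0, av.data(), bv.data(), slope, L);
  if (i0 < total)
    span_bn_lrelu(yp + i0, xp + i0, av.data(), bv.data(), slope,
                  total - i0);
  return Y;
}

// fused backward of batch-norm + leaky ReLU; xhat is reconstructed from the
// stored output Y (z = Y or Y/slope, xhat = (z - beta)/gamma)
// [[Rcpp::export]]
List cpp_bn_lrelu_bwd(const NumericMatrix& dY, const NumericMatrix& Y,
                      const NumericVector& invstd,
                      const NumericVector& gamma,
                      const NumericVector& beta, double slope) {
  const int C = dY.nrow();
  const size_t P = dY.ncol();
  const size_t total = (size_t)C * P;
  const double islope = 1.0 / slope;
  const size_t L = tile_len(C);
  std::vector<double> btv(L), igv(L), dgv(L, 0.0), dbv(L, 0.0);
  for (int c = 0; c < C; ++c) {
    double g = gamma[c];
    if (std::fabs(g) < 1e-12) g = g >= 0 ? 1e-12 : -1e-12;
    igv[c] = 1.0 / g;
    btv[c] = beta[c];
  }
  for (size_t i = C; i < L; ++i) {
    igv[i] = igv[i - C];
    btv[i] = btv[i - C];
  }
  const double* RSTRCT gp = dY.begin();
  const double* RSTRCT yp = Y.begin();
  size_t i0 = 0;
  for (; i0 + L <= total; i0 += L)
    span_bn_lrelu_acc(dgv.data(), dbv.data(), gp + i0, yp + i0, btv.data(),
                      igv.data(), islope, slope, L);
  if (i0 < total)
    span_bn_lrelu_acc(dgv.data(), dbv.data(), gp + i0, yp + i0, btv.data(),
                      igv.data(), islope, slope, total - i0);
  NumericVector dgamma(C), dbeta(C);
  for (size_t i = 0; i < L; ++i) {
    dgamma[i % C] += dgv[i];
    dbeta[i % C] += dbv[i];
  }
  std::vector<double> mgv(L), mghv(L), isv(L), gmv(L);
  for (int c = 0; c < C; ++c) {
    mgv[c] = gamma[c] * dbeta[c] / (double)P;
    mghv[c] = gamma[c] * dgamma[c] / (double)P;
    isv[c] = invstd[c];
    gmv[c] = gamma[c];
  }
  for (size_t i = C; i < L; ++i) {
    mgv[i] = mgv[i - C];
    mghv[i] = mghv[i - C];
    isv[i] = isv[i - C];
    gmv[i] = gmv[i - C];
  }
  NumericMatrix dX = alloc_mat(C, (int)P);
  double* RSTRCT dp = dX.begin();
  i0 = 0;
  for (; i0 + L <= total; i0 += L)
    span_bn_lrelu_dx(dp + i0, gp + i0, yp + i0, btv.data(), igv.data(),
                     isv.data(), gmv.data(), mgv.data(), mghv.data(),
                     islope, slope, L);
  if (i0 < total)
    span_bn_lrelu_dx(dp + i0, gp + i0, yp + i0, btv.data(), igv.data(),
                     isv.data(), gmv.data(), mgv.data(), mghv.data(),
                     islope, slope, total - i0);
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// ---------------------------------------------------------------------------
// bilinear sampling of a single H x W image under an affine *inverse* map:
// source = M %*% c(x, y) + v for every output pixel (x, y), 0 outside.
// img is an ordinary R matrix indexed [y+1, x+1].
// [[Rcpp::export]]
NumericMatrix cpp_affine_sample(const NumericMatrix& img, double m11,
                                double m12, double m21, double m22,
                                double v1, double v2) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      const double xs = m11 * x + m12 * y + v1;
      const double ys = m21 * x + m22 * y + v2;
      if (xs < 0 || xs > W - 1 || ys < 0 || ys > H - 1) continue;
      const int x0 = (int)std::floor(xs);
      const int y0 = (int)std::floor(ys);
      const int x1 = x0 + 1 < W ? x0 + 1 : x0;
      const int y1 = y0 + 1 < H ? y0 + 1 : y0;
      const double b = xs - x0, a = ys - y0;
      out(y, x) = (1 - a) * ((1 - b) * img(y0, x0) + b * img(y0, x1)) +
                  a * ((1 - b) * img(y1, x0) + b * img(y1, x1));
    }
  }
  return out;
}

// stack two channel-row maps (rbind without R's dispatch overhead)
// [[Rcpp::export]]
NumericMatrix cpp_vconcat(const NumericMatrix& A, const NumericMatrix& B) {
  const int Ca = A.nrow(), Cb = B.nrow();
  const size_t P = A.ncol();
  NumericMatrix Y = alloc_mat(Ca + Cb, (int)P);
  const double* RSTRCT ap = A.begin();
  const double* RSTRCT bp = B.begin();
  double* RSTRCT yp = Y.begin();
  for (size_t s = 0; s < P; ++s) {
    std::memcpy(yp + s * (Ca + Cb), ap + s * Ca, Ca * sizeof(double));
    std::memcpy(yp + s * (Ca + Cb) + Ca, bp + s * Cb, Cb * sizeof(double));
  }
  return Y;
}

// contiguous row range [from, to] (1-based, inclusive)
// [[Rcpp::export]]
NumericMatrix cpp_rowrange(const NumericMatrix& X, int from, int to) {
  const int C = X.nrow();
  const int Co = to - from + 1;
  const size_t P = X.ncol();
  NumericMatrix Y = alloc_mat(Co, (int)P);
  const double* RSTRCT xp = X.begin();
  double* RSTRCT yp = Y.begin();
  for (size_t s = 0; s < P; ++s)
    std::memcpy(yp + s * Co, xp + s * C + (from - 1), Co * sizeof(double));
  return Y;
}

// soft-label binary cross-entropy, summed over all entries, predictions
// clamped to [eps, 1-eps]
// [[Rcpp::export]]
double cpp_bce_sum(const NumericMatrix& F, const NumericMatrix& Y,
                   double eps) {
  const double* RSTRCT fp = F.begin();
  const double* RSTRCT yp = Y.begin();
  const size_t n = (size_t)F.nrow() * F.ncol();
  double acc = 0;
  for (size_t i = 0; i < n; ++i) {
    const double f = std::min(std::max(fp[i], eps), 1.0 - eps);
    acc += -yp[i] * std::log(f) - (1.0 - yp[i]) * std::log(1.0 - f);
  }
  return acc;
}

// gradient of the batch-mean BCE w.r.t. the prediction (zero where the
// clamp is active)
// [[Rcpp::export]]
NumericMatrix cpp_bce_grad(const NumericMatrix& F, const NumericMatrix& Y,
                           double n_batch, double eps) {
  NumericMatrix G = alloc_mat(F.nrow(), F.ncol());
  const double* RSTRCT fp = F.begin();
  const double* RSTRCT yp = Y.begin();
  double* RSTRCT gp = G.begin();
  const size_t n = (size_t)F.nrow() * F.ncol();
  const double inv = 1.0 / n_batch;
  for (size_t i = 0; i < n; ++i) {
    const double inside =
      std::max(0.0, std::min(1.0, (fp[i] - eps) * 1e300)) *
      std::max(0.0, std::min(1.0, (1.0 - eps - fp[i]) * 1e300));
    const double f = std::min(std::max(fp[i], eps), 1.0 - eps);
    gp[i] = inside * inv * (f - yp[i]) / (f * (1.0 - f));
  }
  return G;
}
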