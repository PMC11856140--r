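#include <Rcpp.h>
using namespace Rcpp;

// Shared low-level kernels.  Feature grids are R arrays with dim (D, H, W, C)
// (spatial axes first, channels last, column-major).  Positions are 0-based
// fractional voxel coordinates ordered (d, h, w).  Out-of-bounds sampling
// clamps to the border (replicate edge).

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Trilinear gather: sample every channel of `vol` at N fractional positions.
// Returns an N x C matrix.
// [[Rcpp::export]]
NumericMatrix cpp_trilinear_gather(NumericVector vol, IntegerVector dims,
                                   NumericMatrix pos) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const int C = dims.size() > 3 ? dims[3] : 1;
  const int N = pos.nrow();
  const R_xlen_t sW = (R_xlen_t)D * H;       // stride of w index
  const R_xlen_t sC = (R_xlen_t)D * H * W;   // stride of channel
  NumericMatrix out(N, C);
  for (int n = 0; n < N; ++n) {
    const double pd = pos(n, 0), ph = pos(n, 1), pw = pos(n, 2);
    const int d0 = (int)std::floor(pd), h0 = (int)std::floor(ph),
              w0 = (int)std::floor(pw);
    const double fd = pd - d0, fh = ph - h0, fw = pw - w0;
    const int dc0 = clampi(d0, 0, D - 1), dc1 = clampi(d0 + 1, 0, D - 1);
    const int hc0 = clampi(h0, 0, H - 1), hc1 = clampi(h0 + 1, 0, H - 1);
    const int wc0 = clampi(w0, 0, W - 1), wc1 = clampi(w0 + 1, 0, W - 1);
    const double wd0 = 1.0 - fd, wh0 = 1.0 - fh, ww0 = 1.0 - fw;
    for (int c = 0; c < C; ++c) {
      const double *v = REAL(vol) + sC * c;
      double acc = 0.0;
      acc += wd0 * wh0 * ww0 * v[dc0 + (R_xlen_t)D * hc0 + sW * wc0];
      acc += fd  * wh0 * ww0 * v[dc1 + (R_xlen_t)D * hc0 + sW * wc0];
      acc += wd0 * fh  * ww0 * v[dc0 + (R_xlen_t)D * hc1 + sW * wc0];
      acc += fd  * fh  * ww0 * v[dc1 + (R_xlen_t)D * hc1 + sW * wc0];
      acc += wd0 * wh0 * fw  * v[dc0 + (R_xlen_t)D * hc0 + sW * wc1];
      acc += fd  * wh0 * fw  * v[dc1 + (R_xlen_t)D * hc0 + sW * wc1];
      acc += wd0 * fh  * fw  * v[dc0 + (R_xlen_t)D * hc1 + sW * wc1];
      acc += fd  * fh  * fw  * v[dc1 + (R_xlen_t)D * hc1 + sW * wc1];
      out(n, c) = acc;
    }
  }
  return out;
}

// Backward of the trilinear gather: given d(loss)/d(out) (N x C), accumulate
// gradients w.r.t. the volume (scatter) and w.r.t. the positions.
// [[Rcpp::export]]
List cpp_trilinear_gather_grad(NumericVector vol, IntegerVector dims,
                               NumericMatrix pos, NumericMatrix gout) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const int C = dims.size() > 3 ? dims[3] : 1;
  const int N = pos.nrow();
  const R_xlen_t sW = (R_xlen_t)D * H, sC = (R_xlen_t)D * H * W;
  NumericVector gvol((R_xlen_t)D * H * W * C);
  NumericMatrix gpos(N, 3);
  for (int n = 0; n < N; ++n) {
    const double pd = pos(n, 0), ph = pos(n, 1), pw = pos(n, 2);
    const int d0 = (int)std::floor(pd), h0 = (int)std::floor(ph),
              w0 = (int)std::floor(pw);
    const double fd = pd - d0, fh = ph - h0, fw = pw - w0;
    const int dc0 = clampi(d0, 0, D - 1), dc1 = clampi(d0 + 1, 0, D - 1);
    const int hc0 = clampi(h0, 0, H - 1), hc1 = clampi(h0 + 1, 0, H - 1);
    const int wc0 = clampi(w0, 0, W - 1), wc1 = clampi(w0 + 1, 0, W - 1);
    const double wd[2] = {1.0 - fd, fd}, wh[2] = {1.0 - fh, fh},
                 ww[2] = {1.0 - fw, fw};
    const int di[2] = {dc0, dc1}, hi[2] = {hc0, hc1}, wi[2] = {wc0, wc1};
    double gd = 0.0, gh = 0.0, gw = 0.0;
    for (int c = 0; c < C; ++c) {
      const double g = gout(n, c);
      if (g == 0.0) continue;
      const double *v = REAL(vol) + sC * c;
      double *gv = REAL(gvol) + sC * c;
      for (int a = 0; a < 2; ++a)
        for (int b = 0; b < 2; ++b)
          for (int e = 0; e < 2; ++e) {
            const R_xlen_t idx = di[a] + (R_xlen_t)D * hi[b] + sW * wi[e];
            gv[idx] += g * wd[a] * wh[b] * ww[e];
            const double val = v[idx];
            gd += g * (a == 0 ? -1.0 : 1.0) * wh[b] * ww[e] * val;
            gh += g * wd[a] * (b == 0 ? -1.0 : 1.0) * ww[e] * val;
            gw += g * wd[a] * wh[b] * (e == 0 ? -1.0 : 1.0) * val;
          }
    }
    gpos(n, 0) = gd; gpos(n, 1) = gh; gpos(n, 2) = gw;
  }
  return List::create(_["grad_vol"] = gvol, _["grad_pos"] = gpos);
}

// Nearest-neighbour gather (used for label maps; never averages labels).
// [[Rcpp::export]]
NumericVector cpp_nearest_gather(NumericVector vol, IntegerVector dims,
                                 NumericMatrix pos) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const int N = pos.nrow();
  const R_xlen_t sW = (R_xlen_t)D * H;
  NumericVector out(N);
  for (int n = 0; n < N; ++n) {
    const int d = clampi((int)std::lround(pos(n, 0)), 0, D - 1);
    const int h = clampi((int)std::lround(pos(n, 1)), 0, H - 1);
    const int w = clampi((int)std::lround(pos(n, 2)), 0, W - 1);
    out[n] = vol[d + (R_xlen_t)D * h + sW * w];
  }
  return out;
}

// im2col for 3D convolution over a (D, H, W, C) grid with cubic kernel k,
// stride s and zero padding p.  Output: Nout x (k^3 * C); column order is
// kd fastest, then kh, kw, then channel (matching the column-major
// flattening of a (k, k, k, Cin, Cout) weight array).
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, IntegerVector dims, int k, int s,
                         int p) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int Do = (D + 2 * p - k) / s + 1;
  const int Ho = (H + 2 * p - k) / s + 1;
  const int Wo = (W + 2 * p - k) / s + 1;
  const R_xlen_t N = (R_xlen_t)Do * Ho * Wo;
  const R_xlen_t sW = (R_xlen_t)D * H, sC = (R_xlen_t)D * H * W;
  NumericMatrix cols(N, (R_xlen_t)k * k * k * C);
  for (int c = 0; c < C; ++c) {
    const double *v = REAL(x) + sC * c;
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh)
        for (int kd = 0; kd < k; ++kd) {
          const R_xlen_t col = kd + (R_xlen_t)k * kh + (R_xlen_t)k * k * kw +
                               (R_xlen_t)k * k * k * c;
          double *dst = &cols(0, col);
          R_xlen_t n = 0;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * s - p + kw;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * s - p + kh;
              for (int doo = 0; doo < Do; ++doo, ++n) {
                const int di = doo * s - p + kd;
                dst[n] = (di >= 0 && di < D && hi >= 0 && hi < H && wi >= 0 &&
                          wi < W)
                             ? v[di + (R_xlen_t)D * hi + sW * wi]
                             : 0.0;
              }
            }
          }
        }
  }
  return cols;
}

// Adjoint of im2col: scatter column gradients back onto the input grid.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, IntegerVector dims, int k, int s,
                         int p) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int Do = (D + 2 * p - k) / s + 1;
  const int Ho = (H + 2 * p - k) / s + 1;
  const int Wo = (W + 2 * p - k) / s + 1;
  const R_xlen_t sW = (R_xlen_t)D * H, sC = (R_xlen_t)D * H * W;
  NumericVector gx((R_xlen_t)D * H * W * C);
  for (int c = 0; c < C; ++c) {
    double *gv = REAL(gx) + sC * c;
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh)
        for (int kd = 0; kd < k; ++kd) {
          const R_xlen_t col = kd + (R_xlen_t)k * kh + (R_xlen_t)k * k * kw +
                               (R_xlen_t)k * k * k * c;
          const double *src = &cols(0, col);
          R_xlen_t n = 0;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * s - p + kw;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * s - p + kh;
              for (int doo = 0; doo < Do; ++doo, ++n) {
                const int di = doo * s - p + kd;
                if (di >= 0 && di < D && hi >= 0 && hi < H && wi >= 0 &&
                    wi < W)
                  gv[di + (R_xlen_t)D * hi + sW * wi] += src[n];
              }
            }
          }
        }
  }
  return gx;
}

// 2x max pooling over a (D, H, W, C) grid (dims must be even).  Returns the
// pooled grid and 1-based argmax indices for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool2(NumericVector x, IntegerVector dims) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int Do = D / 2, Ho = H / 2, Wo = W / 2;
  const R_xlen_t sW = (R_xlen_t)D * H, sC = (R_xlen_t)D * H * W;
  NumericVector out((R_xlen_t)Do * Ho * Wo * C);
  IntegerVector arg((R_xlen_t)Do * Ho * Wo * C);
  R_xlen_t n = 0;
  for (int c = 0; c < C; ++c) {
    const double *v = REAL(x) + sC * c;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int doo = 0; doo < Do; ++doo, ++n) {
          double best = R_NegInf;
          R_xlen_t bi = 0;
          for (int a = 0; a < 2; ++a)
            for (int b = 0; b < 2; ++b)
              for (int e = 0; e < 2; ++e) {
                const R_xlen_t idx = (2 * doo + a) +
                                     (R_xlen_t)D * (2 * ho + b) +
                                     sW * (2 * wo + e);
                if (v[idx] > best) { best = v[idx]; bi = idx; }
              }
          out[n] = best;
          arg[n] = (int)(bi + sC * c) + 1;
        }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// Truncated (border-shrinking) box sum over a (D, H, W) grid: separable 1-D
// moving sums of half-width r along each axis in turn.
// [[Rcpp::export]]
NumericVector cpp_boxsum3(NumericVector x, IntegerVector dims, int r) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const R_xlen_t sW = (R_xlen_t)D * H;
  NumericVector a = clone(x), b((R_xlen_t)D * H * W);
  // pass along d
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      const double *src = REAL(a) + (R_xlen_t)D * h + sW * w;
      double *dst = REAL(b) + (R_xlen_t)D * h + sW * w;
      double run = 0.0;
      for (int d = 0; d < std::min(r, D); ++d) run += src[d];
      for (int d = 0; d < D; ++d) {
        if (d + r < D) run += src[d + r];
        dst[d] = run;
        if (d - r >= 0) run -= src[d - r];
      }
    }
  // pass along h
  for (int w = 0; w < W; ++w)
    for (int d = 0; d < D; ++d) {
      double run = 0.0;
      const double *src = REAL(b) + d + sW * w;
      double *dst = REAL(a) + d + sW * w;
      for (int h = 0; h < std::min(r, H); ++h) run += src[(R_xlen_t)D * h];
      for (int h = 0; h < H; ++h) {
        if (h + r < H) run += src[(R_xlen_t)D * (h + r)];
        dst[(R_xlen_t)D * h] = run;
        if (h - r >= 0) run -= src[(R_xlen_t)D * (h - r)];
      }
    }
  // pass along w
  for (int h = 0; h < H; ++h)
    for (int d = 0; d < D; ++d) {
      double run = 0.0;
      const double *src = REAL(a) + d + (R_xlen_t)D * h;
      double *dst = REAL(b) + d + (R_xlen_t)D * h;
      for (int w = 0; w < std::min(r, W); ++w) run += src[sW * w];
      for (int w = 0; w < W; ++w) {
        if (w + r < W) run += src[sW * (w + r)];
        dst[sW * w] = run;
        if (w - r >= 0) run -= src[sW * (w - r)];
      }
    }
  return b;
}

// Gradient-L2 smoothness of a (D, H, W, 3) displacement field: sum over
// components and axes of the mean squared forward difference, plus its
// gradient (adjoint of the differences).  Returns list(value, grad).
// [[Rcpp::export]]
List cpp_grad_l2(NumericVector u, IntegerVector dims, bool want_grad) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const R_xlen_t sH = D, sW = (R_xlen_t)D * H, sC = (R_xlen_t)D * H * W;
  const R_xlen_t cnt[3] = {(R_xlen_t)(D - 1) * H * W,
                           (R_xlen_t)D * (H - 1) * W,
                           (R_xlen_t)D * H * (W - 1)};
  double total = 0.0;
  NumericVector grad(want_grad ? 3 * sC : 0);
  for (int c = 0; c < 3; ++c) {
    const double *v = REAL(u) + sC * c;
    double *g = want_grad ? REAL(grad) + sC * c : (double *)0;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        for (int d = 0; d < D; ++d) {
          const R_xlen_t i = d + sH * h + sW * w;
          if (d + 1 < D && cnt[0] > 0) {
            const double df = v[i + 1] - v[i];
            total += df * df / cnt[0];
            if (g) { const double t = 2.0 * df / cnt[0];
                     g[i + 1] += t; g[i] -= t; }
          }
          if (h + 1 < H && cnt[1] > 0) {
            const double df = v[i + sH] - v[i];
            total += df * df / cnt[1];
            if (g) { const double t = 2.0 * df / cnt[1];
                     g[i + sH] += t; g[i] -= t; }
          }
          if (w + 1 < W && cnt[2] > 0) {
            const double df = v[i + sW] - v[i];
            total += df * df / cnt[2];
            if (g) { const double t = 2.0 * df / cnt[2];
                     g[i + sW] += t; g[i] -= t; }
          }
        }
  }
  return List::create(_["value"] = total, _["grad"] = grad);
}
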