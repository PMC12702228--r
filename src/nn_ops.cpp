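// Low-level spatial-spectral network primitives.
//
// Activation layout: column-major array [H, W, B, C] (height, width,
// spectral band, channel). Convolution weights: [kh, kw, kb, Cin/groups,
// Cout]. All convolutions are zero-padded "same" with odd kernels and
// per-axis dilation; groups = Cin gives a depthwise convolution.
//
// The forward kernel accumulates one output H-column at a time in a
// stack buffer, so each output value is written to memory once and the
// input columns a kernel touches stay cache-resident. The input
// gradient of the backward pass is expressed as a forward convolution
// with flipped, channel-transposed weights (built on the R side);
// conv3d_gw computes the weight/bias gradients with the same
// column-buffer structure.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline R_xlen_t idx4(int h, int w, int b, int c, int H, int W, int B) {
  return h + (R_xlen_t)H * (w + (R_xlen_t)W * (b + (R_xlen_t)B * c));
}

// [[Rcpp::export]]
NumericVector conv3d_fw(const NumericVector& x, const IntegerVector& xdim,
                        const NumericVector& wt, const IntegerVector& wdim,
                        const NumericVector& bias, const IntegerVector& dil,
                        int groups) {
  const int H = xdim[0], W = xdim[1], B = xdim[2], Cin = xdim[3];
  const int kh = wdim[0], kw = wdim[1], kb = wdim[2];
  const int Cing = wdim[3], Cout = wdim[4];
  const int dh = dil[0], dw = dil[1], db = dil[2];
  if (Cin / groups != Cing) stop("group/channel mismatch in conv3d");
  const int cout_per_g = Cout / groups;

  NumericVector y((R_xlen_t)H * W * B * Cout);
  const double* px = x.begin();
  const double* pw = wt.begin();
  double* py = y.begin();
  std::vector<double> ybuf(H);

  for (int co = 0; co < Cout; ++co) {
    const int g = co / cout_per_g;
    const double bv = bias[co];
    for (int b = 0; b < B; ++b) {
      for (int w2 = 0; w2 < W; ++w2) {
        for (int h = 0; h < H; ++h) ybuf[h] = bv;
        for (int cl = 0; cl < Cing; ++cl) {
          const int ci = g * Cing + cl;
          for (int tk = 0; tk < kb; ++tk) {
            const int bb = b + (tk - kb / 2) * db;
            if (bb < 0 || bb >= B) continue;
            for (int tj = 0; tj < kw; ++tj) {
              const int ww = w2 + (tj - kw / 2) * dw;
              if (ww < 0 || ww >= W) continue;
              const double* xcol = px + idx4(0, ww, bb, ci, H, W, B);
              const double* wcol =
                pw + (R_xlen_t)kh * (tj + (R_xlen_t)kw *
                   (tk + (R_xlen_t)kb * (cl + (R_xlen_t)Cing * co)));
              for (int ti = 0; ti < kh; ++ti) {
                const double wv = wcol[ti];
                if (wv == 0.0) continue;
                const int oh = (ti - kh / 2) * dh;
                const int h0 = std::max(0, -oh), h1 = std::min(H, H - oh);
                const double* xs = xcol + oh;
                for (int h = h0; h < h1; ++h) ybuf[h] += wv * xs[h];
              }
            }
          }
        }
        double* yc = py + idx4(0, w2, b, co, H, W, B);
        for (int h = 0; h < H; ++h) yc[h] = ybuf[h];
      }
    }
  }
  return y;
}

// weight and bias gradients; gx is computed separately on the R side as
// a forward convolution of gy with flipped/transposed weights
// [[Rcpp::export]]
List conv3d_gw(const NumericVector& x, const IntegerVector& xdim,
               const IntegerVector& wdim, const NumericVector& gy,
               const IntegerVector& dil, int groups) {
  const int H = xdim[0], W = xdim[1], B = xdim[2], Cin = xdim[3];
  const int kh = wdim[0], kw = wdim[1], kb = wdim[2];
  const int Cing = wdim[3], Cout = wdim[4];
  const int dh = dil[0], dw = dil[1], db = dil[2];
  const int cout_per_g = Cout / groups;

  NumericVector gw((R_xlen_t)kh * kw * kb * Cing * Cout);
  NumericVector gb(Cout);
  const double* px = x.begin();
  const double* pgy = gy.begin();
  double* pgw = gw.begin();

  for (int co = 0; co < Cout; ++co) {
    const int g = co / cout_per_g;
    double bsum = 0.0;
    for (int b = 0; b < B; ++b) {
      for (int w2 = 0; w2 < W; ++w2) {
        const double* gcol = pgy + idx4(0, w2, b, co, H, W, B);
        for (int h = 0; h < H; ++h) bsum += gcol[h];
        for (int cl = 0; cl < Cing; ++cl) {
          const int ci = g * Cing + cl;
          for (int tk = 0; tk < kb; ++tk) {
            const int bb = b + (tk - kb / 2) * db;
            if (bb < 0 || bb >= B) continue;
            for (int tj = 0; tj < kw; ++tj) {
              const int ww = w2 + (tj - kw / 2) * dw;
              if (ww < 0 || ww >= W) continue;
              const double* xcol = px + idx4(0, ww, bb, ci, H, W, B);
              double* wcol =
                pgw + (R_xlen_t)kh * (tj + (R_xlen_t)kw *
                   (tk + (R_xlen_t)kb * (cl + (R_xlen_t)Cing * co)));
              for (int ti = 0; ti < kh; ++ti) {
                const int oh = (ti - kh / 2) * dh;
                const int h0 = std::max(0, -oh), h1 = std::min(H, H - oh);
                const double* xs = xcol + oh;
                double acc = 0.0;
                for (int h = h0; h < h1; ++h) acc += xs[h] * gcol[h];
                wcol[ti] += acc;
              }
            }
          }
        }
      }
    }
    gb[co] = bsum;
  }
  return List::create(_["gw"] = gw, _["gb"] = gb);
}

// 2x2x2 max pooling; input extents must be even.
// [[Rcpp::export]]
List maxpool2_fw(const NumericVector& x, const IntegerVector& xdim) {
  const int H = xdim[0], W = xdim[1], B = xdim[2], C = xdim[3];
  if (H % 2 || W % 2 || B % 2) stop("maxpool2 requires even extents");
  const int Ho = H / 2, Wo = W / 2, Bo = B / 2;
  NumericVector y((R_xlen_t)Ho * Wo * Bo * C);
  IntegerVector arg(y.size());
  const double* px = x.begin();
  for (int c = 0; c < C; ++c)
    for (int b = 0; b < Bo; ++b)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          double best = R_NegInf; R_xlen_t bi = 0;
          for (int db = 0; db < 2; ++db)
            for (int dw = 0; dw < 2; ++dw)
              for (int dh = 0; dh < 2; ++dh) {
                R_xlen_t i = idx4(2 * h + dh, 2 * w + dw, 2 * b + db, c, H, W, B);
                if (px[i] > best) { best = px[i]; bi = i; }
              }
          R_xlen_t o = idx4(h, w, b, c, Ho, Wo, Bo);
          y[o] = best;
          arg[o] = (int)bi; // extents used here keep linear indices < 2^31
        }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool2_bw(const NumericVector& gy, const IntegerVector& argmax,
                          const IntegerVector& xdim) {
  NumericVector gx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[argmax[i]] += gy[i];
  return gx;
}

// trilinear x2 upsampling, half-pixel centers, edges clamped
static void lin_weights(int n_out, int n_in, std::vector<int>& i0,
                        std::vector<int>& i1, std::vector<double>& f) {
  i0.resize(n_out); i1.resize(n_out); f.resize(n_out);
  for (int o = 0; o < n_out; ++o) {
    double src = (o + 0.5) / 2.0 - 0.5;
    int lo = (int)std::floor(src);
    double fr = src - lo;
    if (lo < 0) { lo = 0; fr = 0.0; }
    int hi = lo + 1;
    if (hi > n_in - 1) { hi = n_in - 1; fr = 0.0; }
    i0[o] = lo; i1[o] = hi; f[o] = fr;
  }
}

// [[Rcpp::export]]
NumericVector upsample2_fw(const NumericVector& x, const IntegerVector& xdim) {
  const int H = xdim[0], W = xdim[1], B = xdim[2], C = xdim[3];
  const int Ho = 2 * H, Wo = 2 * W, Bo = 2 * B;
  std::vector<int> h0, h1, w0, w1, b0, b1;
  std::vector<double> fh, fw, fb;
  lin_weights(Ho, H, h0, h1, fh);
  lin_weights(Wo, W, w0, w1, fw);
  lin_weights(Bo, B, b0, b1, fb);
  NumericVector y((R_xlen_t)Ho * Wo * Bo * C);
  const double* px = x.begin();
  double* py = y.begin();
  for (int c = 0; c < C; ++c)
    for (int b = 0; b < Bo; ++b)
      for (int w = 0; w < Wo; ++w) {
        const double wwl = 1.0 - fw[w], wwh = fw[w];
        const double wbl = 1.0 - fb[b], wbh = fb[b];
        const double* c00 = px + idx4(0, w0[w], b0[b], c, H, W, B);
        const double* c01 = px + idx4(0, w0[w], b1[b], c, H, W, B);
        const double* c10 = px + idx4(0, w1[w], b0[b], c, H, W, B);
        const double* c11 = px + idx4(0, w1[w], b1[b], c, H, W, B);
        double* yc = py + idx4(0, w, b, c, Ho, Wo, Bo);
        for (int h = 0; h < Ho; ++h) {
          const double fl = 1.0 - fh[h], fhh = fh[h];
          const int lo = h0[h], hi = h1[h];
          const double v0 = wbl * (wwl * c00[lo] + wwh * c10[lo]) +
                            wbh * (wwl * c01[lo] + wwh * c11[lo]);
          const double v1 = wbl * (wwl * c00[hi] + wwh * c10[hi]) +
                            wbh * (wwl * c01[hi] + wwh * c11[hi]);
          yc[h] = fl * v0 + fhh * v1;
        }
      }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_bw(const NumericVector& gy, const IntegerVector& xdim) {
  const int H = xdim[0], W = xdim[1], B = xdim[2], C = xdim[3];
  const int Ho = 2 * H, Wo = 2 * W, Bo = 2 * B;
  std::vector<int> h0, h1, w0, w1, b0, b1;
  std::vector<double> fh, fw, fb;
  lin_weights(Ho, H, h0, h1, fh);
  lin_weights(Wo, W, w0, w1, fw);
  lin_weights(Bo, B, b0, b1, fb);
  NumericVector gx((R_xlen_t)H * W * B * C);
  const double* pg = gy.begin();
  double* px = gx.begin();
  for (int c = 0; c < C; ++c)
    for (int b = 0; b < Bo; ++b)
      for (int w = 0; w < Wo; ++w) {
        const double wwl = 1.0 - fw[w], wwh = fw[w];
        const double wbl = 1.0 - fb[b], wbh = fb[b];
        double* c00 = px + idx4(0, w0[w], b0[b], c, H, W, B);
        double* c01 = px + idx4(0, w0[w], b1[b], c, H, W, B);
        double* c10 = px + idx4(0, w1[w], b0[b], c, H, W, B);
        double* c11 = px + idx4(0, w1[w], b1[b], c, H, W, B);
        const double* gc = pg + idx4(0, w, b, c, Ho, Wo, Bo);
        for (int h = 0; h < Ho; ++h) {
          const double g = gc[h];
          if (g == 0.0) continue;
          const double fl = 1.0 - fh[h], fhh = fh[h];
          const int lo = h0[h], hi = h1[h];
          c00[lo] += fl * wbl * wwl * g;  c10[lo] += fl * wbl * wwh * g;
          c01[lo] += fl * wbh * wwl * g;  c11[lo] += fl * wbh * wwh * g;
          c00[hi] += fhh * wbl * wwl * g; c10[hi] += fhh * wbl * wwh * g;
          c01[hi] += fhh * wbh * wwl * g; c11[hi] += fhh * wbh * wwh * g;
        }
      }
  return gx;
}

// ---- fused channel-wise helpers (avoid large R temporaries) ----------

// y = x * s[c] + t[c]
// [[Rcpp::export]]
NumericVector chan_axpb(const NumericVector& x, int C,
                        const NumericVector& s, const NumericVector& t) {
  const R_xlen_t V = x.size() / C;
  NumericVector y(x.size());
  const double* px = x.begin();
  double* py = y.begin();
  for (int c = 0; c < C; ++c) {
    const double sc = s.size() == 1 ? s[0] : s[c];
    const double tc = t.size() == 1 ? t[0] : t[c];
    const double* xc = px + V * c;
    double* yc = py + V * c;
    for (R_xlen_t i = 0; i < V; ++i) yc[i] = xc[i] * sc + tc;
  }
  return y;
}

// z = x * sx[c] + y * sy[c] + t[c]
// [[Rcpp::export]]
NumericVector chan_lincomb(const NumericVector& x, const NumericVector& y,
                           int C, const NumericVector& sx,
                           const NumericVector& sy, const NumericVector& t) {
  const R_xlen_t V = x.size() / C;
  NumericVector z(x.size());
  const double* px = x.begin();
  const double* py = y.begin();
  double* pz = z.begin();
  for (int c = 0; c < C; ++c) {
    const double a = sx[c], b = sy[c], tc = t[c];
    const double* xc = px + V * c;
    const double* yc = py + V * c;
    double* zc = pz + V * c;
    for (R_xlen_t i = 0; i < V; ++i) zc[i] = xc[i] * a + yc[i] * b + tc;
  }
  return z;
}

// per-channel sum and sum of squares in one pass
// [[Rcpp::export]]
List chan_stats(const NumericVector& x, int C) {
  const R_xlen_t V = x.size() / C;
  NumericVector s(C), ss(C);
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = px + V * c;
    double a = 0.0, b = 0.0;
    for (R_xlen_t i = 0; i < V; ++i) { a += xc[i]; b += xc[i] * xc[i]; }
    s[c] = a; ss[c] = b;
  }
  return List::create(_["sum"] = s, _["sumsq"] = ss);
}

// per-channel sum(x * y)
// [[Rcpp::export]]
NumericVector chan_dot(const NumericVector& x, const NumericVector& y, int C) {
  const R_xlen_t V = x.size() / C;
  NumericVector d(C);
  const double* px = x.begin();
  const double* py = y.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = px + V * c;
    const double* yc = py + V * c;
    double a = 0.0;
    for (R_xlen_t i = 0; i < V; ++i) a += xc[i] * yc[i];
    d[c] = a;
  }
  return d;
}

// PReLU: y = max(x, 0) + a[c] * min(x, 0)
// [[Rcpp::export]]
NumericVector prelu_fw_cpp(const NumericVector& x, int C,
                           const NumericVector& a) {
  const R_xlen_t V = x.size() / C;
  NumericVector y(x.size());
  const double* px = x.begin();
  double* py = y.begin();
  for (int c = 0; c < C; ++c) {
    const double ac = a[c];
    const double* xc = px + V * c;
    double* yc = py + V * c;
    for (R_xlen_t i = 0; i < V; ++i)
      yc[i] = xc[i] > 0.0 ? xc[i] : ac * xc[i];
  }
  return y;
}

// [[Rcpp::export]]
List prelu_bw_cpp(const NumericVector& x, int C, const NumericVector& a,
                  const NumericVector& gy) {
  const R_xlen_t V = x.size() / C;
  NumericVector gx(x.size());
  NumericVector ga(C);
  const double* px = x.begin();
  const double* pg = gy.begin();
  double* pgx = gx.begin();
  for (int c = 0; c < C; ++c) {
    const double ac = a[c];
    const double* xc = px + V * c;
    const double* gc = pg + V * c;
    double* gxc = pgx + V * c;
    double acc = 0.0;
    for (R_xlen_t i = 0; i < V; ++i) {
      if (xc[i] > 0.0) gxc[i] = gc[i];
      else { gxc[i] = ac * gc[i]; acc += gc[i] * xc[i]; }
    }
    ga[c] = acc;
  }
  return List::create(_["gx"] = gx, _["ga"] = ga);
}
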