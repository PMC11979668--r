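// 3D convolution primitives for the encoder-decoder network.
//
// Tensors are R arrays in column-major order:
//   activations  (D, H, W, C)
//   conv weights (k, k, k, C_in, C_out)
//   transposed-conv weights (2, 2, 2, C_in, C_out)
// Convolutions are computed directly (no im2col): for each (c_out, c_in,
// kernel offset) the inner loop is a contiguous AXPY along the fastest
// axis, which keeps the working set at one input plus one output channel
// and vectorizes well at the small channel counts this network uses.
// Backward passes return analytic gradients (verified against finite
// differences in the test suite).

#include <Rcpp.h>
#include <algorithm>

using namespace Rcpp;

static inline int out_dim(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

static IntegerVector dims_of(const NumericVector& a, int expected) {
  IntegerVector d = a.attr("dim");
  if (d.size() != expected)
    stop("expected a %d-dimensional array, got %d dimensions",
         expected, (int)d.size());
  return d;
}

// Stride-1 same-padding fast path for the 3x3x3 kernel (the network's
// workhorse). Channels are copied once into zero-padded planes with one
// guard plane at each end of the buffer; each (c_in, c_out, z) pair is then
// a single fused loop over a whole padded plane applying all 27 kernel
// taps, so every loaded cache line feeds many multiply-accumulates and the
// loop is long enough for vector code to win. Padding lanes accumulate
// garbage that the copy-back discards; zero padding in the gradient buffer
// makes the same trick exact for the weight-gradient dot products.
//
// target_clones lets the compiler emit SIMD variants with safe runtime
// dispatch on CPUs without AVX.
#if defined(__GNUC__) && defined(__x86_64__) && !defined(__clang__)
#define HOT_CLONES __attribute__((target_clones("default", "avx2")))
#else
#define HOT_CLONES
#endif

#include <vector>

// (D,H,W,C) -> padded (D+2, H+2, W+2, C) with one extra guard plane before
// and after each channel block (so shifted whole-plane reads stay in
// bounds). Returns the buffer; channel c starts at data() + plane + c*pch.
struct Padded3 {
  std::vector<double> buf;
  int Dp, Hp, Wp;
  size_t plane, pch;  // guard offset and per-channel stride
};

static Padded3 pad3_channels(const double* src, int D, int H, int W, int C) {
  Padded3 p;
  p.Dp = D + 2; p.Hp = H + 2; p.Wp = W + 2;
  p.plane = (size_t)p.Dp * p.Hp;
  p.pch = (size_t)p.Dp * p.Hp * p.Wp;
  p.buf.assign(p.pch * C + 2 * p.plane, 0.0);
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < W; ++z)
      for (int y = 0; y < H; ++y) {
        const double* srow = src + (size_t)D * (y + (size_t)H * z) +
                             (size_t)c * D * H * W;
        double* drow = p.buf.data() + p.plane + (size_t)c * p.pch +
          (size_t)p.Dp * ((y + 1) + (size_t)p.Hp * (z + 1)) + 1;
        std::copy(srow, srow + D, drow);
      }
  return p;
}

// out_pad[z][.] += sum_{kz,ky,kx} w[kx,ky,kz] * in_pad[z+kz-1][. + (ky-1)*Dp + kx-1]
// for every z-plane of the output; both buffers share Padded3 geometry.
HOT_CLONES
static void conv3_fused(const Padded3& xg, const double* xbase, double* obase,
                        const double* w27, int W) {
  const int Dp = xg.Dp;
  const size_t plane = xg.plane;
  const size_t span = plane;
  for (int z = 1; z <= W; ++z) {
    double* __restrict__ o = obase + (size_t)z * plane;
    for (int kz = 0; kz < 3; ++kz) {
      const double* xpl = xbase + (size_t)(z + kz - 1) * plane;
      const double* wk = w27 + 9 * kz;
      const double* __restrict__ r0 = xpl - Dp - 1;
      const double* __restrict__ r1 = xpl - 1;
      const double* __restrict__ r2 = xpl + Dp - 1;
      const double w00 = wk[0], w01 = wk[1], w02 = wk[2];
      const double w10 = wk[3], w11 = wk[4], w12 = wk[5];
      const double w20 = wk[6], w21 = wk[7], w22 = wk[8];
      for (size_t i = 0; i < span; ++i) {
        o[i] += w00 * r0[i] + w01 * r0[i + 1] + w02 * r0[i + 2]
              + w10 * r1[i] + w11 * r1[i + 1] + w12 * r1[i + 2]
              + w20 * r2[i] + w21 * r2[i + 1] + w22 * r2[i + 2];
      }
    }
  }
}

// per-tap dot products of the padded input against the zero-padded output
// gradient (whose padding lanes are zero, so shifted reads contribute
// nothing spurious): gw[kx,ky,kz] += sum gy[v] * x[v + tap offset]
HOT_CLONES
static void conv3_fused_gw(const Padded3& g, const double* gybase,
                           const double* xbase, double* gw27, int W) {
  const int Dp = g.Dp;
  const size_t plane = g.plane;
  for (int z = 1; z <= W; ++z) {
    const double* __restrict__ gyp = gybase + (size_t)z * plane;
    for (int kz = 0; kz < 3; ++kz) {
      const double* xpl = xbase + (size_t)(z + kz - 1) * plane;
      double* gwk = gw27 + 9 * kz;
      for (int ky = 0; ky < 3; ++ky) {
        const double* xrb = xpl + (size_t)(ky - 1) * Dp - 1;
        // one clean dot product per tap, 4-way unrolled partial sums so
        // the FP reduction can vectorize
        for (int kx = 0; kx < 3; ++kx) {
          const double* __restrict__ xr = xrb + kx;
          double a0 = 0, a1 = 0, a2 = 0, a3 = 0;
          size_t i = 0;
          for (; i + 4 <= plane; i += 4) {
            a0 += gyp[i] * xr[i];
            a1 += gyp[i + 1] * xr[i + 1];
            a2 += gyp[i + 2] * xr[i + 2];
            a3 += gyp[i + 3] * xr[i + 3];
          }
          for (; i < plane; ++i) a0 += gyp[i] * xr[i];
          gwk[3 * ky + kx] += a0 + a1 + a2 + a3;
        }
      }
    }
  }
}

static void unpad3_into(const Padded3& p, const double* pbase, double* dst,
                        int D, int H, int W, double add = 0.0) {
  for (int z = 0; z < W; ++z)
    for (int y = 0; y < H; ++y) {
      const double* srow = pbase +
        (size_t)p.Dp * ((y + 1) + (size_t)p.Hp * (z + 1)) + 1;
      double* drow = dst + (size_t)D * (y + (size_t)H * z);
      for (int i = 0; i < D; ++i) drow[i] = srow[i] + add;
    }
}

// [[Rcpp::export(name = ".conv3d_fw")]]
NumericVector conv3d_fw(NumericVector x, NumericVector w, NumericVector b,
                        int stride, int pad) {
  IntegerVector xd = dims_of(x, 4), wd = dims_of(w, 5);
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const int k = wd[0], Cin = wd[3], Cout = wd[4];
  if (wd[1] != k || wd[2] != k) stop("conv3d: kernel must be cubic");
  if (Cin != C) stop("conv3d: input has %d channels, weights expect %d", C, Cin);
  if (b.size() != Cout) stop("conv3d: bias length mismatch");
  const int Do = out_dim(D, k, stride, pad), Ho = out_dim(H, k, stride, pad),
            Wo = out_dim(W, k, stride, pad);
  if (Do <= 0 || Ho <= 0 || Wo <= 0) stop("conv3d: output would be empty");
  NumericVector out((size_t)Do * Ho * Wo * Cout);
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, Cout);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* op = out.begin();
  const size_t xch = (size_t)D * H * W, och = (size_t)Do * Ho * Wo;
  if (stride == 1 && k == 3 && pad == 1) {
    Padded3 xg = pad3_channels(xp, D, H, W, C);
    Padded3 og;
    og.Dp = D + 2; og.Hp = H + 2; og.Wp = W + 2;
    og.plane = (size_t)og.Dp * og.Hp;
    og.pch = og.plane * og.Wp;
    og.buf.assign(og.pch * Cout + 2 * og.plane, 0.0);
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < Cin; ++ci)
        conv3_fused(xg, xg.buf.data() + xg.plane + (size_t)ci * xg.pch,
                    og.buf.data() + og.plane + (size_t)co * og.pch,
                    wp + 27 * (ci + (size_t)Cin * co), W);
    for (int co = 0; co < Cout; ++co)
      unpad3_into(og, og.buf.data() + og.plane + (size_t)co * og.pch,
                  op + (size_t)co * och, D, H, W, b[co]);
    return out;
  }
  for (int co = 0; co < Cout; ++co) {
    double* oc = op + co * och;
    const double bias = b[co];
    for (size_t i = 0; i < och; ++i) oc[i] = bias;
    for (int ci = 0; ci < C; ++ci) {
      const double* xc = xp + (size_t)ci * xch;
      const double* wk = wp + (size_t)k * k * k * (ci + (size_t)Cin * co);
      for (int kz = 0; kz < k; ++kz)
        for (int ky = 0; ky < k; ++ky)
          for (int kx = 0; kx < k; ++kx) {
            const double wv = wk[kx + k * (ky + k * kz)];
            if (wv == 0.0) continue;
            // valid output range along x: 0 <= ox*stride + kx - pad < D
            int ox0 = 0;
            while (ox0 * stride + kx - pad < 0) ++ox0;
            int ox1 = Do - 1;
            while (ox1 * stride + kx - pad >= D) --ox1;
            if (ox1 < ox0) continue;
            for (int oz = 0; oz < Wo; ++oz) {
              const int iz = oz * stride + kz - pad;
              if (iz < 0 || iz >= W) continue;
              for (int oy = 0; oy < Ho; ++oy) {
                const int iy = oy * stride + ky - pad;
                if (iy < 0 || iy >= H) continue;
                double* orow = oc + (size_t)Do * (oy + (size_t)Ho * oz);
                const double* xrow = xc + (size_t)D * (iy + (size_t)H * iz) +
                                     (kx - pad);
                if (stride == 1) {
                  for (int ox = ox0; ox <= ox1; ++ox)
                    orow[ox] += wv * xrow[ox];
                } else {
                  for (int ox = ox0; ox <= ox1; ++ox)
                    orow[ox] += wv * xrow[(size_t)ox * stride];
                }
              }
            }
          }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv3d_bw")]]
List conv3d_bw(NumericVector x, NumericVector w, NumericVector gy,
               int stride, int pad) {
  IntegerVector xd = dims_of(x, 4), wd = dims_of(w, 5), gd = dims_of(gy, 4);
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const int k = wd[0], Cin = wd[3], Cout = wd[4];
  const int Do = gd[0], Ho = gd[1], Wo = gd[2];
  if (gd[3] != Cout) stop("conv3d_bw: gradient channel mismatch");
  if (Cin != C) stop("conv3d_bw: channel mismatch");
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  std::fill(gx.begin(), gx.end(), 0.0);
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  std::fill(gw.begin(), gw.end(), 0.0);
  NumericVector gb(Cout);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* gp = gy.begin();
  double* gxp = gx.begin();
  double* gwp = gw.begin();
  const size_t xch = (size_t)D * H * W, och = (size_t)Do * Ho * Wo;
  for (int co = 0; co < Cout; ++co) {
    const double* gc = gp + co * och;
    double acc_b = 0.0;
    for (size_t i = 0; i < och; ++i) acc_b += gc[i];
    gb[co] = acc_b;
  }
  if (stride == 1 && k == 3 && pad == 1) {
    Padded3 xg = pad3_channels(xp, D, H, W, C);
    Padded3 gg = pad3_channels(gp, D, H, W, Cout);
    // input gradient: correlation of gy with the flipped kernel,
    // channel roles transposed
    std::vector<double> wt((size_t)27 * Cin * Cout);
    for (int ci = 0; ci < Cin; ++ci)
      for (int co = 0; co < Cout; ++co)
        for (int kz = 0; kz < 3; ++kz)
          for (int ky = 0; ky < 3; ++ky)
            for (int kx = 0; kx < 3; ++kx)
              wt[(kx + 3 * (ky + 3 * kz)) + 27 * (co + (size_t)Cout * ci)] =
                wp[((2 - kx) + 3 * ((2 - ky) + 3 * (2 - kz))) +
                   27 * (ci + (size_t)Cin * co)];
    Padded3 gxg;
    gxg.Dp = D + 2; gxg.Hp = H + 2; gxg.Wp = W + 2;
    gxg.plane = (size_t)gxg.Dp * gxg.Hp;
    gxg.pch = gxg.plane * gxg.Wp;
    gxg.buf.assign(gxg.pch * Cin + 2 * gxg.plane, 0.0);
    for (int ci = 0; ci < Cin; ++ci)
      for (int co = 0; co < Cout; ++co)
        conv3_fused(gg, gg.buf.data() + gg.plane + (size_t)co * gg.pch,
                    gxg.buf.data() + gxg.plane + (size_t)ci * gxg.pch,
                    wt.data() + 27 * (co + (size_t)Cout * ci), W);
    for (int ci = 0; ci < Cin; ++ci)
      unpad3_into(gxg, gxg.buf.data() + gxg.plane + (size_t)ci * gxg.pch,
                  gxp + (size_t)ci * xch, D, H, W, 0.0);
    for (int ci = 0; ci < Cin; ++ci)
      for (int co = 0; co < Cout; ++co)
        conv3_fused_gw(gg, gg.buf.data() + gg.plane + (size_t)co * gg.pch,
                       xg.buf.data() + xg.plane + (size_t)ci * xg.pch,
                       gwp + 27 * (ci + (size_t)Cin * co), W);
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }
  for (int co = 0; co < Cout; ++co) {
    const double* gc = gp + co * och;
    for (int ci = 0; ci < C; ++ci) {
      const double* xc = xp + (size_t)ci * xch;
      double* gxc = gxp + (size_t)ci * xch;
      const double* wk = wp + (size_t)k * k * k * (ci + (size_t)Cin * co);
      double* gwk = gwp + (size_t)k * k * k * (ci + (size_t)Cin * co);
      for (int kz = 0; kz < k; ++kz)
        for (int ky = 0; ky < k; ++ky)
          for (int kx = 0; kx < k; ++kx) {
            const double wv = wk[kx + k * (ky + k * kz)];
            double acc_w = 0.0;
            int ox0 = 0;
            while (ox0 * stride + kx - pad < 0) ++ox0;
            int ox1 = Do - 1;
            while (ox1 * stride + kx - pad >= D) --ox1;
            if (ox1 < ox0) continue;
            for (int oz = 0; oz < Wo; ++oz) {
              const int iz = oz * stride + kz - pad;
              if (iz < 0 || iz >= W) continue;
              for (int oy = 0; oy < Ho; ++oy) {
                const int iy = oy * stride + ky - pad;
                if (iy < 0 || iy >= H) continue;
                const double* grow = gc + (size_t)Do * (oy + (size_t)Ho * oz);
                const size_t xoff = (size_t)D * (iy + (size_t)H * iz) +
                                    (kx - pad);
                const double* xrow = xc + xoff;
                double* gxrow = gxc + xoff;
                if (stride == 1) {
                  // 4-way partial sums break the FP dependency chain of the
                  // weight-gradient reduction so the loop can vectorize
                  double a0 = 0, a1 = 0, a2 = 0, a3 = 0;
                  int ox = ox0;
                  for (; ox + 3 <= ox1; ox += 4) {
                    const double g0 = grow[ox], g1 = grow[ox + 1],
                                 g2 = grow[ox + 2], g3 = grow[ox + 3];
                    gxrow[ox] += wv * g0;
                    gxrow[ox + 1] += wv * g1;
                    gxrow[ox + 2] += wv * g2;
                    gxrow[ox + 3] += wv * g3;
                    a0 += xrow[ox] * g0;
                    a1 += xrow[ox + 1] * g1;
                    a2 += xrow[ox + 2] * g2;
                    a3 += xrow[ox + 3] * g3;
                  }
                  for (; ox <= ox1; ++ox) {
                    const double g = grow[ox];
                    gxrow[ox] += wv * g;
                    a0 += xrow[ox] * g;
                  }
                  acc_w += a0 + a1 + a2 + a3;
                } else {
                  for (int ox = ox0; ox <= ox1; ++ox) {
                    const double g = grow[ox];
                    gxrow[(size_t)ox * stride] += wv * g;
                    acc_w += xrow[(size_t)ox * stride] * g;
                  }
                }
              }
            }
            gwk[kx + k * (ky + k * kz)] = acc_w;
          }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Transposed convolution, kernel 2, stride 2 (shape-doubling upsampler).
// y(2i+kx, 2j+ky, 2l+kz, co) = sum_ci x(i,j,l,ci) * w(kx,ky,kz,ci,co)
// [[Rcpp::export(name = ".convt3d_fw")]]
NumericVector convt3d_fw(NumericVector x, NumericVector w) {
  IntegerVector xd = dims_of(x, 4), wd = dims_of(w, 5);
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3];
  if (wd[0] != 2 || wd[1] != 2 || wd[2] != 2)
    stop("convt3d: kernel must be 2x2x2");
  if (wd[3] != C) stop("convt3d: channel mismatch");
  const int Cout = wd[4];
  const int Do = 2 * D, Ho = 2 * H, Wo = 2 * W;
  NumericVector out((size_t)Do * Ho * Wo * Cout);
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, Cout);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* op = out.begin();
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < C; ++ci) {
      const double* xc = xp + (size_t)ci * D * H * W;
      double* oc = op + (size_t)co * Do * Ho * Wo;
      for (int kz = 0; kz < 2; ++kz)
        for (int ky = 0; ky < 2; ++ky)
          for (int kx = 0; kx < 2; ++kx) {
            const double wv =
              wp[kx + 2 * (ky + 2 * (kz + 2 * (ci + (size_t)C * co)))];
            for (int iz = 0; iz < W; ++iz)
              for (int iy = 0; iy < H; ++iy) {
                const double* xrow = xc + (size_t)D * (iy + (size_t)H * iz);
                double* orow = oc + (size_t)(2 * iz + kz) * Do * Ho +
                               (size_t)(2 * iy + ky) * Do + kx;
                for (int ix = 0; ix < D; ++ix)
                  orow[2 * ix] += wv * xrow[ix];
              }
          }
    }
  return out;
}

// [[Rcpp::export(name = ".convt3d_bw")]]
List convt3d_bw(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = dims_of(x, 4), wd = dims_of(w, 5), gd = dims_of(gy, 4);
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const int Cout = wd[4];
  const int Do = gd[0], Ho = gd[1];
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  std::fill(gx.begin(), gx.end(), 0.0);
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  std::fill(gw.begin(), gw.end(), 0.0);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* gp = gy.begin();
  double* gxp = gx.begin();
  double* gwp = gw.begin();
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < C; ++ci) {
      const double* xc = xp + (size_t)ci * D * H * W;
      double* gxc = gxp + (size_t)ci * D * H * W;
      const double* gc = gp + (size_t)co * Do * Ho * (size_t)(2 * W);
      for (int kz = 0; kz < 2; ++kz)
        for (int ky = 0; ky < 2; ++ky)
          for (int kx = 0; kx < 2; ++kx) {
            const size_t widx =
              kx + 2 * (ky + 2 * (kz + 2 * (ci + (size_t)C * co)));
            const double wv = wp[widx];
            double gwacc = 0.0;
            for (int iz = 0; iz < W; ++iz)
              for (int iy = 0; iy < H; ++iy) {
                const double* xrow = xc + (size_t)D * (iy + (size_t)H * iz);
                double* gxrow = gxc + (size_t)D * (iy + (size_t)H * iz);
                const double* grow = gc + (size_t)(2 * iz + kz) * Do * Ho +
                                     (size_t)(2 * iy + ky) * Do + kx;
                for (int ix = 0; ix < D; ++ix) {
                  const double g = grow[2 * ix];
                  gxrow[ix] += wv * g;
                  gwacc += xrow[ix] * g;
                }
              }
            gwp[widx] += gwacc;
          }
    }
  return List::create(_["gx"] = gx, _["gw"] = gw);
}
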