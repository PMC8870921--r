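#include <Rcpp.h>
using namespace Rcpp;

// Activations are (H*W*N) x C matrices, rows ordered h fastest, then w, then
// batch index n. Direct 3x3 same-padded (zero boundary) convolution and its
// adjoints; channel counts in this network are small, so direct loops with a
// contiguous inner h-loop beat im2col+GEMM on memory traffic.
//
// Weight layout matches the R-side (3,3,Cin,Cout) array flattening:
//   W[(dh+1) + 3*(dw+1) + 9*cin + 9*Cin*cout],  dh, dw in {-1,0,1}.
// Forward: out(h,w,cout) = sum_{dh,dw,cin} W * x(h+dh, w+dw, cin).

// Multiple ISA-specific clones are emitted for the hot kernels; the loader
// picks the widest vector variant the CPU supports, so the same binary runs
// on any x86-64 while using AVX2+FMA where available.
#if defined(__x86_64__) && defined(__gnu_linux__)
#define LQ_CLONES __attribute__((target_clones("arch=haswell", "default")))
#else
#define LQ_CLONES
#endif

static LQ_CLONES void conv3_fwd_impl(const double *x, const double *wt,
                                     const double *bias, int H, int W, int N,
                                     int Cin, int Cout, double *o) {
  const R_xlen_t R = (R_xlen_t)H * W * N;
  for (int co = 0; co < Cout; ++co) {
    const double bc = bias[co];
    double *ocol = o + R * co;
    for (R_xlen_t i = 0; i < R; ++i) ocol[i] = bc;
  }
  for (int n = 0; n < N; ++n) {
    const R_xlen_t nb = (R_xlen_t)H * W * n;
    for (int w = 0; w < W; ++w) {
      const R_xlen_t ob = nb + (R_xlen_t)H * w;
      for (int dw = -1; dw <= 1; ++dw) {
        const int sw = w + dw;
        if (sw < 0 || sw >= W) continue;
        const R_xlen_t sb = nb + (R_xlen_t)H * sw;
        for (int ci = 0; ci < Cin; ++ci) {
          const double *src = x + sb + R * ci;
          for (int dh = -1; dh <= 1; ++dh) {
            const int hlo = dh < 0 ? 1 : 0;
            const int hhi = dh > 0 ? H - 1 : H;
            const double *s = src + dh;
            const double *wrow = wt + (dh + 1) + 3 * (dw + 1) + 9 * ci;
            for (int co = 0; co < Cout; ++co) {
              const double g = wrow[9 * Cin * co];
              double *__restrict dst = o + ob + R * co;
              const double *__restrict sr = s;
              for (int h = hlo; h < hhi; ++h) dst[h] += g * sr[h];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_conv3_fwd(NumericMatrix X, NumericVector Wt,
                            NumericVector bias, int H, int W, int N,
                            int Cout) {
  NumericMatrix out((R_xlen_t)H * W * N, Cout);
  conv3_fwd_impl(X.begin(), Wt.begin(), bias.begin(), H, W, N, X.ncol(),
                 Cout, out.begin());
  return out;
}

// Gradient w.r.t. the input: correlation of dOut with the flipped kernel.
// dX(h,w,ci) = sum_{dh,dw,co} W[dh,dw,ci,co] * dOut(h-dh, w-dw, co)
static LQ_CLONES void conv3_dx_impl(const double *do_, const double *wt,
                                    int H, int W, int N, int Cin, int Cout,
                                    double *dx) {
  const R_xlen_t R = (R_xlen_t)H * W * N;
  for (int n = 0; n < N; ++n) {
    const R_xlen_t nb = (R_xlen_t)H * W * n;
    for (int w = 0; w < W; ++w) {
      const R_xlen_t ob = nb + (R_xlen_t)H * w;
      for (int dw = -1; dw <= 1; ++dw) {
        const int sw = w - dw;
        if (sw < 0 || sw >= W) continue;
        const R_xlen_t sb = nb + (R_xlen_t)H * sw;
        for (int co = 0; co < Cout; ++co) {
          const double *src = do_ + sb + R * co;
          for (int dh = -1; dh <= 1; ++dh) {
            const int hlo = dh > 0 ? 1 : 0;       // need h-dh in [0,H)
            const int hhi = dh < 0 ? H - 1 : H;
            const double *s = src - dh;
            const double *wrow = wt + (dh + 1) + 3 * (dw + 1) + 9 * Cin * co;
            for (int ci = 0; ci < Cin; ++ci) {
              const double g = wrow[9 * ci];
              double *__restrict dst = dx + ob + R * ci;
              const double *__restrict sr = s;
              for (int h = hlo; h < hhi; ++h) dst[h] += g * sr[h];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_conv3_dx(NumericMatrix dOut, NumericVector Wt,
                           int H, int W, int N, int Cin) {
  NumericMatrix dX((R_xlen_t)H * W * N, Cin);
  conv3_dx_impl(dOut.begin(), Wt.begin(), H, W, N, Cin, dOut.ncol(),
                dX.begin());
  return dX;
}

// Gradient w.r.t. the weights.
// dW[dh,dw,ci,co] = sum_{h,w,n valid} x(h+dh, w+dw, ci) * dOut(h,w,co)
static LQ_CLONES void conv3_dw_impl(const double *x, const double *do_,
                                    int H, int W, int N, int Cin, int Cout,
                                    double *dw_) {
  const R_xlen_t R = (R_xlen_t)H * W * N;
  for (int n = 0; n < N; ++n) {
    const R_xlen_t nb = (R_xlen_t)H * W * n;
    for (int w = 0; w < W; ++w) {
      const R_xlen_t ob = nb + (R_xlen_t)H * w;
      for (int dw = -1; dw <= 1; ++dw) {
        const int sw = w + dw;
        if (sw < 0 || sw >= W) continue;
        const R_xlen_t sb = nb + (R_xlen_t)H * sw;
        for (int ci = 0; ci < Cin; ++ci) {
          const double *src = x + sb + R * ci;
          for (int dh = -1; dh <= 1; ++dh) {
            const int hlo = dh < 0 ? 1 : 0;
            const int hhi = dh > 0 ? H - 1 : H;
            const double *s = src + dh;
            double *wrow = dw_ + (dh + 1) + 3 * (dw + 1) + 9 * ci;
            for (int co = 0; co < Cout; ++co) {
              const double *__restrict g = do_ + ob + R * co;
              const double *__restrict sr = s;
              double acc = 0.0;
              for (int h = hlo; h < hhi; ++h) acc += g[h] * sr[h];
              wrow[9 * Cin * co] += acc;
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3_dw(NumericMatrix X, NumericMatrix dOut,
                           int H, int W, int N) {
  NumericVector dW(9 * X.ncol() * dOut.ncol());
  conv3_dw_impl(X.begin(), dOut.begin(), H, W, N, X.ncol(), dOut.ncol(),
                dW.begin());
  return dW;
}

// out[i,j] = X[i,j] * scale[j] + shift[j]  (column-wise affine, avoids
// materializing recycled vectors on the R side)
// [[Rcpp::export]]
NumericMatrix cpp_colaffine(NumericMatrix X, NumericVector scale,
                            NumericVector shift) {
  const int R = X.nrow(), C = X.ncol();
  NumericMatrix out(R, C);
  for (int c = 0; c < C; ++c) {
    const double sc = scale[c], sh = shift[c];
    const double *x = &X(0, c);
    double *o = &out(0, c);
    for (int i = 0; i < R; ++i) o[i] = x[i] * sc + sh;
  }
  return out;
}
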