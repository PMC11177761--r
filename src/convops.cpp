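#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// Feature maps are stored as column-major R arrays with dim (H, W, N, C):
// linear index h + H*(w + W*(n + N*c)). im2col lays patches out as an
// (Ho*Wo*N) x (kh*kw*C) matrix, row index ho + Ho*(wo + Wo*n), column
// index i + kh*(j + kw*c), so that a convolution is a single GEMM against
// a (kh*kw*C) x Cout weight matrix. Out-of-frame taps read as zero
// (zero padding).

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int N, int C,
                         int kh, int kw, int sh, int sw, int ph, int pw) {
  const int Ho = (H + 2 * ph - kh) / sh + 1;
  const int Wo = (W + 2 * pw - kw) / sw + 1;
  const R_xlen_t R = (R_xlen_t)Ho * Wo * N;
  const int K = kh * kw * C;
  NumericMatrix M(R, K);
  const double* xp = x.begin();
  double* mp = M.begin();
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int k = i + kh * (j + kw * c);
        double* col = mp + (R_xlen_t)k * R;
        for (int n = 0; n < N; ++n) {
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * sw - pw + j;
            const R_xlen_t rbase = (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n);
            if (wi < 0 || wi >= W) {
              for (int ho = 0; ho < Ho; ++ho) col[rbase + ho] = 0.0;
              continue;
            }
            const R_xlen_t xbase =
              (R_xlen_t)H * (wi + (R_xlen_t)W * (n + (R_xlen_t)N * c));
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * sh - ph + i;
              col[rbase + ho] = (hi >= 0 && hi < H) ? xp[xbase + hi] : 0.0;
            }
          }
        }
      }
    }
  }
  return M;
}

// Adjoint of im2col: scatter-add patch gradients back onto the input grid.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix M, int H, int W, int N, int C,
                         int kh, int kw, int sh, int sw, int ph, int pw) {
  const int Ho = (H + 2 * ph - kh) / sh + 1;
  const int Wo = (W + 2 * pw - kw) / sw + 1;
  const R_xlen_t R = (R_xlen_t)Ho * Wo * N;
  NumericVector x((R_xlen_t)H * W * N * C);
  double* xp = x.begin();
  const double* mp = M.begin();
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int k = i + kh * (j + kw * c);
        const double* col = mp + (R_xlen_t)k * R;
        for (int n = 0; n < N; ++n) {
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * sw - pw + j;
            if (wi < 0 || wi >= W) continue;
            const R_xlen_t rbase = (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n);
            const R_xlen_t xbase =
              (R_xlen_t)H * (wi + (R_xlen_t)W * (n + (R_xlen_t)N * c));
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * sh - ph + i;
              if (hi >= 0 && hi < H) xp[xbase + hi] += col[rbase + ho];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, N, C);
  return x;
}

// Pooling over (H, W) windows; out dim (Ho, Wo, N, C). For max pooling the
// 1-based linear argmax into x is returned so the backward pass can
// scatter; padded taps never win (-DBL_MAX) and avg pooling divides by the
// full kernel area (zero padding contributes zeros).
// [[Rcpp::export]]
List pool_fwd_cpp(NumericVector x, int H, int W, int N, int C,
                  int kh, int kw, int sh, int sw, int ph, int pw,
                  bool maxpool) {
  const int Ho = (H + 2 * ph - kh) / sh + 1;
  const int Wo = (W + 2 * pw - kw) / sw + 1;
  const R_xlen_t OUT = (R_xlen_t)Ho * Wo * N * C;
  NumericVector out(OUT);
  IntegerVector arg(maxpool ? OUT : 0);
  const double* xp = x.begin();
  const double inv_area = 1.0 / (kh * kw);
  R_xlen_t o = 0;
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      const R_xlen_t planebase = (R_xlen_t)H * W * (n + (R_xlen_t)N * c);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -DBL_MAX, acc = 0.0;
          R_xlen_t besti = -1;
          for (int j = 0; j < kw; ++j) {
            const int wi = wo * sw - pw + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < kh; ++i) {
              const int hi = ho * sh - ph + i;
              if (hi < 0 || hi >= H) continue;
              const R_xlen_t xi = planebase + hi + (R_xlen_t)H * wi;
              const double v = xp[xi];
              if (maxpool) {
                if (v > best) { best = v; besti = xi; }
              } else {
                acc += v;
              }
            }
          }
          // out index ho + Ho*(wo + Wo*(n + N*c)) — but we iterate c outer,
          // n, wo, ho inner, which is NOT the column-major order of
          // (Ho,Wo,N,C); compute explicitly.
          const R_xlen_t oi =
            ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * (n + (R_xlen_t)N * c));
          if (maxpool) {
            out[oi] = best;
            arg[oi] = (int)(besti + 1);  // 1-based for R
          } else {
            out[oi] = acc * inv_area;
          }
          ++o;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, N, C);
  if (maxpool) return List::create(_["out"] = out, _["argmax"] = arg);
  return List::create(_["out"] = out);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector gout, IntegerVector argmax,
                              int H, int W, int N, int C) {
  NumericVector gx((R_xlen_t)H * W * N * C);
  double* gp = gx.begin();
  const double* go = gout.begin();
  for (R_xlen_t o = 0; o < gout.size(); ++o) {
    const int a = argmax[o];
    if (a > 0) gp[a - 1] += go[o];
  }
  gx.attr("dim") = IntegerVector::create(H, W, N, C);
  return gx;
}

// [[Rcpp::export]]
NumericVector avgpool_bwd_cpp(NumericVector gout, int H, int W, int N, int C,
                              int kh, int kw, int sh, int sw, int ph, int pw) {
  const int Ho = (H + 2 * ph - kh) / sh + 1;
  const int Wo = (W + 2 * pw - kw) / sw + 1;
  NumericVector gx((R_xlen_t)H * W * N * C);
  double* gp = gx.begin();
  const double* go = gout.begin();
  const double inv_area = 1.0 / (kh * kw);
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      const R_xlen_t planebase = (R_xlen_t)H * W * (n + (R_xlen_t)N * c);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const R_xlen_t oi =
            ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * (n + (R_xlen_t)N * c));
          const double g = go[oi] * inv_area;
          for (int j = 0; j < kw; ++j) {
            const int wi = wo * sw - pw + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < kh; ++i) {
              const int hi = ho * sh - ph + i;
              if (hi < 0 || hi >= H) continue;
              gp[planebase + hi + (R_xlen_t)H * wi] += g;
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(H, W, N, C);
  return gx;
}

// [[Rcpp::export]]
NumericVector relu_fwd_cpp(NumericVector x) {
  NumericVector out(x.size());
  const double* xp = x.begin();
  double* op = out.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) op[i] = xp[i] > 0 ? xp[i] : 0.0;
  out.attr("dim") = x.attr("dim");
  return out;
}

// [[Rcpp::export]]
NumericVector relu_bwd_cpp(NumericVector g, NumericVector x) {
  NumericVector out(g.size());
  const double* gp = g.begin();
  const double* xp = x.begin();
  double* op = out.begin();
  for (R_xlen_t i = 0; i < g.size(); ++i) op[i] = xp[i] > 0 ? gp[i] : 0.0;
  out.attr("dim") = g.attr("dim");
  return out;
}

// Y (R x K, column-major) + b[k] broadcast down each column, in one pass.
// [[Rcpp::export]]
NumericMatrix add_bias_cols_cpp(NumericMatrix Y, NumericVector b) {
  NumericMatrix out(Y.nrow(), Y.ncol());
  const double* yp = Y.begin();
  double* op = out.begin();
  const R_xlen_t R = Y.nrow();
  for (int k = 0; k < Y.ncol(); ++k) {
    const double bk = b[k];
    const double* yc = yp + (R_xlen_t)k * R;
    double* oc = op + (R_xlen_t)k * R;
    for (R_xlen_t i = 0; i < R; ++i) oc[i] = yc[i] + bk;
  }
  return out;
}

// Y (R x K) with column k scaled by s[k].
// [[Rcpp::export]]
NumericMatrix scale_cols_cpp(NumericMatrix Y, NumericVector s) {
  NumericMatrix out(Y.nrow(), Y.ncol());
  const double* yp = Y.begin();
  double* op = out.begin();
  const R_xlen_t R = Y.nrow();
  for (int k = 0; k < Y.ncol(); ++k) {
    const double sk = s[k];
    const double* yc = yp + (R_xlen_t)k * R;
    double* oc = op + (R_xlen_t)k * R;
    for (R_xlen_t i = 0; i < R; ++i) oc[i] = yc[i] * sk;
  }
  return out;
}
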