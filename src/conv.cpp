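// Direct 3x3 same-padding convolution kernels on stacked-slice activation
// matrices: rows are pixels in (batch, row, col) order with col fastest,
// columns are channels. Weight layout: (9*cin) x cout with the offset index
// k running over (dy, dx), dx fastest, rows (k*cin .. k*cin+cin-1).
//
// Channel counts are small (2..64), so im2col/GEMM shapes would be too
// skinny for BLAS to be efficient; instead the kernels loop directly over
// offsets and channels with contiguous inner loops along the slice width,
// which the compiler vectorizes. Arithmetic runs in single precision
// (activations cross the R boundary as doubles); weight-gradient
// accumulation uses double accumulators.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int koff(int dy, int dx) { return (dy + 1) * 3 + (dx + 1); }

// the three dx-tap correlation sums of one row pair (see stencil_row for
// why noinline matters)
__attribute__((noinline))
static void dw_row(const float* __restrict x, const float* __restrict dyp,
                   const int W, float* __restrict taps) {
  float sm = 0.0f, s0 = 0.0f, sp = 0.0f;
  for (int c = 1; c < W - 1; ++c) {
    const float d = dyp[c];
    sm += x[c - 1] * d; s0 += x[c] * d; sp += x[c + 1] * d;
  }
  s0 += x[0] * dyp[0] + x[W - 1] * dyp[W - 1];
  sp += x[1] * dyp[0];
  sm += x[W - 2] * dyp[W - 1];
  taps[0] = sm; taps[1] = s0; taps[2] = sp;
}

// one horizontal 3-tap stencil pass: y += w_m*x[c-1] + w_0*x[c] + w_p*x[c+1].
// noinline keeps the __restrict qualifiers effective (inlining into the loop
// nest defeats them and blocks vectorization).
__attribute__((noinline))
static void stencil_row(float* __restrict y, const float* __restrict x,
                        const float wm, const float w0, const float wp,
                        const int W) {
  y[0] += w0 * x[0] + wp * x[1];
  for (int c = 1; c < W - 1; ++c)
    y[c] += wm * x[c - 1] + w0 * x[c] + wp * x[c + 1];
  y[W - 1] += wm * x[W - 2] + w0 * x[W - 1];
}

// [[Rcpp::export(name = ".conv3x3_fwd_cpp")]]
arma::mat conv3x3_fwd_cpp(const arma::mat& X, const arma::mat& Wt,
                          int B, int H, int W) {
  const int cin = X.n_cols, cout = Wt.n_cols;
  const int HW = H * W;
  arma::fmat Xf = arma::conv_to<arma::fmat>::from(X);
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(Wt);
  arma::fmat Yf(X.n_rows, cout, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int r = 0; r < H; ++r) {
      for (int co = 0; co < cout; ++co) {
        float* y = Yf.colptr(co) + b * HW + r * W;
        for (int dy = -1; dy <= 1; ++dy) {
          const int r2 = r + dy;
          if (r2 < 0 || r2 >= H) continue;
          for (int ci = 0; ci < cin; ++ci) {
            const float* x = Xf.colptr(ci) + b * HW + r2 * W;
            stencil_row(y, x,
                        Wf(koff(dy, -1) * cin + ci, co),
                        Wf(koff(dy, 0) * cin + ci, co),
                        Wf(koff(dy, 1) * cin + ci, co), W);
          }
        }
      }
    }
  }
  return arma::conv_to<arma::mat>::from(Yf);
}

// [[Rcpp::export(name = ".conv3x3_bwd_cpp")]]
List conv3x3_bwd_cpp(const arma::mat& X, const arma::mat& Wt,
                     const arma::mat& dY, int B, int H, int W) {
  const int cin = X.n_cols, cout = Wt.n_cols;
  const int HW = H * W;
  arma::fmat Xf = arma::conv_to<arma::fmat>::from(X);
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(Wt);
  arma::fmat dYf = arma::conv_to<arma::fmat>::from(dY);
  arma::fmat dXf(X.n_rows, cin, arma::fill::zeros);
  arma::mat dW(9 * cin, cout, arma::fill::zeros);

  // dX(b, r, c, ci) = sum_{dy,dx,co} dY(b, r-dy, c-dx, co) * W(k(dy,dx),ci,co)
  // = a 3x3 correlation of dY with the flipped kernel: same stencil form.
  for (int b = 0; b < B; ++b) {
    for (int r = 0; r < H; ++r) {
      for (int ci = 0; ci < cin; ++ci) {
        float* dx_row = dXf.colptr(ci) + b * HW + r * W;
        for (int dy = -1; dy <= 1; ++dy) {
          const int rs = r - dy;
          if (rs < 0 || rs >= H) continue;
          for (int co = 0; co < cout; ++co) {
            const float* dyp = dYf.colptr(co) + b * HW + rs * W;
            stencil_row(dx_row, dyp,
                        Wf(koff(dy, 1) * cin + ci, co),
                        Wf(koff(dy, 0) * cin + ci, co),
                        Wf(koff(dy, -1) * cin + ci, co), W);
          }
        }
      }
    }
  }

  // dW(k,ci,co) = sum_{b,r,c} X(b, r+dy, c+dx, ci) * dY(b, r, c, co):
  // one pass per (dy, ci, co, b, r) accumulating the three dx taps.
  for (int dy = -1; dy <= 1; ++dy) {
    for (int ci = 0; ci < cin; ++ci) {
      for (int co = 0; co < cout; ++co) {
        double am = 0.0, a0 = 0.0, ap = 0.0;
        for (int b = 0; b < B; ++b) {
          for (int r = 0; r < H; ++r) {
            const int r2 = r + dy;
            if (r2 < 0 || r2 >= H) continue;
            float taps[3];
            dw_row(Xf.colptr(ci) + b * HW + r2 * W,
                   dYf.colptr(co) + b * HW + r * W, W, taps);
            am += taps[0]; a0 += taps[1]; ap += taps[2];
          }
        }
        dW(koff(dy, -1) * cin + ci, co) = am;
        dW(koff(dy, 0) * cin + ci, co) = a0;
        dW(koff(dy, 1) * cin + ci, co) = ap;
      }
    }
  }
  return List::create(Named("dX") = arma::conv_to<arma::mat>::from(dXf),
                      Named("dW") = dW);
}

// Batch-norm forward: returns normalized output plus the per-channel batch
// statistics needed for the backward pass.
// [[Rcpp::export(name = ".bn_fwd_cpp")]]
List bn_fwd_cpp(const arma::mat& X, const arma::vec& gamma,
                const arma::vec& beta, double eps) {
  const int N = X.n_rows, C = X.n_cols;
  arma::rowvec mu = arma::mean(X, 0);
  arma::mat xhat(N, C);
  arma::rowvec var(C);
  for (int j = 0; j < C; ++j) {
    const double* x = X.colptr(j);
    double m = mu(j), acc = 0.0;
    for (int i = 0; i < N; ++i) { const double d = x[i] - m; acc += d * d; }
    var(j) = acc / N;
    const double inv = 1.0 / std::sqrt(var(j) + eps);
    double* xh = xhat.colptr(j);
    for (int i = 0; i < N; ++i) xh[i] = (x[i] - m) * inv;
  }
  arma::mat Y(N, C);
  for (int j = 0; j < C; ++j) {
    const double g = gamma(j), b = beta(j);
    const double* xh = xhat.colptr(j);
    double* y = Y.colptr(j);
    for (int i = 0; i < N; ++i) y[i] = g * xh[i] + b;
  }
  return List::create(Named("y") = Y, Named("xhat") = xhat,
                      Named("mu") = mu, Named("var") = var);
}

// [[Rcpp::export(name = ".bn_bwd_cpp")]]
List bn_bwd_cpp(const arma::mat& dY, const arma::mat& xhat,
                const arma::vec& gamma, const arma::vec& var, double eps) {
  const int N = dY.n_rows, C = dY.n_cols;
  arma::vec gbeta(C), ggamma(C);
  arma::mat dX(N, C);
  for (int j = 0; j < C; ++j) {
    const double* dy = dY.colptr(j);
    const double* xh = xhat.colptr(j);
    double sb = 0.0, sg = 0.0;
    for (int i = 0; i < N; ++i) { sb += dy[i]; sg += dy[i] * xh[i]; }
    gbeta(j) = sb; ggamma(j) = sg;
    const double g = gamma(j);
    const double inv = 1.0 / std::sqrt(var(j) + eps);
    const double t1 = g * sb / N, t2 = g * sg / N;
    double* dx = dX.colptr(j);
    for (int i = 0; i < N; ++i)
      dx[i] = (g * dy[i] - t1 - xh[i] * t2) * inv;
  }
  return List::create(Named("dX") = dX, Named("ggamma") = ggamma,
                      Named("gbeta") = gbeta);
}

// Bilinear resampling of a matrix at fractional coordinates (zero outside);
// used by the patch augmenter.
// [[Rcpp::export(name = ".bilinear_cpp")]]
arma::mat bilinear_cpp(const arma::mat& img, const arma::mat& rs,
                       const arma::mat& cs) {
  const int H = img.n_rows, W = img.n_cols;
  arma::mat out(rs.n_rows, rs.n_cols, arma::fill::zeros);
  for (arma::uword i = 0; i < rs.n_elem; ++i) {
    const double r = rs(i), c = cs(i);
    const int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
    const double fr = r - r0, fc = c - c0;
    double acc = 0.0;
    for (int dr = 0; dr <= 1; ++dr) {
      for (int dc = 0; dc <= 1; ++dc) {
        const int rr = r0 + dr, cc = c0 + dc;
        if (rr < 1 || rr > H || cc < 1 || cc > W) continue;
        const double w = (dr ? fr : 1 - fr) * (dc ? fc : 1 - fc);
        acc += w * img(rr - 1, cc - 1);
      }
    }
    out(i) = acc;
  }
  return out;
}
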