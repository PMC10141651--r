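// Low-level kernels for the autodiff engine: im2col/col2im convolution,
// 2x2 stride-2 transposed convolution, 2x2 max pooling and batch
// normalisation.
//
// All image tensors cross the R boundary as dense column-major double
// arrays with dims (H, W, C, N): element (h, w, c, n) sits at
// h + H*(w + W*(c + C*n)), 0-based. Kernel internals run in single
// precision (sgemm + halved memory traffic); conversions are fused into
// the gather/scatter loops. Convolution weights are matrices of dims
// Co x (kh*kw*Ci) with column q = ki + kh*(kj + kw*ci); transposed-conv
// (kernel 2, stride 2) weights are (4*Co) x Ci with row i + 2*(j + 2*co).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int conv_out_size(int H, int k, int pad, int stride, int dil) {
  return (H + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

static NumericVector make_arr4(int H, int W, int C, int N) {
  NumericVector out((R_xlen_t)H * W * C * N);
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  return out;
}

static arma::fmat fmat_of(const arma::mat& m) {
  return arma::conv_to<arma::fmat>::from(m);
}

// rows = output positions p = ho + Ho*(wo + Wo*n) (contiguous writes),
// cols = patch entries q = ki + kh*(kj + kw*c).
static arma::fmat* im2col_core(const double* x, int H, int W, int C, int N,
                               int kh, int kw, int pad, int stride, int dil) {
  const int Ho = conv_out_size(H, kh, pad, stride, dil);
  const int Wo = conv_out_size(W, kw, pad, stride, dil);
  arma::fmat* Ap = new arma::fmat((arma::uword)Ho * Wo * N, kh * kw * C,
                                  arma::fill::none);
  arma::fmat& A = *Ap;
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        const int q = ki + kh * (kj + kw * c);
        float* col = A.colptr(q);
        for (int n = 0; n < N; ++n)
          for (int wo = 0; wo < Wo; ++wo) {
            const int w = wo * stride - pad + kj * dil;
            const size_t poff = (size_t)Ho * (wo + (size_t)Wo * n);
            if (w < 0 || w >= W) {
              std::fill(col + poff, col + poff + Ho, 0.0f);
              continue;
            }
            const size_t xoff = (size_t)H * (w + (size_t)W * (c + (size_t)C * n));
            for (int ho = 0; ho < Ho; ++ho) {
              const int h = ho * stride - pad + ki * dil;
              col[ho + poff] = (h < 0 || h >= H) ? 0.0f : (float)x[h + xoff];
            }
          }
      }
  return Ap;
}

// Accumulate patch-matrix gradients back into the input image (double).
static void col2im_core(const arma::fmat& A, double* x, int H, int W, int C,
                        int N, int kh, int kw, int pad, int stride, int dil) {
  const int Ho = conv_out_size(H, kh, pad, stride, dil);
  const int Wo = conv_out_size(W, kw, pad, stride, dil);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        const int q = ki + kh * (kj + kw * c);
        const float* col = A.colptr(q);
        for (int n = 0; n < N; ++n)
          for (int wo = 0; wo < Wo; ++wo) {
            const int w = wo * stride - pad + kj * dil;
            if (w < 0 || w >= W) continue;
            const size_t xoff = (size_t)H * (w + (size_t)W * (c + (size_t)C * n));
            const size_t poff = (size_t)Ho * (wo + (size_t)Wo * n);
            for (int ho = 0; ho < Ho; ++ho) {
              const int h = ho * stride - pad + ki * dil;
              if (h < 0 || h >= H) continue;
              x[h + xoff] += col[ho + poff];
            }
          }
      }
}

// Forward convolution.  x: (H,W,Ci,N); Wm: Co x (kh*kw*Ci); b: length Co
// or 0.  Returns list(out, cols) where cols is an external pointer to the
// patch matrix, reused by the backward pass without copying.
// [[Rcpp::export]]
List conv2d_fwd_cpp(NumericVector x, const arma::mat& Wm, NumericVector b,
                    int kh, int kw, int pad, int stride, int dil,
                    bool keep_cols) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if ((int)Wm.n_cols != kh * kw * C)
    stop("conv2d: weight expects %d input channels, got %d",
         (int)Wm.n_cols / (kh * kw), C);
  const int Co = Wm.n_rows;
  const int Ho = conv_out_size(H, kh, pad, stride, dil);
  const int Wo = conv_out_size(W, kw, pad, stride, dil);
  arma::fmat* A = im2col_core(x.begin(), H, W, C, N, kh, kw, pad, stride, dil);
  arma::fmat O = (*A) * fmat_of(Wm).t();  // (Ho*Wo*N) x Co
  NumericVector out = make_arr4(Ho, Wo, Co, N);
  double* po = out.begin();
  const bool has_b = b.size() > 0;
  const size_t hw = (size_t)Ho * Wo;
  for (int co = 0; co < Co; ++co) {
    const float* oc = O.colptr(co);
    const double bb = has_b ? b[co] : 0.0;
    for (int n = 0; n < N; ++n) {
      const float* src = oc + hw * n;
      double* dst = po + hw * (co + (size_t)Co * n);
      for (size_t i = 0; i < hw; ++i) dst[i] = (double)src[i] + bb;
    }
  }
  if (keep_cols) {
    XPtr<arma::fmat> pa(A, true);  // freed when the tape node is collected
    return List::create(_["out"] = out, _["cols"] = pa);
  }
  delete A;
  return List::create(_["out"] = out);
}

// Backward convolution. dout: (Ho,Wo,Co,N); cols: pointer from the forward
// pass. Returns list(dx, dW, db).
// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector dout, SEXP cols_ptr, const arma::mat& Wm,
                    IntegerVector xdim, int kh, int kw, int pad, int stride,
                    int dil, bool has_bias) {
  arma::fmat* cols = (arma::fmat*)R_ExternalPtrAddr(cols_ptr);
  if (!cols) stop("conv2d backward: patch matrix already released");
  IntegerVector d = dout.attr("dim");
  const int Ho = d[0], Wo = d[1], Co = d[2], N = d[3];
  arma::fmat dO((arma::uword)Ho * Wo * N, Co, arma::fill::none);
  const double* pd = dout.begin();
  const size_t hw = (size_t)Ho * Wo;
  for (int co = 0; co < Co; ++co) {
    float* oc = dO.colptr(co);
    for (int n = 0; n < N; ++n) {
      const double* src = pd + hw * (co + (size_t)Co * n);
      float* dst = oc + hw * n;
      for (size_t i = 0; i < hw; ++i) dst[i] = (float)src[i];
    }
  }
  arma::fmat dWf = dO.t() * (*cols);    // Co x (kh*kw*Ci)
  arma::fmat dA = dO * fmat_of(Wm);     // (Ho*Wo*N) x (kh*kw*Ci)
  const int H = xdim[0], W = xdim[1], C = xdim[2];
  NumericVector dx = make_arr4(H, W, C, N);
  col2im_core(dA, dx.begin(), H, W, C, N, kh, kw, pad, stride, dil);
  NumericVector db(has_bias ? Co : 0);
  if (has_bias) {
    arma::frowvec s = arma::sum(dO, 0);
    for (int co = 0; co < Co; ++co) db[co] = s[co];
  }
  // free the patch matrix now (backward runs once per node); the XPtr
  // finalizer then sees a cleared pointer and does nothing
  delete cols;
  R_ClearExternalPtr(cols_ptr);
  return List::create(_["dx"] = dx,
                      _["dW"] = wrap(arma::conv_to<arma::mat>::from(dWf)),
                      _["db"] = db);
}

// Gather x (H,W,C,N) into a float matrix C x (H*W*N).
static arma::fmat gather_cm(const double* px, int H, int W, int C, int N) {
  arma::fmat X(C, (arma::uword)H * W * N, arma::fill::none);
  const size_t hw = (size_t)H * W;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* src = px + hw * (c + (size_t)C * n);
      const size_t m0 = hw * n;
      for (size_t i = 0; i < hw; ++i) X(c, i + m0) = (float)src[i];
    }
  return X;
}

// Transposed convolution, kernel 2, stride 2 (exact upsampling by 2).
// x: (H,W,Ci,N); Wt: (4*Co) x Ci; b: length Co or 0. out: (2H,2W,Co,N).
// [[Rcpp::export]]
NumericVector tconv2_fwd_cpp(NumericVector x, const arma::mat& Wt,
                             NumericVector b) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if ((int)Wt.n_cols != C) stop("tconv2: channel mismatch");
  const int Co = Wt.n_rows / 4;
  arma::fmat X = gather_cm(x.begin(), H, W, C, N);
  arma::fmat O = fmat_of(Wt) * X;  // (4*Co) x (H*W*N)
  NumericVector out = make_arr4(2 * H, 2 * W, Co, N);
  double* po = out.begin();
  const bool has_b = b.size() > 0;
  const int Ho = 2 * H, Wo = 2 * W;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      const size_t o0 = (size_t)Ho * Wo * (co + (size_t)Co * n);
      const size_t m0 = (size_t)H * W * n;
      const double bb = has_b ? b[co] : 0.0;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const size_t m = h + (size_t)H * w + m0;
          for (int j = 0; j < 2; ++j)
            for (int i = 0; i < 2; ++i)
              po[(2 * h + i) + (size_t)Ho * (2 * w + j) + o0] =
                  (double)O(i + 2 * (j + 2 * co), m) + bb;
        }
    }
  return out;
}

// Backward of tconv2. Returns list(dx, dW, db).
// [[Rcpp::export]]
List tconv2_bwd_cpp(NumericVector dout, NumericVector x, const arma::mat& Wt,
                    bool has_bias) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Co = Wt.n_rows / 4;
  const int Ho = 2 * H, Wo = 2 * W;
  arma::fmat dO(4 * Co, (arma::uword)H * W * N, arma::fill::none);
  const double* pd = dout.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      const size_t o0 = (size_t)Ho * Wo * (co + (size_t)Co * n);
      const size_t m0 = (size_t)H * W * n;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const size_t m = h + (size_t)H * w + m0;
          for (int j = 0; j < 2; ++j)
            for (int i = 0; i < 2; ++i)
              dO(i + 2 * (j + 2 * co), m) =
                  (float)pd[(2 * h + i) + (size_t)Ho * (2 * w + j) + o0];
        }
    }
  arma::fmat X = gather_cm(x.begin(), H, W, C, N);
  arma::fmat dWf = dO * X.t();
  arma::fmat dX = fmat_of(Wt).t() * dO;  // C x (H*W*N)
  NumericVector dx = make_arr4(H, W, C, N);
  double* pdx = dx.begin();
  const size_t hw = (size_t)H * W;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* dst = pdx + hw * (c + (size_t)C * n);
      const size_t m0 = hw * n;
      for (size_t i = 0; i < hw; ++i) dst[i] = (double)dX(c, i + m0);
    }
  NumericVector db(has_bias ? Co : 0);
  if (has_bias)
    for (int co = 0; co < Co; ++co) {
      double s = 0;
      for (int r = 0; r < 4; ++r) s += arma::accu(dO.row(r + 4 * co));
      db[co] = s;
    }
  return List::create(_["dx"] = dx,
                      _["dW"] = wrap(arma::conv_to<arma::mat>::from(dWf)),
                      _["db"] = db);
}

// 2x2 stride-2 max pooling; requires even H and W. Returns list(out, arg)
// where arg stores the winning offset i + 2*j per window.
// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("maxpool2: spatial size must be even, got %dx%d", H, W);
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out = make_arr4(Ho, Wo, C, N);
  IntegerVector arg((R_xlen_t)Ho * Wo * C * N);
  arg.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* px = x.begin();
  double* po = out.begin();
  int* pa = arg.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t x0 = (size_t)H * W * (c + (size_t)C * n);
      const size_t o0 = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -INFINITY;
          int besta = 0;
          for (int j = 0; j < 2; ++j)
            for (int i = 0; i < 2; ++i) {
              const double v = px[(2 * ho + i) + (size_t)H * (2 * wo + j) + x0];
              if (v > best) { best = v; besta = i + 2 * j; }
            }
          po[ho + (size_t)Ho * wo + o0] = best;
          pa[ho + (size_t)Ho * wo + o0] = besta;
        }
    }
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(NumericVector dout, IntegerVector arg,
                               int H, int W) {
  IntegerVector d = dout.attr("dim");
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector dx = make_arr4(H, W, C, N);
  const double* pd = dout.begin();
  const int* pa = arg.begin();
  double* px = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t x0 = (size_t)H * W * (c + (size_t)C * n);
      const size_t o0 = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const int a = pa[ho + (size_t)Ho * wo + o0];
          px[(2 * ho + a % 2) + (size_t)H * (2 * wo + a / 2) + x0] +=
              pd[ho + (size_t)Ho * wo + o0];
        }
    }
  return dx;
}

// Per-channel batch statistics: biased mean and variance over (H, W, N).
// [[Rcpp::export]]
List bn_stats_cpp(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t hw = (size_t)H * W;
  NumericVector mu(C), va(C);
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* src = px + hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) { s += src[i]; s2 += src[i] * src[i]; }
    }
    const double m = s / (hw * N);
    mu[c] = m;
    va[c] = std::max(s2 / (hw * N) - m * m, 0.0);
  }
  return List::create(_["mean"] = mu, _["var"] = va);
}

// Batch-norm forward: out = xhat * gamma + beta with
// xhat = (x - mean) / sqrt(var + eps). Returns out and xhat (kept for the
// backward pass as an external pointer).
// [[Rcpp::export]]
List bn_fwd_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
                NumericVector mean, NumericVector var_, double eps,
                bool keep_xhat) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t hw = (size_t)H * W;
  NumericVector out = make_arr4(H, W, C, N);
  arma::fmat* xhat =
      keep_xhat ? new arma::fmat(hw * N, C, arma::fill::none) : nullptr;
  const double* px = x.begin();
  double* po = out.begin();
  for (int c = 0; c < C; ++c) {
    const double m = mean[c], s = std::sqrt(var_[c] + eps);
    const double g = gamma[c], b = beta[c];
    float* xh = keep_xhat ? xhat->colptr(c) : nullptr;
    for (int n = 0; n < N; ++n) {
      const double* src = px + hw * (c + (size_t)C * n);
      double* dst = po + hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) {
        const double z = (src[i] - m) / s;
        if (keep_xhat) xh[i + hw * n] = (float)z;
        dst[i] = z * g + b;
      }
    }
  }
  if (!keep_xhat) return List::create(_["out"] = out);
  return List::create(_["out"] = out,
                      _["xhat"] = XPtr<arma::fmat>(xhat, true));
}

// Batch-norm backward. In training mode
//   dx = gamma/sd * (g - mean_c(g) - xhat * mean_c(g*xhat));
// in inference mode dx = gamma/sd * g. Returns list(dx, dgamma, dbeta).
// [[Rcpp::export]]
List bn_bwd_cpp(NumericVector g, SEXP xhat_ptr, NumericVector gamma,
                NumericVector sd_, bool train) {
  arma::fmat* xhat = (arma::fmat*)R_ExternalPtrAddr(xhat_ptr);
  if (!xhat) stop("batch-norm backward: saved activations already released");
  IntegerVector d = g.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t hw = (size_t)H * W;
  const double m = (double)hw * N;
  NumericVector dx = make_arr4(H, W, C, N);
  NumericVector dgamma(C), dbeta(C);
  const double* pg = g.begin();
  double* pdx = dx.begin();
  for (int c = 0; c < C; ++c) {
    const float* xh = xhat->colptr(c);
    double sg = 0, sgx = 0;
    for (int n = 0; n < N; ++n) {
      const double* src = pg + hw * (c + (size_t)C * n);
      const float* xhd = xh + hw * n;
      for (size_t i = 0; i < hw; ++i) { sg += src[i]; sgx += src[i] * xhd[i]; }
    }
    dgamma[c] = sgx;
    dbeta[c] = sg;
    const double gs = gamma[c] / sd_[c];
    for (int n = 0; n < N; ++n) {
      const double* src = pg + hw * (c + (size_t)C * n);
      const float* xhd = xh + hw * n;
      double* dst = pdx + hw * (c + (size_t)C * n);
      if (train) {
        for (size_t i = 0; i < hw; ++i)
          dst[i] = gs * (src[i] - sg / m - xhd[i] * (sgx / m));
      } else {
        for (size_t i = 0; i < hw; ++i) dst[i] = gs * src[i];
      }
    }
  }
  delete xhat;
  R_ClearExternalPtr(xhat_ptr);
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Fused ReLU forward; backward masks by the stored output sign.
// [[Rcpp::export]]
NumericVector relu_fwd_cpp(NumericVector x) {
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  const double* px = x.begin();
  double* po = out.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) po[i] = px[i] > 0 ? px[i] : 0.0;
  return out;
}

// [[Rcpp::export]]
NumericVector relu_bwd_cpp(NumericVector g, NumericVector out) {
  NumericVector dx(g.size());
  dx.attr("dim") = g.attr("dim");
  const double* pg = g.begin();
  const double* po = out.begin();
  double* pd = dx.begin();
  for (R_xlen_t i = 0; i < g.size(); ++i) pd[i] = po[i] > 0 ? pg[i] : 0.0;
  return dx;
}

// Inverted dropout using R's RNG (seed-reproducible): returns the masked
// activations and the mask/keep scaling, reused in backward.
// [[Rcpp::export]]
List dropout_fwd_cpp(NumericVector x, double rate) {
  const double keep = 1.0 - rate;
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  IntegerVector mask(x.size());
  const double* px = x.begin();
  double* po = out.begin();
  int* pm = mask.begin();
  GetRNGstate();
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const int m = unif_rand() < keep;
    pm[i] = m;
    po[i] = m ? px[i] / keep : 0.0;
  }
  PutRNGstate();
  return List::create(_["out"] = out, _["mask"] = mask);
}

// [[Rcpp::export]]
NumericVector dropout_bwd_cpp(NumericVector g, IntegerVector mask,
                              double rate) {
  const double keep = 1.0 - rate;
  NumericVector dx(g.size());
  dx.attr("dim") = g.attr("dim");
  const double* pg = g.begin();
  const int* pm = mask.begin();
  double* pd = dx.begin();
  for (R_xlen_t i = 0; i < g.size(); ++i) pd[i] = pm[i] ? pg[i] / keep : 0.0;
  return dx;
}

// Hybrid fusion: channel-wise concatenation of elementwise sum, product
// and maximum over n same-shaped maps. Sum and product are folded in
// elementwise-sorted value order, so the output is bit-identical under any
// permutation of the input maps; the product is clamped to +/- clip.
// [[Rcpp::export]]
NumericVector fuse_fwd_cpp(List maps, double clip) {
  const int nm = maps.size();
  NumericVector m0 = maps[0];
  IntegerVector d = m0.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t hw = (size_t)H * W;
  NumericVector out((R_xlen_t)H * W * 3 * C * N);
  out.attr("dim") = IntegerVector::create(H, W, 3 * C, N);
  std::vector<const double*> px(nm);
  for (int j = 0; j < nm; ++j) {
    NumericVector mj = maps[j];
    px[j] = mj.begin();
  }
  double* po = out.begin();
  std::vector<double> v(nm);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t xoff = hw * (c + (size_t)C * n);
      const size_t so = hw * (c + (size_t)(3 * C) * n);
      const size_t poff = hw * (C + c + (size_t)(3 * C) * n);
      const size_t mo = hw * (2 * C + c + (size_t)(3 * C) * n);
      for (size_t i = 0; i < hw; ++i) {
        for (int j = 0; j < nm; ++j) v[j] = px[j][i + xoff];
        std::sort(v.begin(), v.end());
        double s = 0, p = 1;
        for (int j = 0; j < nm; ++j) { s += v[j]; p *= v[j]; }
        if (p > clip) p = clip; else if (p < -clip) p = -clip;
        po[i + so] = s;
        po[i + poff] = p;
        po[i + mo] = v[nm - 1];
      }
    }
  return out;
}

// Backward of fuse_fwd_cpp: per element, the sum part passes the gradient
// to every map; the product part passes g * (leave-one-out product) while
// inside the clip range; the max part routes to the first map (in input
// order) attaining the maximum.
// [[Rcpp::export]]
List fuse_bwd_cpp(NumericVector g, List maps, double clip) {
  const int nm = maps.size();
  NumericVector m0 = maps[0];
  IntegerVector d = m0.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t hw = (size_t)H * W;
  std::vector<const double*> px(nm);
  List grads(nm);
  std::vector<double*> pg(nm);
  for (int j = 0; j < nm; ++j) {
    NumericVector mj = maps[j];
    px[j] = mj.begin();
    NumericVector gj((R_xlen_t)H * W * C * N);
    gj.attr("dim") = IntegerVector::create(H, W, C, N);
    grads[j] = gj;
    pg[j] = gj.begin();
  }
  const double* pgin = g.begin();
  std::vector<double> v(nm), sv(nm), pre(nm + 1), suf(nm + 1);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t xoff = hw * (c + (size_t)C * n);
      const size_t so = hw * (c + (size_t)(3 * C) * n);
      const size_t poff = hw * (C + c + (size_t)(3 * C) * n);
      const size_t mo = hw * (2 * C + c + (size_t)(3 * C) * n);
      for (size_t i = 0; i < hw; ++i) {
        const double gs = pgin[i + so], gp = pgin[i + poff],
                     gm = pgin[i + mo];
        for (int j = 0; j < nm; ++j) v[j] = px[j][i + xoff];
        sv = v;
        std::sort(sv.begin(), sv.end());
        double ptot = 1;
        for (int j = 0; j < nm; ++j) ptot *= sv[j];
        const bool inclip = std::abs(ptot) <= clip;
        // argmax with ties to the first input
        int jmax = 0;
        for (int j = 1; j < nm; ++j) if (v[j] > v[jmax]) jmax = j;
        if (inclip && gp != 0) {
          pre[0] = 1;
          for (int j = 0; j < nm; ++j) pre[j + 1] = pre[j] * sv[j];
          suf[nm] = 1;
          for (int j = nm - 1; j >= 0; --j) suf[j] = suf[j + 1] * sv[j];
          // leave-one-out by matching each original value to one sorted slot
          std::vector<bool> used(nm, false);
          for (int j = 0; j < nm; ++j) {
            int k = std::lower_bound(sv.begin(), sv.end(), v[j]) - sv.begin();
            while (used[k]) ++k;
            used[k] = true;
            pg[j][i + xoff] += gs + gp * pre[k] * suf[k + 1] +
                               (j == jmax ? gm : 0.0);
          }
        } else {
          for (int j = 0; j < nm; ++j)
            pg[j][i + xoff] += gs + (j == jmax ? gm : 0.0);
        }
      }
    }
  return grads;
}
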