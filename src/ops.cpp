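// Low-level tensor kernels for the U-net engine and mask post-processing.
//
// Tensor layout follows R's column-major array convention throughout:
// activations are (H, W, C, N) arrays, convolution kernels (k, k, C_in, C_out),
// transpose-convolution kernels (k, k, C_out, C_in).  Convolutions are
// evaluated per sample as im2col + GEMM so that BLAS carries the load;
// the 3x3 stride-2 transpose convolutions use a scatter/gather col2im with
// the "pad right/bottom" convention that exactly doubles the spatial size.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& d1, int& d2,
                             int& d3, int& d4) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d (H, W, C, N) array");
  d1 = d[0]; d2 = d[1]; d3 = d[2]; d4 = d[3];
}

// Single-precision GEMM (column-major, BLAS interface).  The convolution
// kernels run in float, as deep-learning frameworks do: it halves the
// memory traffic of the patch matrices, which dominates the cost.
extern "C" void sgemm_(const char* transa, const char* transb,
                       const int* m, const int* n, const int* k,
                       const float* alpha, const float* a, const int* lda,
                       const float* b, const int* ldb, const float* beta,
                       float* c, const int* ldc);

// Vertical-only im2col: Mv has H*(W + 2p) rows (the image columns plus p
// zero-padded columns on each side) and k*C columns indexed di + k*c, so
// that for each horizontal offset dj the operand of the GEMM is the
// row-window of Mv starting at H*dj.  This keeps the scratch matrix k times
// smaller than a full im2col and avoids materializing the k^2 blow-up.
template <typename T>
static void im2col_vertical(const T* xs, int H, int W, int C, int k,
                            float* Mv, size_t ld) {
  const int p = (k - 1) / 2;
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    const T* plane = xs + HW * c;
    for (int di = 0; di < k; ++di) {
      float* col = Mv + ld * ((size_t)di + (size_t)k * c) + (size_t)H * p;
      const int lo = std::max(0, p - di);
      const int hi = std::min(H, H + p - di);
      for (int j = 0; j < W; ++j) {
        float* dst = col + (size_t)H * j;
        const T* src = plane + (size_t)H * j;
        for (int i = 0;  i < lo; ++i) dst[i] = 0.0f;
        for (int i = lo; i < hi; ++i) dst[i] = (float)src[i + di - p];
        for (int i = hi; i < H;  ++i) dst[i] = 0.0f;
      }
    }
  }
}

// Repack a (k, k, Ci, Co) kernel into per-dj float blocks Wd[dj], each of
// shape (k*Ci, Co) with row index di + k*ci.  `flip` additionally flips
// the kernel spatially and swaps the channel roles (the backward-data
// convolution).
static std::vector<std::vector<float> >
pack_weights(const double* w, int k, int Ci, int Co, bool flip) {
  std::vector<std::vector<float> > Wd(k);
  const int Ri = flip ? Co : Ci;  // input channels of the packed conv
  const int Ro = flip ? Ci : Co;
  for (int dj = 0; dj < k; ++dj) {
    Wd[dj].assign((size_t)k * Ri * Ro, 0.0f);
    for (int co = 0; co < Ro; ++co)
      for (int ci = 0; ci < Ri; ++ci)
        for (int di = 0; di < k; ++di) {
          double v;
          if (!flip)
            v = w[di + (size_t)k * dj + (size_t)k * k * ci +
                  (size_t)k * k * Ci * co];
          else
            v = w[(k - 1 - di) + (size_t)k * (k - 1 - dj) +
                  (size_t)k * k * co + (size_t)k * k * Ci * ci];
          Wd[dj][(size_t)di + (size_t)k * ci +
                 (size_t)k * Ri * co] = (float)v;
        }
  }
  return Wd;
}

// Core 'same' convolution of one sample:
// Y (HW x Co, float) = sum_dj window_dj(Mv) * Wd[dj] (+ bias).
static void conv_core(const float* Mv, size_t ld, int H, int W, int Ci,
                      int Co, int k,
                      const std::vector<std::vector<float> >& Wd,
                      const double* bias, float* Y) {
  const int HW = H * W;
  const int kc = k * Ci;
  if (bias) {
    for (int co = 0; co < Co; ++co) {
      const float bc = (float)bias[co];
      float* yc = Y + (size_t)HW * co;
      for (int q = 0; q < HW; ++q) yc[q] = bc;
    }
  } else {
    std::fill(Y, Y + (size_t)HW * Co, 0.0f);
  }
  const float one = 1.0f;
  const int ldi = (int)ld;
  for (int dj = 0; dj < k; ++dj) {
    const float* A = Mv + (size_t)H * dj;
    sgemm_("N", "N", &HW, &Co, &kc, &one, A, &ldi, Wd[dj].data(), &kc,
           &one, Y, &HW);
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int H, W, Ci, N; get_dims4(x, H, W, Ci, N);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4 || wd[0] != wd[1] || wd[2] != Ci)
    stop("kernel must be (k, k, C_in, C_out) with C_in matching the input");
  const int k = wd[0], Co = wd[3];
  if (k % 2 == 0) stop("kernel size must be odd for 'same' padding");
  const int p = (k - 1) / 2;
  const size_t HW = (size_t)H * W;
  const size_t ld = (size_t)H * (W + 2 * p);
  NumericVector y((R_xlen_t)(HW * Co * N));
  y.attr("dim") = IntegerVector::create(H, W, Co, N);
  std::vector<std::vector<float> > Wd = pack_weights(w.begin(), k, Ci, Co,
                                                     false);
  std::vector<float> Mv(ld * (size_t)k * Ci, 0.0f);
  std::vector<float> Y(HW * (size_t)Co);
  for (int n = 0; n < N; ++n) {
    im2col_vertical(x.begin() + HW * Ci * (size_t)n, H, W, Ci, k,
                    Mv.data(), ld);
    conv_core(Mv.data(), ld, H, W, Ci, Co, k, Wd, b.begin(), Y.data());
    double* ys = y.begin() + HW * Co * (size_t)n;
    for (size_t q = 0; q < HW * (size_t)Co; ++q) ys[q] = (double)Y[q];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  int H, W, Ci, N; get_dims4(x, H, W, Ci, N);
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], Co = wd[3];
  const int p = (k - 1) / 2;
  const size_t HW = (size_t)H * W;
  const size_t ld = (size_t)H * (W + 2 * p);
  const int HWi = (int)HW, kc = k * Ci, kco = k * Co, ldi = (int)ld;
  NumericVector dx((R_xlen_t)(HW * Ci * N));
  dx.attr("dim") = IntegerVector::create(H, W, Ci, N);
  NumericVector dw(w.length()); dw.attr("dim") = wd;
  NumericVector db(Co);
  std::vector<std::vector<float> > Wflip = pack_weights(w.begin(), k, Ci, Co,
                                                        true);
  std::vector<std::vector<float> > dWd(k);
  for (int dj = 0; dj < k; ++dj) dWd[dj].assign((size_t)kc * Co, 0.0f);
  std::vector<float> Mv(ld * (size_t)k * Ci, 0.0f);
  std::vector<float> MvD(ld * (size_t)k * Co, 0.0f);
  std::vector<float> DY(HW * (size_t)Co);
  std::vector<float> DX(HW * (size_t)Ci);
  const float one = 1.0f;
  for (int n = 0; n < N; ++n) {
    const double* dys = dy.begin() + HW * Co * (size_t)n;
    for (size_t q = 0; q < HW * (size_t)Co; ++q) DY[q] = (float)dys[q];
    for (int co = 0; co < Co; ++co) {
      double s = 0.0;
      const double* pd = dys + HW * co;
      for (size_t q = 0; q < HW; ++q) s += pd[q];
      db[co] += s;
    }
    // weight gradient: dWd[dj] += window_dj(Mv(x))^T * DY
    im2col_vertical(x.begin() + HW * Ci * (size_t)n, H, W, Ci, k,
                    Mv.data(), ld);
    for (int dj = 0; dj < k; ++dj) {
      const float* A = Mv.data() + (size_t)H * dj;
      sgemm_("T", "N", &kc, &Co, &HWi, &one, A, &ldi, DY.data(), &HWi,
             &one, dWd[dj].data(), &kc);
    }
    // data gradient: convolution of dy with the flipped kernel
    im2col_vertical(dys, H, W, Co, k, MvD.data(), ld);
    conv_core(MvD.data(), ld, H, W, Co, Ci, k, Wflip, nullptr, DX.data());
    double* dxs = dx.begin() + HW * Ci * (size_t)n;
    for (size_t q = 0; q < HW * (size_t)Ci; ++q) dxs[q] = (double)DX[q];
  }
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < Ci; ++ci)
      for (int dj = 0; dj < k; ++dj)
        for (int di = 0; di < k; ++di)
          dw[di + (size_t)k * dj + (size_t)k * k * ci +
             (size_t)k * k * Ci * co] =
            (double)dWd[dj][(size_t)di + (size_t)k * ci + (size_t)kc * co];
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Transpose convolution, kernel k x k (k = 3 in the model), stride 2,
// output exactly doubles the spatial size; the implicit single padded
// row/column sits at the bottom/right edge.
// Kernel layout (k, k, C_out, C_in); column index in the scatter matrix
// is di + k*dj + k*k*cout.

// [[Rcpp::export]]
NumericVector cpp_tconv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int h, wdt, Ci, N; get_dims4(x, h, wdt, Ci, N);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4 || wd[0] != wd[1] || wd[3] != Ci)
    stop("transpose kernel must be (k, k, C_out, C_in)");
  const int k = wd[0], Co = wd[2];
  const int H = 2 * h, W = 2 * wdt;
  const size_t hw = (size_t)h * wdt, HW = (size_t)H * W;
  NumericVector y((R_xlen_t)(HW * Co * N));
  y.attr("dim") = IntegerVector::create(H, W, Co, N);
  arma::mat W2(const_cast<double*>(w.begin()), (size_t)k * k * Co, Ci, false, true);
  arma::mat COLS(hw, (size_t)k * k * Co);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + hw * Ci * (size_t)n,
                hw, Ci, false, true);
    COLS = X * W2.t();
    double* ys = y.begin() + HW * Co * (size_t)n;
    for (int co = 0; co < Co; ++co) {
      double* plane = ys + HW * co;
      for (int dj = 0; dj < k; ++dj) {
        for (int di = 0; di < k; ++di) {
          const double* col = COLS.colptr((size_t)di + (size_t)k * dj +
                                          (size_t)k * k * co);
          for (int j = 0; j < wdt; ++j) {
            const int cc = 2 * j + dj;
            if (cc >= W) continue;
            double* dplane = plane + (size_t)H * cc;
            const double* src = col + (size_t)h * j;
            for (int i = 0; i < h; ++i) {
              const int r = 2 * i + di;
              if (r >= H) break;
              dplane[r] += src[i];
            }
          }
        }
      }
      const double bc = b[co];
      for (size_t q = 0; q < HW; ++q) plane[q] += bc;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_tconv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  int h, wdt, Ci, N; get_dims4(x, h, wdt, Ci, N);
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], Co = wd[2];
  const int H = 2 * h, W = 2 * wdt;
  const size_t hw = (size_t)h * wdt, HW = (size_t)H * W;
  NumericVector dx((R_xlen_t)(hw * Ci * N));
  dx.attr("dim") = IntegerVector::create(h, wdt, Ci, N);
  NumericVector dw(w.length()); dw.attr("dim") = wd;
  NumericVector db(Co);
  arma::mat W2(const_cast<double*>(w.begin()), (size_t)k * k * Co, Ci, false, true);
  arma::mat dW2(dw.begin(), (size_t)k * k * Co, Ci, false, true);
  arma::mat G(hw, (size_t)k * k * Co);
  for (int n = 0; n < N; ++n) {
    const double* dys = dy.begin() + HW * Co * (size_t)n;
    for (int co = 0; co < Co; ++co) {
      const double* plane = dys + HW * co;
      double s = 0.0;
      for (size_t q = 0; q < HW; ++q) s += plane[q];
      db[co] += s;
      for (int dj = 0; dj < k; ++dj) {
        for (int di = 0; di < k; ++di) {
          double* col = G.colptr((size_t)di + (size_t)k * dj + (size_t)k * k * co);
          for (int j = 0; j < wdt; ++j) {
            const int cc = 2 * j + dj;
            double* dst = col + (size_t)h * j;
            if (cc >= W) { std::fill(dst, dst + h, 0.0); continue; }
            const double* src = plane + (size_t)H * cc;
            for (int i = 0; i < h; ++i) {
              const int r = 2 * i + di;
              dst[i] = (r < H) ? src[r] : 0.0;
            }
          }
        }
      }
    }
    arma::mat X(const_cast<double*>(x.begin()) + hw * Ci * (size_t)n,
                hw, Ci, false, true);
    dW2 += G.t() * X;
    arma::mat DX(dx.begin() + hw * Ci * (size_t)n, hw, Ci, false, true);
    DX = G * W2;
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("max-pooling requires even spatial dimensions");
  const int H2 = H / 2, W2 = W / 2;
  const size_t HW = (size_t)H * W, hw = (size_t)H2 * W2;
  NumericVector y((R_xlen_t)(hw * C * N));
  y.attr("dim") = IntegerVector::create(H2, W2, C, N);
  IntegerVector idx(y.length());
  R_xlen_t e = 0;
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + HW * C * (size_t)n;
    for (int c = 0; c < C; ++c) {
      const double* plane = xs + HW * c;
      for (int j = 0; j < W2; ++j) {
        for (int i = 0; i < H2; ++i) {
          double best = -std::numeric_limits<double>::infinity();
          size_t besti = 0;
          for (int b2 = 0; b2 < 2; ++b2) {
            for (int a = 0; a < 2; ++a) {
              const size_t li = (size_t)(2 * i + a) + (size_t)H * (2 * j + b2);
              const double v = plane[li];
              if (v > best) { best = v; besti = li; }
            }
          }
          y[e] = best;
          idx[e] = (int)(besti + HW * c);  // linear index within the sample slice
          ++e;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, IntegerVector idx, int H, int W) {
  int H2, W2, C, N; get_dims4(dy, H2, W2, C, N);
  const size_t HW = (size_t)H * W;
  NumericVector dx((R_xlen_t)(HW * C * N));
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const R_xlen_t per = (R_xlen_t)H2 * W2 * C;
  R_xlen_t e = 0;
  for (int n = 0; n < N; ++n) {
    double* dxs = dx.begin() + HW * C * (size_t)n;
    for (R_xlen_t q = 0; q < per; ++q, ++e) dxs[idx[e]] += dy[e];
  }
  return dx;
}

// Batch normalization over (H, W, N) per channel, biased variance.

// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                double eps) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const size_t HW = (size_t)H * W;
  const double M = (double)HW * N;
  NumericVector y(x.length()); y.attr("dim") = x.attr("dim");
  NumericVector mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + HW * (c + (size_t)C * n);
      for (size_t q = 0; q < HW; ++q) { const double v = p[q]; s += v; s2 += v * v; }
    }
    const double m = s / M;
    double v = s2 / M - m * m;
    if (v < 0) v = 0;
    mean[c] = m; var[c] = v;
    const double istd = 1.0 / std::sqrt(v + eps);
    const double g = gamma[c], bb = beta[c];
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + HW * (c + (size_t)C * n);
      double* py = y.begin() + HW * (c + (size_t)C * n);
      for (size_t q = 0; q < HW; ++q) py[q] = g * (p[q] - m) * istd + bb;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export]]
NumericVector cpp_bn_infer(NumericVector x, NumericVector gamma,
                           NumericVector beta, NumericVector rmean,
                           NumericVector rvar, double eps) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const size_t HW = (size_t)H * W;
  NumericVector y(x.length()); y.attr("dim") = x.attr("dim");
  for (int c = 0; c < C; ++c) {
    const double m = rmean[c];
    const double istd = 1.0 / std::sqrt(rvar[c] + eps);
    const double g = gamma[c], bb = beta[c];
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + HW * (c + (size_t)C * n);
      double* py = y.begin() + HW * (c + (size_t)C * n);
      for (size_t q = 0; q < HW; ++q) py[q] = g * (p[q] - m) * istd + bb;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, NumericVector gamma, NumericVector mean,
                NumericVector var, NumericVector dy, double eps) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const size_t HW = (size_t)H * W;
  const double M = (double)HW * N;
  NumericVector dx(x.length()); dx.attr("dim") = x.attr("dim");
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double m = mean[c];
    const double istd = 1.0 / std::sqrt(var[c] + eps);
    double s1 = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* px = x.begin() + HW * (c + (size_t)C * n);
      const double* pd = dy.begin() + HW * (c + (size_t)C * n);
      for (size_t q = 0; q < HW; ++q) {
        s1 += pd[q];
        s2 += pd[q] * (px[q] - m) * istd;
      }
    }
    dgamma[c] = s2; dbeta[c] = s1;
    const double g = gamma[c];
    for (int n = 0; n < N; ++n) {
      const double* px = x.begin() + HW * (c + (size_t)C * n);
      const double* pd = dy.begin() + HW * (c + (size_t)C * n);
      double* pdx = dx.begin() + HW * (c + (size_t)C * n);
      for (size_t q = 0; q < HW; ++q) {
        const double xh = (px[q] - m) * istd;
        pdx[q] = g * istd / M * (M * pd[q] - s1 - xh * s2);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Connected-component labelling of a binary mask (0 background, 1 foreground)
// by breadth-first search; connectivity 4 or 8.  Labels are 1..K in first-pixel
// (column-major) discovery order, background stays 0.

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int dr8[8] = { -1, 1, 0, 0, -1, -1, 1, 1 };
  const int dc8[8] = { 0, 0, -1, 1, -1, 1, -1, 1 };
  const int nd = (connectivity == 4) ? 4 : 8;
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.clear();
      stack.push_back(i + H * j);
      while (!stack.empty()) {
        const int cur = stack.back(); stack.pop_back();
        const int ci = cur % H, cj = cur / H;
        for (int d = 0; d < nd; ++d) {
          const int ni = ci + dr8[d], nj = cj + dc8[d];
          if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
          if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back(ni + H * nj);
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Float tensor pipeline.
//
// During training and inference the activations flow between layer kernels
// as single-precision tensors held in external pointers, so nothing is
// converted back to R doubles (or allocated by R) between layers.  Weights
// and gradients cross the R boundary as ordinary double arrays, which are
// small compared to the activations.

struct FTensor {
  std::vector<float> v;
  int d[4];
  size_t size() const {
    return (size_t)d[0] * d[1] * d[2] * d[3];
  }
};
typedef Rcpp::XPtr<FTensor> FTp;

static FTp make_ft(int a, int b, int c, int n, bool zero = false) {
  FTensor* t = new FTensor();
  t->d[0] = a; t->d[1] = b; t->d[2] = c; t->d[3] = n;
  if (zero) t->v.assign(t->size(), 0.0f); else t->v.resize(t->size());
  return FTp(t, true);
}

// [[Rcpp::export]]
SEXP ft_from_array(NumericVector x) {
  int a, b, c, n; get_dims4(x, a, b, c, n);
  FTp t = make_ft(a, b, c, n);
  const double* p = x.begin();
  for (size_t q = 0; q < t->size(); ++q) t->v[q] = (float)p[q];
  return t;
}

// [[Rcpp::export]]
NumericVector ft_to_array(SEXP xp) {
  FTp t(xp);
  NumericVector out((R_xlen_t)t->size());
  for (size_t q = 0; q < t->size(); ++q) out[q] = (double)t->v[q];
  out.attr("dim") = IntegerVector::create(t->d[0], t->d[1], t->d[2], t->d[3]);
  return out;
}

// [[Rcpp::export]]
IntegerVector ft_dims(SEXP xp) {
  FTp t(xp);
  return IntegerVector::create(t->d[0], t->d[1], t->d[2], t->d[3]);
}

// [[Rcpp::export]]
SEXP ft_conv2d_fwd(SEXP xp, NumericVector w, NumericVector b) {
  FTp x(xp);
  const int H = x->d[0], W = x->d[1], Ci = x->d[2], N = x->d[3];
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4 || wd[0] != wd[1] || wd[2] != Ci)
    stop("kernel must be (k, k, C_in, C_out) matching the input");
  const int k = wd[0], Co = wd[3];
  const int p = (k - 1) / 2;
  const size_t HW = (size_t)H * W;
  const size_t ld = (size_t)H * (W + 2 * p);
  FTp y = make_ft(H, W, Co, N);
  std::vector<std::vector<float> > Wd = pack_weights(w.begin(), k, Ci, Co,
                                                     false);
  std::vector<float> Mv(ld * (size_t)k * Ci, 0.0f);
  for (int n = 0; n < N; ++n) {
    im2col_vertical(x->v.data() + HW * Ci * (size_t)n, H, W, Ci, k,
                    Mv.data(), ld);
    conv_core(Mv.data(), ld, H, W, Ci, Co, k, Wd, b.begin(),
              y->v.data() + HW * Co * (size_t)n);
  }
  return y;
}

// [[Rcpp::export]]
List ft_conv2d_bwd(SEXP xp, NumericVector w, SEXP dyp) {
  FTp x(xp); FTp dy(dyp);
  const int H = x->d[0], W = x->d[1], Ci = x->d[2], N = x->d[3];
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], Co = wd[3];
  const int p = (k - 1) / 2;
  const size_t HW = (size_t)H * W;
  const size_t ld = (size_t)H * (W + 2 * p);
  const int HWi = (int)HW, kc = k * Ci, ldi = (int)ld;
  FTp dx = make_ft(H, W, Ci, N);
  NumericVector dw(w.length()); dw.attr("dim") = wd;
  NumericVector db(Co);
  std::vector<std::vector<float> > Wflip = pack_weights(w.begin(), k, Ci, Co,
                                                        true);
  std::vector<std::vector<float> > dWd(k);
  for (int dj = 0; dj < k; ++dj) dWd[dj].assign((size_t)kc * Co, 0.0f);
  std::vector<float> Mv(ld * (size_t)k * Ci, 0.0f);
  std::vector<float> MvD(ld * (size_t)k * Co, 0.0f);
  const float one = 1.0f;
  for (int n = 0; n < N; ++n) {
    const float* dys = dy->v.data() + HW * Co * (size_t)n;
    for (int co = 0; co < Co; ++co) {
      double s = 0.0;
      const float* pd = dys + HW * co;
      for (size_t q = 0; q < HW; ++q) s += pd[q];
      db[co] += s;
    }
    im2col_vertical(x->v.data() + HW * Ci * (size_t)n, H, W, Ci, k,
                    Mv.data(), ld);
    for (int dj = 0; dj < k; ++dj) {
      const float* A = Mv.data() + (size_t)H * dj;
      sgemm_("T", "N", &kc, &Co, &HWi, &one, A, &ldi, dys, &HWi,
             &one, dWd[dj].data(), &kc);
    }
    im2col_vertical(dys, H, W, Co, k, MvD.data(), ld);
    conv_core(MvD.data(), ld, H, W, Co, Ci, k, Wflip, nullptr,
              dx->v.data() + HW * Ci * (size_t)n);
  }
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < Ci; ++ci)
      for (int dj = 0; dj < k; ++dj)
        for (int di = 0; di < k; ++di)
          dw[di + (size_t)k * dj + (size_t)k * k * ci +
             (size_t)k * k * Ci * co] =
            (double)dWd[dj][(size_t)di + (size_t)k * ci + (size_t)kc * co];
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Batch normalization (+ optional fused ReLU) on float tensors; statistics
// are accumulated in double.

// [[Rcpp::export]]
List ft_bn_relu_fwd(SEXP xp, NumericVector gamma, NumericVector beta,
                    double eps, bool relu) {
  FTp x(xp);
  const int H = x->d[0], W = x->d[1], C = x->d[2], N = x->d[3];
  const size_t HW = (size_t)H * W;
  const double M = (double)HW * N;
  FTp y = make_ft(H, W, C, N);
  NumericVector mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const float* p = x->v.data() + HW * (c + (size_t)C * n);
      for (size_t q = 0; q < HW; ++q) {
        const double v = p[q]; s += v; s2 += v * v;
      }
    }
    const double m = s / M;
    double v = s2 / M - m * m;
    if (v < 0) v = 0;
    mean[c] = m; var[c] = v;
    const float istd = (float)(1.0 / std::sqrt(v + eps));
    const float g = (float)gamma[c], bb = (float)beta[c], mf = (float)m;
    for (int n = 0; n < N; ++n) {
      const float* p = x->v.data() + HW * (c + (size_t)C * n);
      float* py = y->v.data() + HW * (c + (size_t)C * n);
      for (size_t q = 0; q < HW; ++q) {
        float val = g * (p[q] - mf) * istd + bb;
        py[q] = (relu && val < 0.0f) ? 0.0f : val;
      }
    }
  }
  return List::create(_["y"] = (SEXP)y, _["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export]]
SEXP ft_bn_infer(SEXP xp, NumericVector gamma, NumericVector beta,
                 NumericVector rmean, NumericVector rvar, double eps,
                 bool relu) {
  FTp x(xp);
  const int H = x->d[0], W = x->d[1], C = x->d[2], N = x->d[3];
  const size_t HW = (size_t)H * W;
  FTp y = make_ft(H, W, C, N);
  for (int c = 0; c < C; ++c) {
    const float istd = (float)(1.0 / std::sqrt(rvar[c] + eps));
    const float g = (float)gamma[c], bb = (float)beta[c];
    const float mf = (float)rmean[c];
    for (int n = 0; n < N; ++n) {
      const float* p = x->v.data() + HW * (c + (size_t)C * n);
      float* py = y->v.data() + HW * (c + (size_t)C * n);
      for (size_t q = 0; q < HW; ++q) {
        float val = g * (p[q] - mf) * istd + bb;
        py[q] = (relu && val < 0.0f) ? 0.0f : val;
      }
    }
  }
  return y;
}

// Backward through (optional ReLU) + batch norm.  `zp` is the convolution
// output cached in the forward pass, `yp` the post-activation output (used
// for the ReLU mask), `dyp` the incoming gradient.

// [[Rcpp::export]]
List ft_bn_relu_bwd(SEXP zp, SEXP yp, NumericVector gamma,
                    NumericVector mean, NumericVector var, SEXP dyp,
                    double eps, bool relu) {
  FTp z(zp); FTp y(yp); FTp dy(dyp);
  const int H = z->d[0], W = z->d[1], C = z->d[2], N = z->d[3];
  const size_t HW = (size_t)H * W;
  const double M = (double)HW * N;
  FTp dx = make_ft(H, W, C, N);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double m = mean[c];
    const double istd = 1.0 / std::sqrt(var[c] + eps);
    double s1 = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const size_t off = HW * (c + (size_t)C * n);
      const float* pz = z->v.data() + off;
      const float* py = y->v.data() + off;
      const float* pd = dy->v.data() + off;
      for (size_t q = 0; q < HW; ++q) {
        const double d = (relu && py[q] <= 0.0f) ? 0.0 : (double)pd[q];
        s1 += d;
        s2 += d * ((double)pz[q] - m) * istd;
      }
    }
    dgamma[c] = s2; dbeta[c] = s1;
    const double g = gamma[c];
    const double f = g * istd / M;
    for (int n = 0; n < N; ++n) {
      const size_t off = HW * (c + (size_t)C * n);
      const float* pz = z->v.data() + off;
      const float* py = y->v.data() + off;
      const float* pd = dy->v.data() + off;
      float* px = dx->v.data() + off;
      for (size_t q = 0; q < HW; ++q) {
        const double d = (relu && py[q] <= 0.0f) ? 0.0 : (double)pd[q];
        const double xh = ((double)pz[q] - m) * istd;
        px[q] = (float)(f * (M * d - s1 - xh * s2));
      }
    }
  }
  return List::create(_["dx"] = (SEXP)dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
List ft_maxpool2_fwd(SEXP xp) {
  FTp x(xp);
  const int H = x->d[0], W = x->d[1], C = x->d[2], N = x->d[3];
  if (H % 2 || W % 2) stop("max-pooling requires even spatial dimensions");
  const int H2 = H / 2, W2 = W / 2;
  const size_t HW = (size_t)H * W;
  FTp y = make_ft(H2, W2, C, N);
  IntegerVector idx((R_xlen_t)y->size());
  R_xlen_t e = 0;
  for (int n = 0; n < N; ++n) {
    const float* xs = x->v.data() + HW * C * (size_t)n;
    for (int c = 0; c < C; ++c) {
      const float* plane = xs + HW * c;
      for (int j = 0; j < W2; ++j) {
        for (int i = 0; i < H2; ++i) {
          float best = -std::numeric_limits<float>::infinity();
          size_t besti = 0;
          for (int b2 = 0; b2 < 2; ++b2)
            for (int a = 0; a < 2; ++a) {
              const size_t li = (size_t)(2 * i + a) + (size_t)H * (2 * j + b2);
              if (plane[li] > best) { best = plane[li]; besti = li; }
            }
          y->v[e] = best;
          idx[e] = (int)(besti + HW * c);
          ++e;
        }
      }
    }
  }
  return List::create(_["y"] = (SEXP)y, _["idx"] = idx);
}

// [[Rcpp::export]]
SEXP ft_maxpool2_bwd(SEXP dyp, IntegerVector idx, int H, int W) {
  FTp dy(dyp);
  const int C = dy->d[2], N = dy->d[3];
  const size_t HW = (size_t)H * W;
  FTp dx = make_ft(H, W, C, N, true);
  const R_xlen_t per = (R_xlen_t)dy->d[0] * dy->d[1] * C;
  R_xlen_t e = 0;
  for (int n = 0; n < N; ++n) {
    float* dxs = dx->v.data() + HW * C * (size_t)n;
    for (R_xlen_t q = 0; q < per; ++q, ++e) dxs[idx[e]] += dy->v[e];
  }
  return dx;
}

// [[Rcpp::export]]
SEXP ft_tconv2d_fwd(SEXP xp, NumericVector w, NumericVector b) {
  FTp x(xp);
  const int h = x->d[0], wdt = x->d[1], Ci = x->d[2], N = x->d[3];
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4 || wd[0] != wd[1] || wd[3] != Ci)
    stop("transpose kernel must be (k, k, C_out, C_in)");
  const int k = wd[0], Co = wd[2];
  const int H = 2 * h, W = 2 * wdt;
  const size_t hw = (size_t)h * wdt, HW = (size_t)H * W;
  const int hwi = (int)hw, kkCo = k * k * Co;
  FTp y = make_ft(H, W, Co, N, true);
  std::vector<float> W2((size_t)kkCo * Ci);
  for (size_t q = 0; q < W2.size(); ++q) W2[q] = (float)w[q];
  std::vector<float> COLS(hw * (size_t)kkCo);
  const float one = 1.0f, zero = 0.0f;
  for (int n = 0; n < N; ++n) {
    const float* X = x->v.data() + hw * Ci * (size_t)n;
    // COLS (hw x kkCo) = X (hw x Ci) * W2^T (Ci x kkCo)
    sgemm_("N", "T", &hwi, &kkCo, &Ci, &one, X, &hwi, W2.data(), &kkCo,
           &zero, COLS.data(), &hwi);
    float* ys = y->v.data() + HW * Co * (size_t)n;
    for (int co = 0; co < Co; ++co) {
      float* plane = ys + HW * co;
      for (int dj = 0; dj < k; ++dj)
        for (int di = 0; di < k; ++di) {
          const float* col = COLS.data() +
            hw * ((size_t)di + (size_t)k * dj + (size_t)k * k * co);
          for (int j = 0; j < wdt; ++j) {
            const int cc = 2 * j + dj;
            if (cc >= W) continue;
            float* dplane = plane + (size_t)H * cc;
            const float* src = col + (size_t)h * j;
            for (int i = 0; i < h; ++i) {
              const int r = 2 * i + di;
              if (r >= H) break;
              dplane[r] += src[i];
            }
          }
        }
      const float bc = (float)b[co];
      for (size_t q = 0; q < HW; ++q) plane[q] += bc;
    }
  }
  return y;
}

// [[Rcpp::export]]
List ft_tconv2d_bwd(SEXP xp, NumericVector w, SEXP dyp) {
  FTp x(xp); FTp dy(dyp);
  const int h = x->d[0], wdt = x->d[1], Ci = x->d[2], N = x->d[3];
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], Co = wd[2];
  const int H = 2 * h, W = 2 * wdt;
  const size_t hw = (size_t)h * wdt, HW = (size_t)H * W;
  const int hwi = (int)hw, kkCo = k * k * Co;
  FTp dx = make_ft(h, wdt, Ci, N);
  NumericVector dw(w.length()); dw.attr("dim") = wd;
  NumericVector db(Co);
  std::vector<float> W2((size_t)kkCo * Ci);
  for (size_t q = 0; q < W2.size(); ++q) W2[q] = (float)w[q];
  std::vector<float> dW2((size_t)kkCo * Ci, 0.0f);
  std::vector<float> G(hw * (size_t)kkCo);
  const float one = 1.0f, zero = 0.0f;
  for (int n = 0; n < N; ++n) {
    const float* dys = dy->v.data() + HW * Co * (size_t)n;
    for (int co = 0; co < Co; ++co) {
      const float* plane = dys + HW * co;
      double s = 0.0;
      for (size_t q = 0; q < HW; ++q) s += plane[q];
      db[co] += s;
      for (int dj = 0; dj < k; ++dj)
        for (int di = 0; di < k; ++di) {
          float* col = G.data() +
            hw * ((size_t)di + (size_t)k * dj + (size_t)k * k * co);
          for (int j = 0; j < wdt; ++j) {
            const int cc = 2 * j + dj;
            float* dst = col + (size_t)h * j;
            if (cc >= W) { std::fill(dst, dst + h, 0.0f); continue; }
            const float* src = plane + (size_t)H * cc;
            for (int i = 0; i < h; ++i) {
              const int r = 2 * i + di;
              dst[i] = (r < H) ? src[r] : 0.0f;
            }
          }
        }
    }
    const float* X = x->v.data() + hw * Ci * (size_t)n;
    // dW2 (kkCo x Ci) += G^T (kkCo x hw) * X (hw x Ci)
    sgemm_("T", "N", &kkCo, &Ci, &hwi, &one, G.data(), &hwi, X, &hwi,
           &one, dW2.data(), &kkCo);
    // dX (hw x Ci) = G (hw x kkCo) * W2 (kkCo x Ci)
    sgemm_("N", "N", &hwi, &Ci, &kkCo, &one, G.data(), &hwi, W2.data(),
           &kkCo, &zero, dx->v.data() + hw * Ci * (size_t)n, &hwi);
  }
  for (R_xlen_t q = 0; q < dw.length(); ++q) dw[q] = (double)dW2[q];
  return List::create(_["dx"] = (SEXP)dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
SEXP ft_concat(SEXP ap, SEXP bp) {
  FTp a(ap); FTp b(bp);
  const int H = a->d[0], W = a->d[1], Ca = a->d[2], Cb = b->d[2],
    N = a->d[3];
  if (b->d[0] != H || b->d[1] != W || b->d[3] != N)
    stop("concat: incompatible shapes");
  const size_t HW = (size_t)H * W;
  FTp y = make_ft(H, W, Ca + Cb, N);
  for (int n = 0; n < N; ++n) {
    float* ys = y->v.data() + HW * (Ca + Cb) * (size_t)n;
    std::copy(a->v.data() + HW * Ca * (size_t)n,
              a->v.data() + HW * Ca * (size_t)(n + 1), ys);
    std::copy(b->v.data() + HW * Cb * (size_t)n,
              b->v.data() + HW * Cb * (size_t)(n + 1), ys + HW * Ca);
  }
  return y;
}

// [[Rcpp::export]]
List ft_split_channels(SEXP xp, int c_first) {
  FTp x(xp);
  const int H = x->d[0], W = x->d[1], C = x->d[2], N = x->d[3];
  if (c_first <= 0 || c_first >= C) stop("invalid channel split");
  const size_t HW = (size_t)H * W;
  FTp a = make_ft(H, W, c_first, N);
  FTp b = make_ft(H, W, C - c_first, N);
  for (int n = 0; n < N; ++n) {
    const float* xs = x->v.data() + HW * C * (size_t)n;
    std::copy(xs, xs + HW * c_first,
              a->v.data() + HW * c_first * (size_t)n);
    std::copy(xs + HW * c_first, xs + HW * C,
              b->v.data() + HW * (C - c_first) * (size_t)n);
  }
  return List::create(_["first"] = (SEXP)a, _["rest"] = (SEXP)b);
}

// [[Rcpp::export]]
SEXP ft_add(SEXP ap, SEXP bp) {
  FTp a(ap); FTp b(bp);
  if (a->size() != b->size()) stop("ft_add: incompatible sizes");
  FTp y = make_ft(a->d[0], a->d[1], a->d[2], a->d[3]);
  for (size_t q = 0; q < y->size(); ++q) y->v[q] = a->v[q] + b->v[q];
  return y;
}

// Sigmoid of a float tensor, returned as a double R array (the head output
// crosses back into R for loss/metric computation).

// [[Rcpp::export]]
NumericVector ft_sigmoid(SEXP xp) {
  FTp x(xp);
  NumericVector out((R_xlen_t)x->size());
  for (size_t q = 0; q < x->size(); ++q)
    out[q] = 1.0 / (1.0 + std::exp(-(double)x->v[q]));
  out.attr("dim") = IntegerVector::create(x->d[0], x->d[1], x->d[2],
                                          x->d[3]);
  return out;
}
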