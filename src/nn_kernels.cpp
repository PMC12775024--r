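// Convolution and pooling kernels for the modality feature extractors and
// the ViT patch embedding. Tensors follow the package convention
// (channel, row, col, image): column-major R arrays with channel fastest.
// Convolutions are computed per image as im2col gathers followed by a BLAS
// gemm; the im2col row index is c + C*ki + C*k*kj (channel fastest), which
// must match the (C_out x C*k*k) weight layout used on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

static void im2col_one(const double* x, int C, int H, int W,
                       int k, int stride, int pad, arma::mat& cols) {
  const int Ho = out_dim(H, k, stride, pad);
  const int Wo = out_dim(W, k, stride, pad);
  // cols is (C*k*k) x (Ho*Wo); column index io + Ho*jo
  for (int jo = 0; jo < Wo; ++jo) {
    for (int io = 0; io < Ho; ++io) {
      double* dst = cols.colptr(io + Ho * jo);
      for (int kj = 0; kj < k; ++kj) {
        const int j = jo * stride + kj - pad;
        for (int ki = 0; ki < k; ++ki) {
          const int i = io * stride + ki - pad;
          double* d = dst + C * (ki + k * kj);
          if (i >= 0 && i < H && j >= 0 && j < W) {
            const double* src = x + (size_t)C * (i + (size_t)H * j);
            std::copy(src, src + C, d);
          } else {
            std::fill(d, d + C, 0.0);
          }
        }
      }
    }
  }
}

static void col2im_one(const arma::mat& cols, int C, int H, int W,
                       int k, int stride, int pad, double* dx) {
  const int Ho = out_dim(H, k, stride, pad);
  const int Wo = out_dim(W, k, stride, pad);
  for (int jo = 0; jo < Wo; ++jo) {
    for (int io = 0; io < Ho; ++io) {
      const double* src = cols.colptr(io + Ho * jo);
      for (int kj = 0; kj < k; ++kj) {
        const int j = jo * stride + kj - pad;
        if (j < 0 || j >= W) continue;
        for (int ki = 0; ki < k; ++ki) {
          const int i = io * stride + ki - pad;
          if (i < 0 || i >= H) continue;
          double* d = dx + (size_t)C * (i + (size_t)H * j);
          const double* s = src + C * (ki + k * kj);
          for (int c = 0; c < C; ++c) d[c] += s[c];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_forward")]]
NumericVector conv2d_forward(NumericVector x, NumericMatrix w,
                             NumericVector b, int k, int stride, int pad) {
  IntegerVector dims = x.attr("dim");
  if (dims.size() != 4) stop("x must be a (C,H,W,N) array");
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  if (w.ncol() != C * k * k) stop("weight shape mismatch");
  const int Cout = w.nrow();
  const int Ho = out_dim(H, k, stride, pad);
  const int Wo = out_dim(W, k, stride, pad);

  arma::mat wm(w.begin(), Cout, C * k * k, false);
  arma::vec bv(b.begin(), Cout, false);
  NumericVector out((size_t)Cout * Ho * Wo * N);
  out.attr("dim") = IntegerVector::create(Cout, Ho, Wo, N);
  arma::mat cols(C * k * k, Ho * Wo);

  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (size_t)C * H * W * n, C, H, W, k, stride, pad, cols);
    arma::mat o(out.begin() + (size_t)Cout * Ho * Wo * n, Cout, Ho * Wo, false, true);
    o = wm * cols;
    o.each_col() += bv;
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_backward")]]
List conv2d_backward(NumericVector x, NumericMatrix w, NumericVector dout,
                     int k, int stride, int pad, bool need_dx) {
  IntegerVector dims = x.attr("dim");
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  const int Cout = w.nrow();
  const int Ho = out_dim(H, k, stride, pad);
  const int Wo = out_dim(W, k, stride, pad);

  arma::mat wm(w.begin(), Cout, C * k * k, false);
  arma::mat dW(Cout, C * k * k, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  NumericVector dx;
  if (need_dx) {
    dx = NumericVector((size_t)C * H * W * N);
    dx.attr("dim") = IntegerVector::create(C, H, W, N);
  }
  arma::mat cols(C * k * k, Ho * Wo);

  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (size_t)C * H * W * n, C, H, W, k, stride, pad, cols);
    arma::mat do_((double*)dout.begin() + (size_t)Cout * Ho * Wo * n,
                  Cout, Ho * Wo, false, true);
    dW += do_ * cols.t();
    db += arma::sum(do_, 1);
    if (need_dx) {
      arma::mat dcols = wm.t() * do_;
      col2im_one(dcols, C, H, W, k, stride, pad,
                 dx.begin() + (size_t)C * H * W * n);
    }
  }
  List res = List::create(_["dw"] = wrap(dW), _["db"] = wrap(db));
  if (need_dx) res["dx"] = dx;
  return res;
}

// 2x2 max pooling, stride 2; dims must be even. Ties take the first
// (lowest-offset) element, keeping backward deterministic.
// [[Rcpp::export(name = ".maxpool2_forward")]]
List maxpool2_forward(NumericVector x) {
  IntegerVector dims = x.attr("dim");
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  if (H % 2 || W % 2) stop("maxpool2 requires even spatial dims");
  const int Ho = H / 2, Wo = W / 2;

  NumericVector out((size_t)C * Ho * Wo * N);
  out.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  IntegerVector amax((size_t)C * Ho * Wo * N); // linear offset within image

  const double* xp = x.begin();
  double* op = out.begin();
  int* ap = amax.begin();
  for (int n = 0; n < N; ++n) {
    const double* xi = xp + (size_t)C * H * W * n;
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        for (int c = 0; c < C; ++c) {
          double best = -HUGE_VAL; int barg = 0;
          for (int dj = 0; dj < 2; ++dj) {
            for (int di = 0; di < 2; ++di) {
              const int i = 2 * io + di, j = 2 * jo + dj;
              const size_t off = c + (size_t)C * (i + (size_t)H * j);
              if (xi[off] > best) { best = xi[off]; barg = (int)off; }
            }
          }
          const size_t oo = (size_t)C * Ho * Wo * n +
                            c + (size_t)C * (io + (size_t)Ho * jo);
          op[oo] = best;
          ap[oo] = barg;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// In-place ReLU; returns the activation mask for backward. Safe only on
// arrays owned exclusively by the training loop.
// [[Rcpp::export(name = ".relu_fwd_inplace")]]
LogicalVector relu_fwd_inplace(NumericVector x) {
  const R_xlen_t n = x.size();
  LogicalVector mask(n);
  double* xp = x.begin();
  int* mp = mask.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    if (xp[i] > 0) {
      mp[i] = 1;
    } else {
      mp[i] = 0;
      xp[i] = 0;
    }
  }
  return mask;
}

// In-place dout *= mask.
// [[Rcpp::export(name = ".mask_bwd_inplace")]]
void mask_bwd_inplace(NumericVector dout, LogicalVector mask) {
  const R_xlen_t n = dout.size();
  double* dp = dout.begin();
  const int* mp = mask.begin();
  for (R_xlen_t i = 0; i < n; ++i)
    if (!mp[i]) dp[i] = 0;
}

// Fused single-pass Adam/AdamW update, mutating p, m and v in place.
// Decoupled weight decay (wd) is applied by the caller only to weight
// matrices. Safe only because the training loops own these buffers.
// [[Rcpp::export(name = ".adam_update_inplace")]]
void adam_update_inplace(NumericVector p, NumericVector g,
                         NumericVector m, NumericVector v,
                         int step, double lr, double beta1, double beta2,
                         double eps, double wd) {
  const R_xlen_t n = p.size();
  if (g.size() != n || m.size() != n || v.size() != n)
    stop("adam buffers must have identical length");
  const double bc1 = 1.0 - std::pow(beta1, step);
  const double bc2 = 1.0 - std::pow(beta2, step);
  double* pp = p.begin();
  const double* gp = g.begin();
  double* mp = m.begin();
  double* vp = v.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = gp[i];
    mp[i] = beta1 * mp[i] + (1.0 - beta1) * gi;
    vp[i] = beta2 * vp[i] + (1.0 - beta2) * gi * gi;
    double upd = lr * (mp[i] / bc1) / (std::sqrt(vp[i] / bc2) + eps);
    if (wd > 0) upd += lr * wd * pp[i];
    pp[i] -= upd;
  }
}

// [[Rcpp::export(name = ".maxpool2_backward")]]
NumericVector maxpool2_backward(NumericVector dout, IntegerVector amax,
                                IntegerVector in_dims) {
  const int C = in_dims[0], H = in_dims[1], W = in_dims[2], N = in_dims[3];
  IntegerVector od = dout.attr("dim");
  const size_t per_out = (size_t)od[0] * od[1] * od[2];
  NumericVector dx((size_t)C * H * W * N);
  dx.attr("dim") = in_dims;
  const double* dp = dout.begin();
  const int* ap = amax.begin();
  double* xp = dx.begin();
  for (int n = 0; n < N; ++n) {
    const size_t ob = per_out * n, ib = (size_t)C * H * W * n;
    for (size_t t = 0; t < per_out; ++t)
      xp[ib + (size_t)ap[ob + t]] += dp[ob + t];
  }
  return dx;
}
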