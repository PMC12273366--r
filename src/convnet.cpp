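// Minimal conv-net kernels (im2col + BLAS matmul) used by the backbone code.
// Array layout follows R: column-major, dims (H, W, C, N) for activations and
// (kh, kw, Cin, Cout) for convolution weights.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dims4(const NumericVector &a, int &d0, int &d1, int &d2,
                             int &d3) {
  IntegerVector dm = a.attr("dim");
  if (dm.size() != 4)
    stop("expected a 4-d array (H, W, C, N)");
  d0 = dm[0];
  d1 = dm[1];
  d2 = dm[2];
  d3 = dm[3];
}

static arma::mat im2col(const double *x, int H, int W, int C, int N, int kh,
                        int kw, int stride, int pad, int Ho, int Wo) {
  const int K = kh * kw * C;
  arma::mat cols(K, (arma::uword)Ho * Wo * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        arma::uword col =
            (arma::uword)ho + (arma::uword)Ho * wo + (arma::uword)Ho * Wo * n;
        double *cp = cols.colptr(col);
        for (int ci = 0; ci < C; ++ci)
          for (int kj = 0; kj < kw; ++kj) {
            int wim = wo * stride + kj - pad;
            if (wim < 0 || wim >= W)
              continue;
            const double *xp =
                x + (size_t)H * (wim + (size_t)W * (ci + (size_t)C * n));
            for (int ki = 0; ki < kh; ++ki) {
              int him = ho * stride + ki - pad;
              if (him < 0 || him >= H)
                continue;
              cp[ki + kh * kj + kh * kw * ci] = xp[him];
            }
          }
      }
  return cols;
}


// Fast path for stride-1 "same" convolutions (Ho == H, Wo == W): the patch
// matrix is built transposed, (H*W*N) x K, so every patch-offset column is
// a contiguously shifted copy of the input plane.
static arma::mat im2colT_same(const double *x, int H, int W, int C, int N,
                              int kh, int kw, int pad) {
  const int K = kh * kw * C;
  arma::mat colsT((arma::uword)H * W * N, K, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci)
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        double *dst0 = colsT.colptr(ki + kh * kj + kh * kw * ci);
        const int lo = std::max(0, pad - ki);          // first valid ho
        const int hi = std::min(H - 1, H - 1 + pad - ki);
        if (hi < lo) continue;
        for (int n = 0; n < N; ++n)
          for (int wo = 0; wo < W; ++wo) {
            int wim = wo + kj - pad;
            if (wim < 0 || wim >= W) continue;
            const double *src =
                x + (size_t)H * (wim + (size_t)W * (ci + (size_t)C * n)) +
                (lo + ki - pad);
            std::copy(src, src + (hi - lo + 1),
                      dst0 + (size_t)H * (wo + (size_t)W * n) + lo);
          }
      }
  return colsT;
}

static void col2imT_same(const arma::mat &dcolsT, double *dx, int H, int W,
                         int C, int N, int kh, int kw, int pad) {
  for (int ci = 0; ci < C; ++ci)
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        const double *src0 = dcolsT.colptr(ki + kh * kj + kh * kw * ci);
        const int lo = std::max(0, pad - ki);
        const int hi = std::min(H - 1, H - 1 + pad - ki);
        if (hi < lo) continue;
        for (int n = 0; n < N; ++n)
          for (int wo = 0; wo < W; ++wo) {
            int wim = wo + kj - pad;
            if (wim < 0 || wim >= W) continue;
            double *dst =
                dx + (size_t)H * (wim + (size_t)W * (ci + (size_t)C * n)) +
                (lo + ki - pad);
            const double *src = src0 + (size_t)H * (wo + (size_t)W * n) + lo;
            for (int i = 0; i <= hi - lo; ++i)
              dst[i] += src[i];
          }
      }
}

// [[Rcpp::export(rng = false)]]
NumericVector rfed_conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad, int relu = 0) {
  int H, W, C, N, kh, kw, Cin, Cout;
  get_dims4(x, H, W, C, N);
  get_dims4(w, kh, kw, Cin, Cout);
  if (Cin != C)
    stop("input channel count does not match kernel");
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1)
    stop("kernel larger than padded input");
  arma::mat Wm(const_cast<double *>(REAL(w)), kh * kw * Cin, Cout, false,
               true);
  const bool same = (stride == 1 && Ho == H && Wo == W);
  arma::mat out_cols; // (Ho*Wo*N) x Cout
  if (same) {
    out_cols = im2colT_same(REAL(x), H, W, C, N, kh, kw, pad) * Wm;
  } else {
    arma::mat cols =
        im2col(REAL(x), H, W, C, N, kh, kw, stride, pad, Ho, Wo);
    out_cols = cols.t() * Wm;
  }
  NumericVector out((R_xlen_t)Ho * Wo * Cout * N);
  double *op = REAL(out);
  const double *bp = REAL(b);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double *src = out_cols.colptr(co) + (arma::uword)Ho * Wo * n;
      double *dst = op + (size_t)Ho * Wo * (co + (size_t)Cout * n);
      const double bb = bp[co];
      if (relu)
        for (int p = 0; p < Ho * Wo; ++p)
          dst[p] = std::max(src[p] + bb, 0.0);
      else
        for (int p = 0; p < Ho * Wo; ++p)
          dst[p] = src[p] + bb;
    }
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return out;
}

// [[Rcpp::export(rng = false)]]
List rfed_conv2d_bw(NumericVector x, NumericVector w, NumericVector dout,
                    int stride, int pad) {
  int H, W, C, N, kh, kw, Cin, Cout, Ho, Wo, Co2, N2;
  get_dims4(x, H, W, C, N);
  get_dims4(w, kh, kw, Cin, Cout);
  get_dims4(dout, Ho, Wo, Co2, N2);
  if (Cin != C || Co2 != Cout || N2 != N)
    stop("gradient dimensions do not match forward pass");
  const int K = kh * kw * Cin;
  const bool same = (stride == 1 && Ho == H && Wo == W);
  // dout rearranged to (Ho*Wo*N) x Cout
  arma::mat dout_cols((arma::uword)Ho * Wo * N, Cout);
  const double *dp = REAL(dout);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double *src = dp + (size_t)Ho * Wo * (co + (size_t)Cout * n);
      double *dst = dout_cols.colptr(co) + (arma::uword)Ho * Wo * n;
      for (int p = 0; p < Ho * Wo; ++p)
        dst[p] = src[p];
    }
  arma::mat Wm(const_cast<double *>(REAL(w)), K, Cout, false, true);
  NumericVector dw((R_xlen_t)K * Cout);
  NumericVector db(Cout);
  for (int co = 0; co < Cout; ++co)
    db[co] = arma::accu(dout_cols.col(co));
  NumericVector dx((R_xlen_t)H * W * C * N); // zero-initialized
  double *dxp = REAL(dx);
  if (same) {
    arma::mat colsT = im2colT_same(REAL(x), H, W, C, N, kh, kw, pad);
    arma::mat dW = colsT.t() * dout_cols;  // K x Cout, same layout as w
    std::copy(dW.memptr(), dW.memptr() + (size_t)K * Cout, REAL(dw));
    arma::mat dcolsT = dout_cols * Wm.t(); // (H*W*N) x K
    col2imT_same(dcolsT, dxp, H, W, C, N, kh, kw, pad);
    dw.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
    dx.attr("dim") = IntegerVector::create(H, W, C, N);
    return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
  }
  arma::mat cols = im2col(REAL(x), H, W, C, N, kh, kw, stride, pad, Ho, Wo);
  arma::mat dW = cols * dout_cols;        // K x Cout, same layout as w
  arma::mat dcols = Wm * dout_cols.t();   // K x (Ho*Wo*N)
  std::copy(dW.memptr(), dW.memptr() + (size_t)K * Cout, REAL(dw));
  dw.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        arma::uword col =
            (arma::uword)ho + (arma::uword)Ho * wo + (arma::uword)Ho * Wo * n;
        const double *cp = dcols.colptr(col);
        for (int ci = 0; ci < C; ++ci)
          for (int kj = 0; kj < kw; ++kj) {
            int wim = wo * stride + kj - pad;
            if (wim < 0 || wim >= W)
              continue;
            double *xp =
                dxp + (size_t)H * (wim + (size_t)W * (ci + (size_t)C * n));
            for (int ki = 0; ki < kh; ++ki) {
              int him = ho * stride + ki - pad;
              if (him < 0 || him >= H)
                continue;
              xp[him] += cp[ki + kh * kj + kh * kw * ci];
            }
          }
      }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// type: 0 = mean, 1 = max. Returns the pooled array plus, for max pooling,
// the 0-based linear argmax index into x (for the backward pass).
// [[Rcpp::export(rng = false)]]
List rfed_pool_fw(NumericVector x, int ksize, int stride, int pad, int type) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const int Ho = (H + 2 * pad - ksize) / stride + 1;
  const int Wo = (W + 2 * pad - ksize) / stride + 1;
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  IntegerVector amax(type == 1 ? (R_xlen_t)Ho * Wo * C * N : 0);
  const double *xp = REAL(x);
  double *op = REAL(out);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xc = xp + (size_t)H * W * (c + (size_t)C * n);
      const size_t xoff = (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = (type == 1) ? R_NegInf : 0.0;
          int cnt = 0, arg = -1;
          for (int kj = 0; kj < ksize; ++kj) {
            int wim = wo * stride + kj - pad;
            if (wim < 0 || wim >= W)
              continue;
            for (int ki = 0; ki < ksize; ++ki) {
              int him = ho * stride + ki - pad;
              if (him < 0 || him >= H)
                continue;
              double v = xc[him + (size_t)H * wim];
              ++cnt;
              if (type == 1) {
                if (v > acc) {
                  acc = v;
                  arg = him + H * wim;
                }
              } else
                acc += v;
            }
          }
          size_t oi = (size_t)ho + (size_t)Ho * wo +
                      (size_t)Ho * Wo * (c + (size_t)C * n);
          if (type == 1) {
            op[oi] = acc;
            amax[oi] = (int)(xoff + arg);
          } else
            op[oi] = cnt > 0 ? acc / cnt : 0.0;
        }
    }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export(rng = false)]]
NumericVector rfed_pool_bw(NumericVector dout, IntegerVector xdim,
                           IntegerVector argmax, int ksize, int stride,
                           int pad, int type) {
  int Ho, Wo, C, N;
  get_dims4(dout, Ho, Wo, C, N);
  const int H = xdim[0], W = xdim[1];
  NumericVector dx((R_xlen_t)H * W * C * N);
  double *dxp = REAL(dx);
  const double *dp = REAL(dout);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double *xc = dxp + (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          size_t oi = (size_t)ho + (size_t)Ho * wo +
                      (size_t)Ho * Wo * (c + (size_t)C * n);
          if (type == 1) {
            dxp[argmax[oi]] += dp[oi];
            continue;
          }
          int cnt = 0;
          for (int kj = 0; kj < ksize; ++kj) {
            int wim = wo * stride + kj - pad;
            if (wim < 0 || wim >= W)
              continue;
            for (int ki = 0; ki < ksize; ++ki) {
              int him = ho * stride + ki - pad;
              if (him >= 0 && him < H)
                ++cnt;
            }
          }
          if (cnt == 0)
            continue;
          double g = dp[oi] / cnt;
          for (int kj = 0; kj < ksize; ++kj) {
            int wim = wo * stride + kj - pad;
            if (wim < 0 || wim >= W)
              continue;
            for (int ki = 0; ki < ksize; ++ki) {
              int him = ho * stride + ki - pad;
              if (him < 0 || him >= H)
                continue;
              xc[him + (size_t)H * wim] += g;
            }
          }
        }
    }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// Zero the entries of a gradient where the forward activation was clipped
// by the ReLU (act <= 0).
// [[Rcpp::export(rng = false)]]
NumericVector rfed_relu_mask(NumericVector dout, NumericVector act) {
  NumericVector out(dout.size());
  const double *d = REAL(dout), *a = REAL(act);
  double *o = REAL(out);
  for (R_xlen_t i = 0; i < dout.size(); ++i)
    o[i] = a[i] > 0 ? d[i] : 0.0;
  out.attr("dim") = dout.attr("dim");
  return out;
}

// Backward of a global spatial mean: spread dz (N x C) over an
// (H, W, C, N) array, dividing by H*W.
// [[Rcpp::export(rng = false)]]
NumericVector rfed_global_mean_bw(NumericMatrix dz, int H, int W) {
  const int N = dz.nrow(), C = dz.ncol();
  NumericVector out((R_xlen_t)H * W * C * N);
  double *o = REAL(out);
  const double inv = 1.0 / (H * W);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double v = dz(n, c) * inv;
      double *dst = o + (size_t)H * W * (c + (size_t)C * n);
      for (int p = 0; p < H * W; ++p)
        dst[p] = v;
    }
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  return out;
}
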