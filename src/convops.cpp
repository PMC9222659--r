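#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// 2-D convolution primitives for batched feature stacks.
//
// Layout conventions (R column-major):
//   x : H x W x C x N    input activations
//   w : kh x kw x C x O  kernels
//   y : Ho x Wo x O x N  output, Ho = H + 2p - kh + 1 (stride 1, zero pad p)
//
// The im2col matrix has one row per output pixel (column-major over Ho, Wo)
// and one column per kernel element, ordered ki + kh*(kj + kw*c) so that a
// kernel array reshaped to (kh*kw*C) x O multiplies it directly.

static void im2col(const double *x, int H, int W, int C,
                   int kh, int kw, int p, int Ho, int Wo, arma::mat &out) {
  out.zeros();
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kh * (kj + kw * c);
        double *dst = out.colptr(col);
        for (int oj = 0; oj < Wo; ++oj) {
          const int iw = oj + kj - p;
          if (iw < 0 || iw >= W) continue;
          // valid output rows: 0 <= oi + ki - p < H
          int oi0 = std::max(0, p - ki);
          int oi1 = std::min(Ho - 1, H - 1 + p - ki);
          if (oi1 < oi0) continue;
          const double *src = xc + (size_t)W * 0 + (size_t)(oi0 + ki - p) + (size_t)H * iw;
          std::copy(src, src + (oi1 - oi0 + 1), dst + (size_t)Ho * oj + oi0);
        }
      }
    }
  }
}

// scatter-add transpose of im2col
static void col2im(const arma::mat &cols, int H, int W, int C,
                   int kh, int kw, int p, int Ho, int Wo, double *x) {
  for (int c = 0; c < C; ++c) {
    double *xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kh * (kj + kw * c);
        const double *src0 = cols.colptr(col);
        for (int oj = 0; oj < Wo; ++oj) {
          const int iw = oj + kj - p;
          if (iw < 0 || iw >= W) continue;
          int oi0 = std::max(0, p - ki);
          int oi1 = std::min(Ho - 1, H - 1 + p - ki);
          if (oi1 < oi0) continue;
          double *dst = xc + (size_t)(oi0 + ki - p) + (size_t)H * iw;
          const double *src = src0 + (size_t)Ho * oj + oi0;
          for (int i = 0; i <= oi1 - oi0; ++i) dst[i] += src[i];
        }
      }
    }
  }
}


static NumericVector alloc4(int d1, int d2, int d3, int d4) {
  NumericVector v((R_xlen_t)d1 * d2 * d3 * d4);
  v.attr("dim") = IntegerVector::create(d1, d2, d3, d4);
  return v;
}

static IntegerVector dims4(const NumericVector &a) {
  IntegerVector d = a.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array");
  return d;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b, int pad) {
  IntegerVector dx = dims4(x), dw = dims4(w);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], O = dw[3];
  if (dw[2] != C) stop("kernel input channels (%d) do not match input (%d)", (int)dw[2], C);
  if (b.size() != O) stop("bias length must equal output channels");
  const int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  if (Ho < 1 || Wo < 1) stop("kernel larger than padded input");

  NumericVector y = alloc4(Ho, Wo, O, N);
  arma::mat Wm(w.begin(), (size_t)kh * kw * C, O, false, true);
  const bool pointwise = (kh == 1 && kw == 1 && pad == 0);
  arma::mat cols;
  if (!pointwise) cols.set_size((size_t)Ho * Wo, (size_t)kh * kw * C);
  for (int n = 0; n < N; ++n) {
    arma::mat Yn(y.begin() + (size_t)Ho * Wo * O * n, (size_t)Ho * Wo, O, false, true);
    if (pointwise) {
      const arma::mat Xn(const_cast<double *>(x.begin()) + (size_t)H * W * C * n,
                         (size_t)H * W, C, false, true);
      Yn = Xn * Wm;
    } else {
      im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, pad, Ho, Wo, cols);
      Yn = cols * Wm;
    }
    for (int o = 0; o < O; ++o) Yn.col(o) += b[o];
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy, int pad, bool need_gx) {
  IntegerVector dx = dims4(x), dw = dims4(w), dg = dims4(gy);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], O = dw[3];
  const int Ho = dg[0], Wo = dg[1];
  if (dg[2] != O || dg[3] != N) stop("gradient dims inconsistent with kernel/batch");

  NumericVector gx = alloc4(H, W, C, N);
  NumericVector gw = alloc4(kh, kw, C, O);
  NumericVector gb(O);
  arma::mat Wm(w.begin(), (size_t)kh * kw * C, O, false, true);
  arma::mat Gw(gw.begin(), (size_t)kh * kw * C, O, false, true);
  arma::vec Gb(gb.begin(), O, false, true);
  const bool pointwise = (kh == 1 && kw == 1 && pad == 0);
  arma::mat cols;
  if (!pointwise) cols.set_size((size_t)Ho * Wo, (size_t)kh * kw * C);
  for (int n = 0; n < N; ++n) {
    arma::mat Gn(gy.begin() + (size_t)Ho * Wo * O * n, (size_t)Ho * Wo, O, false, true);
    Gb += arma::sum(Gn, 0).t();
    if (pointwise) {
      const arma::mat Xn(const_cast<double *>(x.begin()) + (size_t)H * W * C * n,
                         (size_t)H * W, C, false, true);
      Gw += Xn.t() * Gn;
      if (need_gx) {
        arma::mat Gxn(gx.begin() + (size_t)H * W * C * n, (size_t)H * W, C, false, true);
        Gxn = Gn * Wm.t();
      }
    } else {
      im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, pad, Ho, Wo, cols);
      Gw += cols.t() * Gn;
      if (need_gx) {
        arma::mat Gcols = Gn * Wm.t();
        col2im(Gcols, H, W, C, kh, kw, pad, Ho, Wo, gx.begin() + (size_t)H * W * C * n);
      }
    }
  }
  return List::create(Named("gx") = gx, Named("gw") = gw, Named("gb") = gb);
}
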