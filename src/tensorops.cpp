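#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Pointwise / reshaping kernels for the autodiff tape. These exist to keep
// per-step R allocation off the training hot path; semantics are plain.

static NumericVector alloc_like(const NumericVector &x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export(name = ".relu_fwd")]]
NumericVector relu_fwd(NumericVector x) {
  NumericVector y = alloc_like(x);
  const double *px = x.begin();
  double *py = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) py[i] = px[i] > 0 ? px[i] : 0;
  return y;
}

// [[Rcpp::export(name = ".relu_bwd")]]
NumericVector relu_bwd(NumericVector y, NumericVector g) {
  NumericVector gx = alloc_like(g);
  const double *py = y.begin(), *pg = g.begin();
  double *po = gx.begin();
  for (R_xlen_t i = 0; i < g.size(); ++i) po[i] = py[i] > 0 ? pg[i] : 0;
  return gx;
}

// in-place a += b (only ever applied to gradient buffers this package owns)
// [[Rcpp::export(name = ".add_into")]]
void add_into(NumericVector a, NumericVector b) {
  if (a.size() != b.size()) stop("size mismatch in gradient accumulation");
  double *pa = a.begin();
  const double *pb = b.begin();
  for (R_xlen_t i = 0; i < a.size(); ++i) pa[i] += pb[i];
}

static IntegerVector dim4(const NumericVector &a) {
  IntegerVector d = a.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array");
  return d;
}

// concatenate 4-d stacks along the channel dimension
// [[Rcpp::export(name = ".concat_c")]]
NumericVector concat_c(List xs) {
  const int k = xs.size();
  std::vector<NumericVector> v;
  int ctot = 0, H = 0, W = 0, N = 0;
  for (int i = 0; i < k; ++i) {
    NumericVector xi = xs[i];
    IntegerVector d = dim4(xi);
    if (i == 0) { H = d[0]; W = d[1]; N = d[3]; }
    else if (d[0] != H || d[1] != W || d[3] != N) stop("stacks differ in shape");
    ctot += d[2];
    v.push_back(xi);
  }
  NumericVector out((R_xlen_t)H * W * ctot * N);
  out.attr("dim") = IntegerVector::create(H, W, ctot, N);
  const size_t hw = (size_t)H * W;
  double *po = out.begin();
  for (int n = 0; n < N; ++n) {
    size_t at = (size_t)hw * ctot * n;
    for (int i = 0; i < k; ++i) {
      const int ci = dim4(v[i])[2];
      const double *src = v[i].begin() + hw * ci * n;
      std::copy(src, src + hw * ci, po + at);
      at += hw * ci;
    }
  }
  return out;
}

// split a channel-concatenated gradient back into chunks of sizes `cs`
// [[Rcpp::export(name = ".split_c")]]
List split_c(NumericVector g, IntegerVector cs) {
  IntegerVector d = dim4(g);
  const int H = d[0], W = d[1], N = d[3];
  const size_t hw = (size_t)H * W;
  const int ctot = d[2];
  List out(cs.size());
  int at0 = 0;
  for (int i = 0; i < cs.size(); ++i) {
    const int ci = cs[i];
    NumericVector gi((R_xlen_t)hw * ci * N);
    gi.attr("dim") = IntegerVector::create(H, W, ci, N);
    double *pg = gi.begin();
    for (int n = 0; n < N; ++n) {
      const double *src = g.begin() + hw * ((size_t)ctot * n + at0);
      std::copy(src, src + hw * ci, pg + hw * ci * n);
    }
    at0 += ci;
    out[i] = gi;
  }
  if (at0 != ctot) stop("channel sizes do not sum to the stack's channels");
  return out;
}

// x (H,W,C,N) scaled per channel by s (1,1,C,N)
// [[Rcpp::export(name = ".scalec_fwd")]]
NumericVector scalec_fwd(NumericVector x, NumericVector s) {
  IntegerVector d = dim4(x);
  const size_t hw = (size_t)d[0] * d[1];
  const R_xlen_t cn = (R_xlen_t)d[2] * d[3];
  NumericVector y = alloc_like(x);
  const double *px = x.begin(), *ps = s.begin();
  double *py = y.begin();
  for (R_xlen_t j = 0; j < cn; ++j) {
    const double sv = ps[j];
    const double *xi = px + hw * j;
    double *yi = py + hw * j;
    for (size_t i = 0; i < hw; ++i) yi[i] = xi[i] * sv;
  }
  return y;
}

// [[Rcpp::export(name = ".scalec_bwd")]]
List scalec_bwd(NumericVector x, NumericVector s, NumericVector g) {
  IntegerVector d = dim4(x);
  const size_t hw = (size_t)d[0] * d[1];
  const R_xlen_t cn = (R_xlen_t)d[2] * d[3];
  NumericVector gx = alloc_like(x);
  NumericVector gs(cn);
  gs.attr("dim") = IntegerVector::create(1, 1, d[2], d[3]);
  const double *px = x.begin(), *ps = s.begin(), *pg = g.begin();
  double *pgx = gx.begin(), *pgs = gs.begin();
  for (R_xlen_t j = 0; j < cn; ++j) {
    const double sv = ps[j];
    double acc = 0;
    const double *xi = px + hw * j, *gi = pg + hw * j;
    double *oi = pgx + hw * j;
    for (size_t i = 0; i < hw; ++i) {
      oi[i] = gi[i] * sv;
      acc += gi[i] * xi[i];
    }
    pgs[j] = acc;
  }
  return List::create(Named("gx") = gx, Named("gs") = gs);
}

// x (H,W,C,N) scaled per pixel by m (H,W,1,N), shared over channels
// [[Rcpp::export(name = ".scalep_fwd")]]
NumericVector scalep_fwd(NumericVector x, NumericVector m) {
  IntegerVector d = dim4(x);
  const size_t hw = (size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector y = alloc_like(x);
  const double *px = x.begin(), *pm = m.begin();
  double *py = y.begin();
  for (int n = 0; n < N; ++n) {
    const double *mn = pm + hw * n;
    for (int c = 0; c < C; ++c) {
      const double *xi = px + hw * ((size_t)C * n + c);
      double *yi = py + hw * ((size_t)C * n + c);
      for (size_t i = 0; i < hw; ++i) yi[i] = xi[i] * mn[i];
    }
  }
  return y;
}

// [[Rcpp::export(name = ".scalep_bwd")]]
List scalep_bwd(NumericVector x, NumericVector m, NumericVector g) {
  IntegerVector d = dim4(x);
  const size_t hw = (size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector gx = alloc_like(x);
  NumericVector gm((R_xlen_t)hw * N);
  gm.attr("dim") = IntegerVector::create(d[0], d[1], 1, N);
  const double *px = x.begin(), *pm = m.begin(), *pg = g.begin();
  double *pgx = gx.begin(), *pgm = gm.begin();
  std::fill(pgm, pgm + hw * N, 0.0);
  for (int n = 0; n < N; ++n) {
    const double *mn = pm + hw * n;
    double *gmn = pgm + hw * n;
    for (int c = 0; c < C; ++c) {
      const size_t off = hw * ((size_t)C * n + c);
      const double *xi = px + off, *gi = pg + off;
      double *oi = pgx + off;
      for (size_t i = 0; i < hw; ++i) {
        oi[i] = gi[i] * mn[i];
        gmn[i] += gi[i] * xi[i];
      }
    }
  }
  return List::create(Named("gx") = gx, Named("gm") = gm);
}
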