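// Low-level neural-network kernels: 2D convolution (same padding) with
// im2col + gemm, 2x2 max pooling, and nearest-neighbour x2 upsampling,
// each with its backward pass. Tensors are R arrays laid out (H, W, C, B)
// in column-major order; weights are (k, k, Cin, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::uword idx4(int i, int j, int c, int b,
                               int H, int W, int C) {
  return (arma::uword)i + (arma::uword)H * ((arma::uword)j +
         (arma::uword)W * ((arma::uword)c + (arma::uword)C * (arma::uword)b));
}

// shifted-block ranges for kernel offset o = k_index - pad: output rows
// [r0, r1] read source rows [r0 + o, r1 + o], clipped to the grid
static inline bool shift_range(int n, int o, int& r0, int& r1) {
  r0 = o < 0 ? -o : 0;
  r1 = (n - 1) - (o > 0 ? o : 0);
  return r0 <= r1;
}

static void im2col_one(const double* x, int H, int W, int C, int b,
                       int k, int pad, arma::mat& M) {
  // M is (H*W) x (k*k*C); output pixel p = i + H*j; built as 9*C shifted
  // H x W block copies (zero padding at the borders)
  for (int c = 0; c < C; ++c) {
    const arma::mat Xc(const_cast<double*>(x + idx4(0, 0, c, b, H, W, C)),
                       H, W, false, true);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int q = ki + k * kj + k * k * c;
        arma::mat Mq(M.colptr(q), H, W, false, true);
        const int oi = ki - pad, oj = kj - pad;
        int ri0, ri1, rj0, rj1;
        const bool ok = shift_range(H, oi, ri0, ri1) &&
                        shift_range(W, oj, rj0, rj1);
        if (oi != 0 || oj != 0) Mq.zeros();
        if (ok) {
          Mq.submat(ri0, rj0, ri1, rj1) =
            Xc.submat(ri0 + oi, rj0 + oj, ri1 + oi, rj1 + oj);
        }
      }
    }
  }
}

static void col2im_one(const arma::mat& M, int H, int W, int C, int b,
                       int k, int pad, double* gx) {
  for (int c = 0; c < C; ++c) {
    arma::mat Gc(gx + idx4(0, 0, c, b, H, W, C), H, W, false, true);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int q = ki + k * kj + k * k * c;
        const arma::mat Mq(const_cast<double*>(M.colptr(q)), H, W, false, true);
        const int oi = ki - pad, oj = kj - pad;
        int ri0, ri1, rj0, rj1;
        if (shift_range(H, oi, ri0, ri1) && shift_range(W, oj, rj0, rj1)) {
          Gc.submat(ri0 + oi, rj0 + oj, ri1 + oi, rj1 + oj) +=
            Mq.submat(ri0, rj0, ri1, rj1);
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw_cpp(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], B = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[1] != k || wd[2] != Cin) stop("conv2d: weight shape mismatch");
  const int pad = (k - 1) / 2;
  const int HW = H * W;

  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)HW * Cout * B));
  y.attr("dim") = IntegerVector::create(H, W, Cout, B);

  arma::mat Wmat(const_cast<double*>(w.begin()), (arma::uword)k * k * Cin,
                 Cout, false, true);
  arma::mat M(HW, (arma::uword)k * k * Cin);
  for (int bb = 0; bb < B; ++bb) {
    im2col_one(x.begin(), H, W, Cin, bb, k, pad, M);
    arma::mat Yb(y.begin() + (R_xlen_t)HW * Cout * bb, HW, Cout, false, true);
    Yb = M * Wmat;
    for (int o = 0; o < Cout; ++o) Yb.col(o) += b[o];
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bw_cpp(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], B = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int pad = (k - 1) / 2;
  const int HW = H * W;

  NumericVector gx(Rf_allocVector(REALSXP, (R_xlen_t)HW * Cin * B));
  std::fill(gx.begin(), gx.end(), 0.0);
  gx.attr("dim") = IntegerVector::create(H, W, Cin, B);
  NumericVector gw(Rf_allocVector(REALSXP, (R_xlen_t)k * k * Cin * Cout));
  std::fill(gw.begin(), gw.end(), 0.0);
  gw.attr("dim") = wd;
  NumericVector gb(Cout);

  arma::mat Wmat(const_cast<double*>(w.begin()), (arma::uword)k * k * Cin,
                 Cout, false, true);
  arma::mat Gw(gw.begin(), (arma::uword)k * k * Cin, Cout, false, true);
  arma::mat M(HW, (arma::uword)k * k * Cin);
  for (int bb = 0; bb < B; ++bb) {
    arma::mat Gyb(const_cast<double*>(gy.begin()) + (R_xlen_t)HW * Cout * bb,
                  HW, Cout, false, true);
    im2col_one(x.begin(), H, W, Cin, bb, k, pad, M);
    Gw += M.t() * Gyb;
    for (int o = 0; o < Cout; ++o) gb[o] += arma::accu(Gyb.col(o));
    arma::mat GM = Gyb * Wmat.t();
    col2im_one(GM, H, W, Cin, bb, k, pad, gx.begin());
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List maxpool2_fw_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * C * B));
  IntegerVector am(Rf_allocVector(INTSXP, (R_xlen_t)Ho * Wo * C * B));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  am.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  const double* xp = x.begin();
  R_xlen_t p = 0;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i, ++p) {
          const arma::uword base = idx4(2 * i, 2 * j, c, b, H, W, C);
          double v0 = xp[base], v1 = xp[base + 1];
          double v2 = xp[base + H], v3 = xp[base + H + 1];
          int a = 0; double v = v0;
          if (v1 > v) { v = v1; a = 1; }
          if (v2 > v) { v = v2; a = 2; }
          if (v3 > v) { v = v3; a = 3; }
          y[p] = v; am[p] = a;
        }
  return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export]]
NumericVector maxpool2_bw_cpp(NumericVector gy, IntegerVector am,
                              int H, int W) {
  IntegerVector yd = gy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], B = yd[3];
  NumericVector gx(Rf_allocVector(REALSXP, (R_xlen_t)H * W * C * B));
  std::fill(gx.begin(), gx.end(), 0.0);
  gx.attr("dim") = IntegerVector::create(H, W, C, B);
  R_xlen_t p = 0;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i, ++p) {
          const int a = am[p];
          const int di = a & 1, dj = a >> 1;
          gx[idx4(2 * i + di, 2 * j + dj, c, b, H, W, C)] += gy[p];
        }
  return gx;
}

// [[Rcpp::export]]
NumericVector upsample2_fw_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * C * B));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  R_xlen_t p = 0;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i, ++p)
          y[p] = x[idx4(i / 2, j / 2, c, b, H, W, C)];
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_bw_cpp(NumericVector gy, int H, int W) {
  IntegerVector yd = gy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], B = yd[3];
  (void)Ho; (void)Wo;
  NumericVector gx(Rf_allocVector(REALSXP, (R_xlen_t)H * W * C * B));
  std::fill(gx.begin(), gx.end(), 0.0);
  gx.attr("dim") = IntegerVector::create(H, W, C, B);
  R_xlen_t p = 0;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < 2 * W; ++j)
        for (int i = 0; i < 2 * H; ++i, ++p)
          gx[idx4(i / 2, j / 2, c, b, H, W, C)] += gy[p];
  return gx;
}
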