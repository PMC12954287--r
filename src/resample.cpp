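// Grid resampling of 3D volumes on separable target coordinates.
// Coordinates are continuous 0-based voxel indices of the source grid
// (cell-centre convention); sampling clamps at the borders.
// method 0 = trilinear, 1 = tricubic Catmull-Rom (third-order spline).

#include <Rcpp.h>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Catmull-Rom weights for fractional offset t in [0,1)
static inline void cr_weights(double t, double wgt[4]) {
  const double t2 = t * t, t3 = t2 * t;
  wgt[0] = 0.5 * (-t3 + 2.0 * t2 - t);
  wgt[1] = 0.5 * (3.0 * t3 - 5.0 * t2 + 2.0);
  wgt[2] = 0.5 * (-3.0 * t3 + 4.0 * t2 + t);
  wgt[3] = 0.5 * (t3 - t2);
}

// [[Rcpp::export]]
NumericVector resample_grid_cpp(NumericVector x,
                                NumericVector c1, NumericVector c2,
                                NumericVector c3, int method) {
  IntegerVector xd = x.attr("dim");
  const int n1 = xd[0], n2 = xd[1], n3 = xd[2];
  const int m1 = c1.size(), m2 = c2.size(), m3 = c3.size();
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)m1 * m2 * m3));
  y.attr("dim") = IntegerVector::create(m1, m2, m3);
  const double* xp = x.begin();

  // per-axis precomputed support indices and weights
  const int taps = (method == 1) ? 4 : 2;
  std::vector<int> i1(m1 * taps), i2(m2 * taps), i3(m3 * taps);
  std::vector<double> w1(m1 * taps), w2(m2 * taps), w3(m3 * taps);

  auto prep = [&](const NumericVector& c, int n, std::vector<int>& idx,
                  std::vector<double>& wv) {
    const int m = c.size();
    for (int q = 0; q < m; ++q) {
      double cc = c[q];
      if (cc < 0.0) cc = 0.0;
      if (cc > n - 1.0) cc = n - 1.0;
      const int f = (int)std::floor(cc);
      const double t = cc - f;
      if (method == 1) {
        double wgt[4];
        cr_weights(t, wgt);
        for (int a = 0; a < 4; ++a) {
          idx[q * 4 + a] = clampi(f - 1 + a, 0, n - 1);
          wv[q * 4 + a] = wgt[a];
        }
      } else {
        idx[q * 2] = clampi(f, 0, n - 1);
        idx[q * 2 + 1] = clampi(f + 1, 0, n - 1);
        wv[q * 2] = 1.0 - t;
        wv[q * 2 + 1] = t;
      }
    }
  };
  prep(c1, n1, i1, w1);
  prep(c2, n2, i2, w2);
  prep(c3, n3, i3, w3);

  R_xlen_t p = 0;
  for (int q3 = 0; q3 < m3; ++q3)
    for (int q2 = 0; q2 < m2; ++q2)
      for (int q1 = 0; q1 < m1; ++q1, ++p) {
        double acc = 0.0;
        for (int a3 = 0; a3 < taps; ++a3) {
          const double wz = w3[q3 * taps + a3];
          if (wz == 0.0) continue;
          const R_xlen_t off3 = (R_xlen_t)i3[q3 * taps + a3] * n1 * n2;
          for (int a2 = 0; a2 < taps; ++a2) {
            const double wyz = wz * w2[q2 * taps + a2];
            if (wyz == 0.0) continue;
            const R_xlen_t off2 = off3 + (R_xlen_t)i2[q2 * taps + a2] * n1;
            double row = 0.0;
            for (int a1 = 0; a1 < taps; ++a1)
              row += w1[q1 * taps + a1] * xp[off2 + i1[q1 * taps + a1]];
            acc += wyz * row;
          }
        }
        y[p] = acc;
      }
  return y;
}

// Symmetric average surface distance helpers: mean over rows of A of the
// nearest Euclidean distance to any row of B. Points are physical mm.
// [[Rcpp::export]]
double mean_nn_dist_cpp(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  double total = 0.0;
  for (int i = 0; i < na; ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    total += std::sqrt(best);
  }
  return total / na;
}
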