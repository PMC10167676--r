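// Block reshape kernels for kernel-2/stride-2 convolutions.
//
// Feature batches are column-major arrays (x, y, z, channel, n). A stride-2
// kernel-2 convolution touches disjoint 2x2x2 blocks, so im2col is a pure
// re-indexing: rows are ordered (ox fastest, oy, oz, n) and columns
// (kx fastest, ky, kz, channel). These loops replace generalized aperm()
// calls, which dominate the runtime otherwise.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col_k2(NumericVector a, IntegerVector d) {
  const int d1 = d[0], d2 = d[1], d3 = d[2], C = d[3], N = d[4];
  const int o1 = d1 / 2, o2 = d2 / 2, o3 = d3 / 2;
  const R_xlen_t nrow = (R_xlen_t)o1 * o2 * o3 * N;
  NumericMatrix m((int)nrow, 8 * C);
  const double *src = a.begin();
  double *dst = m.begin();
  const R_xlen_t s2 = d1, s3 = (R_xlen_t)d1 * d2, s4 = s3 * d3, s5 = s4 * C;
  for (int c = 0; c < C; ++c) {
    for (int kz = 0; kz < 2; ++kz)
      for (int ky = 0; ky < 2; ++ky)
        for (int kx = 0; kx < 2; ++kx) {
          const int q = kx + 2 * (ky + 2 * (kz + 2 * c));
          double *col = dst + (R_xlen_t)q * nrow;
          R_xlen_t r = 0;
          for (int nn = 0; nn < N; ++nn) {
            const double *base_n = src + (R_xlen_t)nn * s5 + (R_xlen_t)c * s4;
            for (int oz = 0; oz < o3; ++oz) {
              const double *base_z = base_n + (R_xlen_t)(2 * oz + kz) * s3;
              for (int oy = 0; oy < o2; ++oy) {
                const double *base_y = base_z + (R_xlen_t)(2 * oy + ky) * s2 + kx;
                for (int ox = 0; ox < o1; ++ox)
                  col[r++] = base_y[2 * ox];
              }
            }
          }
        }
  }
  return m;
}

// [[Rcpp::export]]
NumericVector cpp_col2im_k2(NumericMatrix m, IntegerVector d) {
  const int d1 = d[0], d2 = d[1], d3 = d[2], C = d[3], N = d[4];
  const int o1 = d1 / 2, o2 = d2 / 2, o3 = d3 / 2;
  NumericVector out((R_xlen_t)d1 * d2 * d3 * C * N);  // zero-filled
  const R_xlen_t nrow = (R_xlen_t)o1 * o2 * o3 * N;
  const double *src = m.begin();
  double *dst = out.begin();
  const R_xlen_t s2 = d1, s3 = (R_xlen_t)d1 * d2, s4 = s3 * d3, s5 = s4 * C;
  for (int c = 0; c < C; ++c) {
    for (int kz = 0; kz < 2; ++kz)
      for (int ky = 0; ky < 2; ++ky)
        for (int kx = 0; kx < 2; ++kx) {
          const int q = kx + 2 * (ky + 2 * (kz + 2 * c));
          const double *col = src + (R_xlen_t)q * nrow;
          R_xlen_t r = 0;
          for (int nn = 0; nn < N; ++nn) {
            double *base_n = dst + (R_xlen_t)nn * s5 + (R_xlen_t)c * s4;
            for (int oz = 0; oz < o3; ++oz) {
              double *base_z = base_n + (R_xlen_t)(2 * oz + kz) * s3;
              for (int oy = 0; oy < o2; ++oy) {
                double *base_y = base_z + (R_xlen_t)(2 * oy + ky) * s2 + kx;
                for (int ox = 0; ox < o1; ++ox)
                  base_y[2 * ox] = col[r++];
              }
            }
          }
        }
  }
  out.attr("dim") = d;
  return out;
}

// rows (ox,oy,oz,n ordering) x C  ->  array (o1,o2,o3,C,N)
// [[Rcpp::export]]
NumericVector cpp_rows_to_feat(NumericMatrix m, IntegerVector o, int N) {
  const int o1 = o[0], o2 = o[1], o3 = o[2];
  const int C = m.ncol();
  const R_xlen_t sp = (R_xlen_t)o1 * o2 * o3;
  NumericVector out(sp * C * N);
  const double *src = m.begin();
  double *dst = out.begin();
  for (int c = 0; c < C; ++c) {
    const double *col = src + (R_xlen_t)c * sp * N;
    for (int nn = 0; nn < N; ++nn) {
      double *base = dst + ((R_xlen_t)nn * C + c) * sp;
      const double *row = col + (R_xlen_t)nn * sp;
      for (R_xlen_t i = 0; i < sp; ++i) base[i] = row[i];
    }
  }
  out.attr("dim") = IntegerVector::create(o1, o2, o3, C, N);
  return out;
}

// array (d1,d2,d3,C,N) -> rows (x,y,z,n ordering) x C
// [[Rcpp::export]]
NumericMatrix cpp_feat_to_rows(NumericVector a, IntegerVector d) {
  const int C = d[3], N = d[4];
  const R_xlen_t sp = (R_xlen_t)d[0] * d[1] * d[2];
  NumericMatrix m((int)(sp * N), C);
  const double *src = a.begin();
  double *dst = m.begin();
  for (int c = 0; c < C; ++c) {
    double *col = dst + (R_xlen_t)c * sp * N;
    for (int nn = 0; nn < N; ++nn) {
      const double *base = src + ((R_xlen_t)nn * C + c) * sp;
      double *row = col + (R_xlen_t)nn * sp;
      for (R_xlen_t i = 0; i < sp; ++i) row[i] = base[i];
    }
  }
  return m;
}

// transposed-conv expansion: rows ((x,y,z,n) order) x (8*C) -> (2d1,2d2,2d3,C,N)
// [[Rcpp::export]]
NumericVector cpp_expand_k2(NumericMatrix m, IntegerVector d, int C, int N) {
  const int d1 = d[0], d2 = d[1], d3 = d[2];
  const int e1 = 2 * d1, e2 = 2 * d2, e3 = 2 * d3;
  const R_xlen_t nrow = (R_xlen_t)d1 * d2 * d3 * N;
  NumericVector out((R_xlen_t)e1 * e2 * e3 * C * N);
  const double *src = m.begin();
  double *dst = out.begin();
  const R_xlen_t t2 = e1, t3 = (R_xlen_t)e1 * e2, t4 = t3 * e3, t5 = t4 * C;
  for (int c = 0; c < C; ++c) {
    for (int kz = 0; kz < 2; ++kz)
      for (int ky = 0; ky < 2; ++ky)
        for (int kx = 0; kx < 2; ++kx) {
          const int q = kx + 2 * (ky + 2 * (kz + 2 * c));
          const double *col = src + (R_xlen_t)q * nrow;
          R_xlen_t r = 0;
          for (int nn = 0; nn < N; ++nn) {
            double *base_n = dst + (R_xlen_t)nn * t5 + (R_xlen_t)c * t4;
            for (int z = 0; z < d3; ++z) {
              double *base_z = base_n + (R_xlen_t)(2 * z + kz) * t3;
              for (int y = 0; y < d2; ++y) {
                double *base_y = base_z + (R_xlen_t)(2 * y + ky) * t2 + kx;
                for (int x = 0; x < d1; ++x)
                  base_y[2 * x] = col[r++];
              }
            }
          }
        }
  }
  out.attr("dim") = IntegerVector::create(e1, e2, e3, C, N);
  return out;
}

// inverse of cpp_expand_k2 (gather)
// [[Rcpp::export]]
NumericMatrix cpp_collapse_k2(NumericVector a, IntegerVector d, int C, int N) {
  const int d1 = d[0], d2 = d[1], d3 = d[2];
  const int e1 = 2 * d1, e2 = 2 * d2, e3 = 2 * d3;
  const R_xlen_t nrow = (R_xlen_t)d1 * d2 * d3 * N;
  NumericMatrix m((int)nrow, 8 * C);
  const double *src = a.begin();
  double *dst = m.begin();
  const R_xlen_t t2 = e1, t3 = (R_xlen_t)e1 * e2, t4 = t3 * e3, t5 = t4 * C;
  for (int c = 0; c < C; ++c) {
    for (int kz = 0; kz < 2; ++kz)
      for (int ky = 0; ky < 2; ++ky)
        for (int kx = 0; kx < 2; ++kx) {
          const int q = kx + 2 * (ky + 2 * (kz + 2 * c));
          double *col = dst + (R_xlen_t)q * nrow;
          R_xlen_t r = 0;
          for (int nn = 0; nn < N; ++nn) {
            const double *base_n = src + (R_xlen_t)nn * t5 + (R_xlen_t)c * t4;
            for (int z = 0; z < d3; ++z) {
              const double *base_z = base_n + (R_xlen_t)(2 * z + kz) * t3;
              for (int y = 0; y < d2; ++y) {
                const double *base_y = base_z + (R_xlen_t)(2 * y + ky) * t2 + kx;
                for (int x = 0; x < d1; ++x)
                  col[r++] = base_y[2 * x];
              }
            }
          }
        }
  }
  return m;
}
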