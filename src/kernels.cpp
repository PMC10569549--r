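#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Arrays are stored column-major with dims (d1, d2, d3) = (z, y, x);
// linear index = i + j*d1 + k*d1*d2 (0-based).

static inline int refl(int i, int n) {
  // reflect padding with edge duplication: (c b a | a b c)
  if (i < 0) return -i - 1;
  if (i >= n) return 2 * n - 1 - i;
  return i;
}

// [[Rcpp::export(name = ".mean3_cpp")]]
NumericVector mean3_cpp(NumericVector x, IntegerVector dim) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  NumericVector out(x.size());
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        double s = 0.0;
        for (int ok = -1; ok <= 1; ++ok) {
          const int kk = refl(k + ok, d3);
          for (int oj = -1; oj <= 1; ++oj) {
            const int jj = refl(j + oj, d2);
            const int base = jj * d1 + kk * d1 * d2;
            for (int oi = -1; oi <= 1; ++oi)
              s += x[refl(i + oi, d1) + base];
          }
        }
        out[i + j * d1 + k * d1 * d2] = s / 27.0;
      }
  return out;
}

// 26-connected component labelling of a binary mask.
// Returns integer labels 0 (background), 1..K; attribute "sizes" = voxels per
// component, ordered by label id.
// [[Rcpp::export(name = ".cc26_cpp")]]
IntegerVector cc26_cpp(IntegerVector mask, IntegerVector dim) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = mask.size();
  IntegerVector lab(n, 0);
  std::vector<int> sizes;
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    int count = 0;
    stack.clear();
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      const R_xlen_t v = stack.back();
      stack.pop_back();
      ++count;
      const int i = v % d1, j = (v / d1) % d2, k = v / (d1 * d2);
      for (int ok = -1; ok <= 1; ++ok) {
        const int kk = k + ok;
        if (kk < 0 || kk >= d3) continue;
        for (int oj = -1; oj <= 1; ++oj) {
          const int jj = j + oj;
          if (jj < 0 || jj >= d2) continue;
          for (int oi = -1; oi <= 1; ++oi) {
            const int ii = i + oi;
            if (ii < 0 || ii >= d1) continue;
            const R_xlen_t w = ii + (R_xlen_t)jj * d1 + (R_xlen_t)kk * d1 * d2;
            if (mask[w] != 0 && lab[w] == 0) {
              lab[w] = next;
              stack.push_back(w);
            }
          }
        }
      }
    }
    sizes.push_back(count);
  }
  lab.attr("sizes") = wrap(sizes);
  return lab;
}

// Surface voxels of one label under the 6-connectivity boundary test:
// a voxel carries the label and at least one face neighbour does not
// (voxels on the array border count as surface).
// [[Rcpp::export(name = ".surface6_cpp")]]
LogicalVector surface6_cpp(IntegerVector lab, IntegerVector dim, int label) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  LogicalVector out(lab.size(), false);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        const R_xlen_t v = i + (R_xlen_t)j * d1 + (R_xlen_t)k * d1 * d2;
        if (lab[v] != label) continue;
        bool surf = i == 0 || i == d1 - 1 || j == 0 || j == d2 - 1 ||
                    k == 0 || k == d3 - 1;
        if (!surf) {
          surf = lab[v - 1] != label || lab[v + 1] != label ||
                 lab[v - d1] != label || lab[v + d1] != label ||
                 lab[v - (R_xlen_t)d1 * d2] != label ||
                 lab[v + (R_xlen_t)d1 * d2] != label;
        }
        out[v] = surf;
      }
  return out;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher) applied in place
// along a strided line.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Exact 3D squared Euclidean distance transform to the set of feature voxels
// (feature != 0), in voxel units.
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(LogicalVector feature, IntegerVector dim) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  // large finite sentinel (> any attainable squared distance) keeps the
  // parabola intersections well-defined on feature-free lines
  const double BIG = (double)d1 * d1 + (double)d2 * d2 + (double)d3 * d3 + 1.0;
  NumericVector g(feature.size());
  for (R_xlen_t i = 0; i < feature.size(); ++i) g[i] = feature[i] ? 0.0 : BIG;
  const int nmax = std::max(d1, std::max(d2, d3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // axis 1
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j) {
      const R_xlen_t base = (R_xlen_t)j * d1 + (R_xlen_t)k * d1 * d2;
      for (int i = 0; i < d1; ++i) f[i] = g[base + i];
      dt1d(f, d, v, z, d1);
      for (int i = 0; i < d1; ++i) g[base + i] = d[i];
    }
  // axis 2
  for (int k = 0; k < d3; ++k)
    for (int i = 0; i < d1; ++i) {
      const R_xlen_t base = i + (R_xlen_t)k * d1 * d2;
      for (int j = 0; j < d2; ++j) f[j] = g[base + (R_xlen_t)j * d1];
      dt1d(f, d, v, z, d2);
      for (int j = 0; j < d2; ++j) g[base + (R_xlen_t)j * d1] = d[j];
    }
  // axis 3
  for (int j = 0; j < d2; ++j)
    for (int i = 0; i < d1; ++i) {
      const R_xlen_t base = i + (R_xlen_t)j * d1;
      for (int k = 0; k < d3; ++k) f[k] = g[base + (R_xlen_t)k * d1 * d2];
      dt1d(f, d, v, z, d3);
      for (int k = 0; k < d3; ++k) g[base + (R_xlen_t)k * d1 * d2] = d[k];
    }
  return g;
}

// im2col for a 3x3x3 neighbourhood with zero padding. X is (batch*N) x C
// (voxels of each sample contiguous, column-major (z,y,x)); the result is
// (batch*N) x (27*C) with offset-major column blocks, enabling the whole
// convolution as a single GEMM.
// [[Rcpp::export(name = ".im2col_cpp")]]
NumericMatrix im2col_cpp(NumericMatrix X, IntegerVector dim, int batch) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const int N = d1 * d2 * d3;
  const int C = X.ncol();
  const R_xlen_t rows = (R_xlen_t)batch * N;
  NumericMatrix out(no_init(rows, 27 * C));
  const double *x = REAL(X);
  double *o_ = REAL(out);
  int oidx = 0;
  for (int o3 = -1; o3 <= 1; ++o3)
    for (int o2 = -1; o2 <= 1; ++o2)
      for (int o1 = -1; o1 <= 1; ++o1, ++oidx) {
        for (int c = 0; c < C; ++c) {
          const double *src = x + (R_xlen_t)c * rows;
          double *dst = o_ + ((R_xlen_t)(oidx * C + c)) * rows;
          for (int b = 0; b < batch; ++b) {
            const R_xlen_t base = (R_xlen_t)b * N;
            for (int k = 0; k < d3; ++k) {
              const int kk = k + o3;
              const bool kin = kk >= 0 && kk < d3;
              for (int j = 0; j < d2; ++j) {
                const int jj = j + o2;
                const bool jin = kin && jj >= 0 && jj < d2;
                double *drow = dst + base + (R_xlen_t)j * d1 +
                               (R_xlen_t)k * d1 * d2;
                if (!jin) {
                  for (int i = 0; i < d1; ++i) drow[i] = 0.0;
                  continue;
                }
                const double *srow = src + base + (R_xlen_t)jj * d1 +
                                     (R_xlen_t)kk * d1 * d2 + o1;
                const int i0 = (o1 < 0) ? 1 : 0;
                const int i1 = (o1 > 0) ? d1 - 1 : d1;
                if (o1 < 0) drow[0] = 0.0;
                if (o1 > 0) drow[d1 - 1] = 0.0;
                for (int i = i0; i < i1; ++i) drow[i] = srow[i];
              }
            }
          }
        }
      }
  return out;
}

// adjoint of im2col: dX(v, c) = sum_o dcol(shift_{-o}(v), (o-1)*C + c)
// [[Rcpp::export(name = ".col2im_cpp")]]
NumericMatrix col2im_cpp(NumericMatrix dcol, IntegerVector dim, int batch,
                         int C) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const int N = d1 * d2 * d3;
  const R_xlen_t rows = (R_xlen_t)batch * N;
  NumericMatrix out(rows, C);
  const double *dc = REAL(dcol);
  double *o_ = REAL(out);
  int oidx = 0;
  for (int o3 = -1; o3 <= 1; ++o3)
    for (int o2 = -1; o2 <= 1; ++o2)
      for (int o1 = -1; o1 <= 1; ++o1, ++oidx) {
        // gather with the negated offset
        const int n1 = -o1, n2 = -o2, n3 = -o3;
        for (int c = 0; c < C; ++c) {
          const double *src = dc + ((R_xlen_t)(oidx * C + c)) * rows;
          double *dst = o_ + (R_xlen_t)c * rows;
          for (int b = 0; b < batch; ++b) {
            const R_xlen_t base = (R_xlen_t)b * N;
            for (int k = 0; k < d3; ++k) {
              const int kk = k + n3;
              const bool kin = kk >= 0 && kk < d3;
              for (int j = 0; j < d2; ++j) {
                const int jj = j + n2;
                const bool jin = kin && jj >= 0 && jj < d2;
                if (!jin) continue;
                double *drow = dst + base + (R_xlen_t)j * d1 +
                               (R_xlen_t)k * d1 * d2;
                const double *srow = src + base + (R_xlen_t)jj * d1 +
                                     (R_xlen_t)kk * d1 * d2 + n1;
                const int i0 = (n1 < 0) ? 1 : 0;
                const int i1 = (n1 > 0) ? d1 - 1 : d1;
                for (int i = i0; i < i1; ++i) drow[i] += srow[i];
              }
            }
          }
        }
      }
  return out;
}
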