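#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Volumes are flat doubles with dim = (nz, ny, nx); flat index z + nz*(y + ny*x).

static inline void get_dims(const NumericVector &x, int &nz, int &ny, int &nx) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3D array");
  nz = d[0]; ny = d[1]; nx = d[2];
}

// Sliding min/max along one axis, window [-r, r], edge handling by clamping to
// the data inside the line (equivalent to min/max over the intersection of the
// window with the grid, i.e. the structuring element is cropped at borders).
static void line_filter(const double *in, double *out, int n, int stride,
                        int r, bool do_max) {
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - r), hi = std::min(n - 1, i + r);
    double v = in[(size_t)lo * stride];
    if (do_max) {
      for (int j = lo + 1; j <= hi; ++j) v = std::max(v, in[(size_t)j * stride]);
    } else {
      for (int j = lo + 1; j <= hi; ++j) v = std::min(v, in[(size_t)j * stride]);
    }
    out[(size_t)i * stride] = v;
  }
}

static NumericVector cube_filter(const NumericVector &x, int r, bool do_max) {
  int nz, ny, nx;
  get_dims(x, nz, ny, nx);
  NumericVector a = clone(x);
  NumericVector b(x.size());
  b.attr("dim") = x.attr("dim");
  double *pa = a.begin(), *pb = b.begin();
  // axis z
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy)
      line_filter(pa + (size_t)nz * (iy + (size_t)ny * ix),
                  pb + (size_t)nz * (iy + (size_t)ny * ix), nz, 1, r, do_max);
  // axis y
  for (int ix = 0; ix < nx; ++ix)
    for (int iz = 0; iz < nz; ++iz)
      line_filter(pb + iz + (size_t)nz * ny * ix,
                  pa + iz + (size_t)nz * ny * ix, ny, nz, r, do_max);
  // axis x
  for (int iy = 0; iy < ny; ++iy)
    for (int iz = 0; iz < nz; ++iz)
      line_filter(pa + iz + (size_t)nz * iy,
                  pb + iz + (size_t)nz * iy, nx, (size_t)nz * ny, r, do_max);
  return b;
}

// [[Rcpp::export]]
NumericVector cpp_dilate_cube(NumericVector x, int r) {
  if (r == 0) return clone(x);
  return cube_filter(x, r, true);
}

// [[Rcpp::export]]
NumericVector cpp_erode_cube(NumericVector x, int r) {
  if (r == 0) return clone(x);
  return cube_filter(x, r, false);
}

// 1-D correlation along an axis with mirror ('reflect') boundary: d c b a | a b c d
// [[Rcpp::export]]
NumericVector cpp_convolve_axis(NumericVector x, NumericVector kernel, int axis) {
  int nz, ny, nx;
  get_dims(x, nz, ny, nx);
  int kr = (kernel.size() - 1) / 2;
  if ((int)kernel.size() != 2 * kr + 1) stop("kernel length must be odd");
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  const double *px = x.begin();
  const double *pk = kernel.begin();
  double *po = out.begin();
  int n, nlines1, nlines2;
  size_t stride, s1, s2;
  if (axis == 1) { n = nz; stride = 1; nlines1 = ny; s1 = nz; nlines2 = nx; s2 = (size_t)nz * ny; }
  else if (axis == 2) { n = ny; stride = nz; nlines1 = nz; s1 = 1; nlines2 = nx; s2 = (size_t)nz * ny; }
  else { n = nx; stride = (size_t)nz * ny; nlines1 = nz; s1 = 1; nlines2 = ny; s2 = nz; }
  std::vector<double> line(n + 2 * kr);
  for (int l2 = 0; l2 < nlines2; ++l2) {
    for (int l1 = 0; l1 < nlines1; ++l1) {
      const double *src = px + l1 * s1 + l2 * s2;
      double *dst = po + l1 * s1 + l2 * s2;
      for (int i = 0; i < n; ++i) line[kr + i] = src[(size_t)i * stride];
      for (int i = 0; i < kr; ++i) {
        int m = (i < n) ? i : (n - 1);            // reflect
        line[kr - 1 - i] = line[kr + m];
        int m2 = (i < n) ? (n - 1 - i) : 0;
        line[kr + n + i] = line[kr + m2];
      }
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        const double *seg = &line[i];
        for (int j = 0; j < 2 * kr + 1; ++j) acc += seg[j] * pk[j];
        dst[(size_t)i * stride] = acc;
      }
    }
  }
  return out;
}
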