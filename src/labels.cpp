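#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>
#include <cstdint>
using namespace Rcpp;

static void dims3(const SEXP x, int &nz, int &ny, int &nx) {
  IntegerVector d = Rf_getAttrib(x, R_DimSymbol);
  if (d.size() != 3) stop("expected a 3D array");
  nz = d[0]; ny = d[1]; nx = d[2];
}

static int build_offsets(int nz, int ny, int conn, int dz[26], int dy[26],
                         int dx[26]) {
  int k = 0;
  for (int x = -1; x <= 1; ++x)
    for (int y = -1; y <= 1; ++y)
      for (int z = -1; z <= 1; ++z) {
        if (x == 0 && y == 0 && z == 0) continue;
        int manh = std::abs(x) + std::abs(y) + std::abs(z);
        if (conn == 6 && manh != 1) continue;
        dz[k] = z; dy[k] = y; dx[k] = x; ++k;
      }
  return k;
}

// Connected components of a binary mask (nonzero = foreground).
// Labels assigned in scan order (flat index ascending, z fastest): the
// component containing the smallest flat index gets id 1, etc.
// [[Rcpp::export]]
IntegerVector cpp_label_components(NumericVector mask, int connectivity) {
  int nz, ny, nx;
  dims3(mask, nz, ny, nx);
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n);
  lab.attr("dim") = mask.attr("dim");
  int dz[26], dy[26], dx[26];
  int nk = build_offsets(nz, ny, connectivity, dz, dy, dx);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i] == 0 || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int cz = (int)(cur % nz);
      int cy = (int)((cur / nz) % ny);
      int cx = (int)(cur / ((R_xlen_t)nz * ny));
      for (int k = 0; k < nk; ++k) {
        int zz = cz + dz[k], yy = cy + dy[k], xx = cx + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[j] != 0 && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return lab;
}

// Squared Euclidean distance transform (distance from foreground voxels to the
// nearest background voxel), exact, separable (Felzenszwalb & Huttenlocher).
static void dt1d(const double *f, double *d, int n, std::vector<int> &v,
                 std::vector<double> &zb) {
  int k = 0;
  v[0] = 0;
  zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + q * q) - (f[p] + p * p)) / (2.0 * q - 2.0 * p);
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    int p = v[k];
    d[q] = (q - p) * (q - p) + f[p];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(NumericVector mask) {
  int nz, ny, nx;
  dims3(mask, nz, ny, nx);
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  const double INF = 1e18;
  NumericVector g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = (mask[i] != 0) ? INF : 0.0;
  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> fline(nmax), dline(nmax);
  std::vector<int> v(nmax);
  std::vector<double> zb(nmax + 1);
  // z axis
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      double *col = g.begin() + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
      dt1d(col, dline.data(), nz, v, zb);
      std::copy(dline.begin(), dline.begin() + nz, col);
    }
  // y axis
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      double *base = g.begin() + z + (R_xlen_t)nz * ny * x;
      for (int y = 0; y < ny; ++y) fline[y] = base[(R_xlen_t)y * nz];
      dt1d(fline.data(), dline.data(), ny, v, zb);
      for (int y = 0; y < ny; ++y) base[(R_xlen_t)y * nz] = dline[y];
    }
  // x axis
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      double *base = g.begin() + z + (R_xlen_t)nz * y;
      for (int x = 0; x < nx; ++x) fline[x] = base[(R_xlen_t)x * nz * ny];
      dt1d(fline.data(), dline.data(), nx, v, zb);
      for (int x = 0; x < nx; ++x) base[(R_xlen_t)x * nz * ny] = dline[x];
    }
  g.attr("dim") = mask.attr("dim");
  return g;
}

// Marker-based priority-flood watershed restricted to a mask.
// Flooding pops the globally lowest topography value first; ties are broken by
// lower competing marker id, then by insertion order (scan-order seeding), so
// the result is fully deterministic.
struct QItem {
  double prio;
  int label;
  uint64_t seq;
  R_xlen_t idx;
};
struct QCmp {
  bool operator()(const QItem &a, const QItem &b) const {
    if (a.prio != b.prio) return a.prio > b.prio;
    if (a.label != b.label) return a.label > b.label;
    return a.seq > b.seq;
  }
};

// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector topo, NumericVector mask,
                            IntegerVector markers, int connectivity) {
  int nz, ny, nx;
  dims3(topo, nz, ny, nx);
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector out(n);
  out.attr("dim") = topo.attr("dim");
  int dz[26], dy[26], dx[26];
  int nk = build_offsets(nz, ny, connectivity, dz, dy, dx);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  std::vector<char> done(n, 0);
  uint64_t seq = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (markers[i] > 0) {
      out[i] = markers[i];
      pq.push({topo[i], markers[i], seq++, i});
    }
  }
  while (!pq.empty()) {
    QItem it = pq.top();
    pq.pop();
    R_xlen_t cur = it.idx;
    if (done[cur]) continue;            // already claimed (ties lost)
    done[cur] = 1;
    out[cur] = it.label;
    int cz = (int)(cur % nz);
    int cy = (int)((cur / nz) % ny);
    int cx = (int)(cur / ((R_xlen_t)nz * ny));
    for (int k = 0; k < nk; ++k) {
      int zz = cz + dz[k], yy = cy + dy[k], xx = cx + dx[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
      if (mask[j] == 0 || out[j] != 0) continue;
      pq.push({topo[j], it.label, seq++, j});
    }
  }
  return out;
}
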