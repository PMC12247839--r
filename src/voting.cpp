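#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Dense stick tensor voting (closed-form kernel).
//
// Each token at voxel p with unit plate normal n and strength s casts, at every
// receiver within a cutoff ball, a vote along the osculating circle tangent to
// the plate at p:
//   ssin  = v_hat . n  (signed sine of the angle from the tangent plane)
//   votes only for |angle| <= 45 degrees
//   arc   = l * theta / sin(theta), curvature kappa = 2 |ssin| / l
//   decay = exp(-(arc^2 + cvote * kappa^2) / sigma^2)
//   n'    = cos(2 theta) n - sin(2 theta) t_hat
// accumulating s * decay * n' n'^T. At l = 0 the token reinforces itself with
// s * n n^T. Output: the 6 unique tensor components (zz, yy, xx, zy, zx, yx).
// [[Rcpp::export]]
List cpp_tensor_vote(IntegerVector idx, NumericVector strength,
                     NumericMatrix normals, IntegerVector dims, double sigma) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector tzz(n), tyy(n), txx(n), tzy(n), tzx(n), tyx(n);
  int rad = (int)std::ceil(3.0 * sigma);
  double sig2 = sigma * sigma;
  double cvote = std::max(0.0, -16.0 * std::log(0.1) * (sigma - 1.0) / (M_PI * M_PI));
  const double smax = std::sqrt(2.0) / 2.0;  // sin(45 deg)
  R_xlen_t m = idx.size();
  for (R_xlen_t t = 0; t < m; ++t) {
    R_xlen_t flat = (R_xlen_t)idx[t] - 1;
    int pz = (int)(flat % nz);
    int py = (int)((flat / nz) % ny);
    int px = (int)(flat / ((R_xlen_t)nz * ny));
    double nzc = normals(0, t), nyc = normals(1, t), nxc = normals(2, t);
    double s = strength[t];
    int z0 = std::max(0, pz - rad), z1 = std::min(nz - 1, pz + rad);
    int y0 = std::max(0, py - rad), y1 = std::min(ny - 1, py + rad);
    int x0 = std::max(0, px - rad), x1 = std::min(nx - 1, px + rad);
    for (int ix = x0; ix <= x1; ++ix) {
      double dx = ix - px;
      for (int iy = y0; iy <= y1; ++iy) {
        double dy = iy - py;
        R_xlen_t base = (R_xlen_t)nz * (iy + (R_xlen_t)ny * ix);
        for (int iz = z0; iz <= z1; ++iz) {
          double dz = iz - pz;
          double l2 = dz * dz + dy * dy + dx * dx;
          if (l2 > (double)rad * rad) continue;
          R_xlen_t q = base + iz;
          if (l2 == 0.0) {
            tzz[q] += s * nzc * nzc; tyy[q] += s * nyc * nyc;
            txx[q] += s * nxc * nxc; tzy[q] += s * nzc * nyc;
            tzx[q] += s * nzc * nxc; tyx[q] += s * nyc * nxc;
            continue;
          }
          double l = std::sqrt(l2);
          double vz = dz / l, vy = dy / l, vx = dx / l;
          double ssin = vz * nzc + vy * nyc + vx * nxc;
          double as = std::fabs(ssin);
          if (as > smax) continue;
          double ct = std::sqrt(std::max(0.0, 1.0 - ssin * ssin));
          double theta = std::asin(ssin);
          double at = std::fabs(theta);
          double arc = (as < 1e-12) ? l : l * at / std::sin(at);
          double kappa = 2.0 * as / l;
          double decay = std::exp(-(arc * arc + cvote * kappa * kappa) / sig2);
          if (decay < 1e-10) continue;
          // tangent-plane direction of v
          double tz = (vz - ssin * nzc) / ct;
          double ty = (vy - ssin * nyc) / ct;
          double tx = (vx - ssin * nxc) / ct;
          double c2 = std::cos(2.0 * theta), s2 = std::sin(2.0 * theta);
          double wz = c2 * nzc - s2 * tz;
          double wy = c2 * nyc - s2 * ty;
          double wx = c2 * nxc - s2 * tx;
          double w = s * decay;
          tzz[q] += w * wz * wz; tyy[q] += w * wy * wy; txx[q] += w * wx * wx;
          tzy[q] += w * wz * wy; tzx[q] += w * wz * wx; tyx[q] += w * wy * wx;
        }
      }
    }
  }
  IntegerVector dm = IntegerVector::create(nz, ny, nx);
  tzz.attr("dim") = dm; tyy.attr("dim") = dm; txx.attr("dim") = dm;
  tzy.attr("dim") = dm; tzx.attr("dim") = dm; tyx.attr("dim") = dm;
  return List::create(_["zz"] = tzz, _["yy"] = tyy, _["xx"] = txx,
                      _["zy"] = tzy, _["zx"] = tzx, _["yx"] = tyx);
}
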