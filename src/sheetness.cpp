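#include <Rcpp.h>
#include "eigen3.h"
using namespace Rcpp;

// Dark-plate score from the 6 unique components of a (gamma-normalized)
// Hessian field. Hessian components are flat arrays of equal length, index
// convention matching the source volume.
//
// Eigenvalues sorted by |.|: |l1| <= |l2| <= |l3|. A dark thin plate in a
// bright surround has one dominant POSITIVE eigenvalue (intensity minimum
// across the sheet) and two near-zero ones, so:
//   require l3 > 0 (dark polarity)
//   Ra = |l2| / |l3|            (plate vs tube; ~0 for a plate)
//   Rb = sqrt(|l1 l2|) / |l3|   (plate vs blob; ~0 for a plate)
//   S  = Frobenius norm         (structureness)
// score = exp(-Ra^2/(2 a^2)) * exp(-Rb^2/(2 b^2)) * (1 - exp(-S^2/(2 c^2)))
// with c = c_frac * max S over the volume (two-pass).
// [[Rcpp::export]]
NumericVector cpp_sheet_score(NumericVector hzz, NumericVector hyy,
                              NumericVector hxx, NumericVector hzy,
                              NumericVector hzx, NumericVector hyx,
                              double alpha, double beta, double c_frac) {
  R_xlen_t n = hzz.size();
  NumericVector out(n);
  out.attr("dim") = hzz.attr("dim");
  std::vector<double> l1v(n), l2v(n), l3v(n);
  double smax = 0.0;
  double w[3];
  for (R_xlen_t i = 0; i < n; ++i) {
    eig_sym3(hzz[i], hyy[i], hxx[i], hzy[i], hzx[i], hyx[i], w);
    // re-sort by absolute value ascending
    double l[3] = {w[0], w[1], w[2]};
    if (std::fabs(l[0]) > std::fabs(l[1])) std::swap(l[0], l[1]);
    if (std::fabs(l[1]) > std::fabs(l[2])) std::swap(l[1], l[2]);
    if (std::fabs(l[0]) > std::fabs(l[1])) std::swap(l[0], l[1]);
    l1v[i] = l[0]; l2v[i] = l[1]; l3v[i] = l[2];
    double s2 = l[0] * l[0] + l[1] * l[1] + l[2] * l[2];
    if (s2 > smax) smax = s2;
  }
  smax = std::sqrt(smax);
  // flat volumes: the derivative kernels cancel only to rounding error, so
  // require non-trivial structureness before scoring at all
  if (smax < 1e-6) return out;
  double c = c_frac * smax;
  double twoa2 = 2.0 * alpha * alpha, twob2 = 2.0 * beta * beta;
  double twoc2 = 2.0 * c * c;
  for (R_xlen_t i = 0; i < n; ++i) {
    double l3 = l3v[i];
    if (l3 <= 0.0) continue;  // dark-selective polarity
    double a3 = std::fabs(l3);
    double ra = std::fabs(l2v[i]) / a3;
    double rb = std::sqrt(std::fabs(l1v[i] * l2v[i])) / a3;
    double s2 = l1v[i] * l1v[i] + l2v[i] * l2v[i] + l3 * l3;
    out[i] = std::exp(-ra * ra / twoa2) * std::exp(-rb * rb / twob2) *
             (1.0 - std::exp(-s2 / twoc2));
  }
  return out;
}

// Plate normal estimate: eigenvector of the MOST NEGATIVE eigenvalue of the
// Hessian of a (smoothed) saliency field. On the crest of a plate-like ridge
// the saliency curves down fastest across the plate, so this eigenvector is
// the plate normal. Returns a 3 x n matrix (rows: z, y, x components).
// [[Rcpp::export]]
NumericMatrix cpp_plate_normals(NumericVector hzz, NumericVector hyy,
                                NumericVector hxx, NumericVector hzy,
                                NumericVector hzx, NumericVector hyx,
                                IntegerVector idx) {
  R_xlen_t m = idx.size();
  NumericMatrix out(3, m);
  double w[3], v[3];
  for (R_xlen_t j = 0; j < m; ++j) {
    R_xlen_t i = idx[j] - 1;  // 1-based from R
    eig_sym3(hzz[i], hyy[i], hxx[i], hzy[i], hzx[i], hyx[i], w);
    eigvec_sym3(hzz[i], hyy[i], hxx[i], hzy[i], hzx[i], hyx[i], w[2], v);
    out(0, j) = v[0]; out(1, j) = v[1]; out(2, j) = v[2];
  }
  return out;
}

// Eigen-gap saliency of a symmetric tensor field given component-wise
// (descending eigenvalues): which_gap = 1 -> lambda1 - lambda2 (plate/stick
// saliency), which_gap = 2 -> lambda2 - lambda3.
// [[Rcpp::export]]
NumericVector cpp_eig_gap(NumericVector tzz, NumericVector tyy,
                          NumericVector txx, NumericVector tzy,
                          NumericVector tzx, NumericVector tyx,
                          int which_gap = 1) {
  R_xlen_t n = tzz.size();
  NumericVector out(n);
  out.attr("dim") = tzz.attr("dim");
  double w[3];
  for (R_xlen_t i = 0; i < n; ++i) {
    if (tzz[i] == 0 && tyy[i] == 0 && txx[i] == 0 &&
        tzy[i] == 0 && tzx[i] == 0 && tyx[i] == 0) continue;
    eig_sym3(tzz[i], tyy[i], txx[i], tzy[i], tzx[i], tyx[i], w);
    out[i] = (which_gap == 1) ? (w[0] - w[1]) : (w[1] - w[2]);
  }
  return out;
}
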