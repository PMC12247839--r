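#ifndef PAWSEG_EIGEN3_H
#define PAWSEG_EIGEN3_H

#include <cmath>
#include <algorithm>

// Eigenvalues of a symmetric 3x3 matrix
//   | a d e |
//   | d b f |
//   | e f c |
// returned in DESCENDING order w[0] >= w[1] >= w[2].
// Analytic (trigonometric) method; adequate for filter responses.
static inline void eig_sym3(double a, double b, double c, double d, double e,
                            double f, double w[3]) {
  double p1 = d * d + e * e + f * f;
  if (p1 == 0.0) {
    w[0] = a; w[1] = b; w[2] = c;
    std::sort(w, w + 3, std::greater<double>());
    return;
  }
  double q = (a + b + c) / 3.0;
  double aa = a - q, bb = b - q, cc = c - q;
  double p2 = aa * aa + bb * bb + cc * cc + 2.0 * p1;
  double p = std::sqrt(p2 / 6.0);
  // B = (A - qI) / p ; r = det(B) / 2
  double b11 = aa / p, b22 = bb / p, b33 = cc / p;
  double b12 = d / p, b13 = e / p, b23 = f / p;
  double r = (b11 * (b22 * b33 - b23 * b23) - b12 * (b12 * b33 - b23 * b13) +
              b13 * (b12 * b23 - b22 * b13)) / 2.0;
  r = std::max(-1.0, std::min(1.0, r));
  double phi = std::acos(r) / 3.0;
  w[0] = q + 2.0 * p * std::cos(phi);
  w[2] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
  w[1] = 3.0 * q - w[0] - w[2];
}

// Unit eigenvector for eigenvalue lam of the same matrix, via the two most
// independent rows of (A - lam I); falls back to an axis vector for the
// (near-)isotropic case.
static inline void eigvec_sym3(double a, double b, double c, double d, double e,
                               double f, double lam, double v[3]) {
  double r0[3] = {a - lam, d, e};
  double r1[3] = {d, b - lam, f};
  double r2[3] = {e, f, c - lam};
  double c01[3] = {r0[1] * r1[2] - r0[2] * r1[1],
                   r0[2] * r1[0] - r0[0] * r1[2],
                   r0[0] * r1[1] - r0[1] * r1[0]};
  double c02[3] = {r0[1] * r2[2] - r0[2] * r2[1],
                   r0[2] * r2[0] - r0[0] * r2[2],
                   r0[0] * r2[1] - r0[1] * r2[0]};
  double c12[3] = {r1[1] * r2[2] - r1[2] * r2[1],
                   r1[2] * r2[0] - r1[0] * r2[2],
                   r1[0] * r2[1] - r1[1] * r2[0]};
  double n01 = c01[0]*c01[0] + c01[1]*c01[1] + c01[2]*c01[2];
  double n02 = c02[0]*c02[0] + c02[1]*c02[1] + c02[2]*c02[2];
  double n12 = c12[0]*c12[0] + c12[1]*c12[1] + c12[2]*c12[2];
  double *best = c01; double nb = n01;
  if (n02 > nb) { best = c02; nb = n02; }
  if (n12 > nb) { best = c12; nb = n12; }
  if (nb <= 1e-24) { v[0] = 1.0; v[1] = 0.0; v[2] = 0.0; return; }
  double inv = 1.0 / std::sqrt(nb);
  v[0] = best[0] * inv; v[1] = best[1] * inv; v[2] = best[2] * inv;
}

#endif
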