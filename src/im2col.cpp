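#include <Rcpp.h>
using namespace Rcpp;

// im2col for 3D convolution. Input tensor layout (Z, Y, X, C), z fastest.
// Output matrix: rows = output voxels (zo fastest, then yo, xo), columns =
// kernel taps ordered (kz fastest, ky, kx, ci) — matching matrix(W, ncol =
// Cout) of a weight tensor with dim (k, k, k, Cin, Cout). Convolution is
// then a single GEMM, which R delegates to BLAS.

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int K, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  int Z = d[0], Y = d[1], X = d[2], C = d[3];
  int Zo = (Z + 2 * pad - K) / stride + 1;
  int Yo = (Y + 2 * pad - K) / stride + 1;
  int Xo = (X + 2 * pad - K) / stride + 1;
  R_xlen_t nrow = (R_xlen_t)Zo * Yo * Xo;
  R_xlen_t ncol = (R_xlen_t)K * K * K * C;
  NumericMatrix out(nrow, ncol);
  const double *px = x.begin();
  double *po = out.begin();
  for (int ci = 0; ci < C; ++ci) {
    for (int kx = 0; kx < K; ++kx) {
      for (int ky = 0; ky < K; ++ky) {
        for (int kz = 0; kz < K; ++kz) {
          R_xlen_t col = kz + (R_xlen_t)K * (ky + (R_xlen_t)K * (kx + (R_xlen_t)K * ci));
          double *ocol = po + col * nrow;
          for (int xo = 0; xo < Xo; ++xo) {
            int xi = xo * stride - pad + kx;
            bool xok = xi >= 0 && xi < X;
            for (int yo = 0; yo < Yo; ++yo) {
              int yi = yo * stride - pad + ky;
              R_xlen_t orow0 = (R_xlen_t)Zo * (yo + (R_xlen_t)Yo * xo);
              if (!xok || yi < 0 || yi >= Y) {
                for (int zo = 0; zo < Zo; ++zo) ocol[orow0 + zo] = 0.0;
                continue;
              }
              const double *irow = px + (R_xlen_t)Z * (yi + (R_xlen_t)Y * (xi + (R_xlen_t)X * ci));
              int zi0 = -pad + kz;
              int zo_lo = 0, zo_hi = Zo - 1;
              while (zo_lo <= zo_hi && zo_lo * stride + zi0 < 0) ++zo_lo;
              while (zo_hi >= zo_lo && zo_hi * stride + zi0 >= Z) --zo_hi;
              for (int zo = 0; zo < zo_lo; ++zo) ocol[orow0 + zo] = 0.0;
              for (int zo = zo_lo; zo <= zo_hi; ++zo)
                ocol[orow0 + zo] = irow[zo * stride + zi0];
              for (int zo = zo_hi + 1; zo < Zo; ++zo) ocol[orow0 + zo] = 0.0;
            }
          }
        }
      }
    }
  }
  return out;
}

// scatter-add of an im2col-shaped gradient matrix back onto the input grid
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix gm, IntegerVector in_dim, int K,
                         int stride, int pad) {
  int Z = in_dim[0], Y = in_dim[1], X = in_dim[2], C = in_dim[3];
  int Zo = (Z + 2 * pad - K) / stride + 1;
  int Yo = (Y + 2 * pad - K) / stride + 1;
  int Xo = (X + 2 * pad - K) / stride + 1;
  R_xlen_t nrow = (R_xlen_t)Zo * Yo * Xo;
  NumericVector gx((R_xlen_t)Z * Y * X * C);
  gx.attr("dim") = IntegerVector::create(Z, Y, X, C);
  const double *pg = gm.begin();
  double *po = gx.begin();
  for (int ci = 0; ci < C; ++ci) {
    for (int kx = 0; kx < K; ++kx) {
      for (int ky = 0; ky < K; ++ky) {
        for (int kz = 0; kz < K; ++kz) {
          R_xlen_t col = kz + (R_xlen_t)K * (ky + (R_xlen_t)K * (kx + (R_xlen_t)K * ci));
          const double *gcol = pg + col * nrow;
          for (int xo = 0; xo < Xo; ++xo) {
            int xi = xo * stride - pad + kx;
            if (xi < 0 || xi >= X) continue;
            for (int yo = 0; yo < Yo; ++yo) {
              int yi = yo * stride - pad + ky;
              if (yi < 0 || yi >= Y) continue;
              R_xlen_t orow0 = (R_xlen_t)Zo * (yo + (R_xlen_t)Yo * xo);
              double *irow = po + (R_xlen_t)Z * (yi + (R_xlen_t)Y * (xi + (R_xlen_t)X * ci));
              int zi0 = -pad + kz;
              int zo_lo = 0, zo_hi = Zo - 1;
              while (zo_lo <= zo_hi && zo_lo * stride + zi0 < 0) ++zo_lo;
              while (zo_hi >= zo_lo && zo_hi * stride + zi0 >= Z) --zo_hi;
              for (int zo = zo_lo; zo <= zo_hi; ++zo)
                irow[zo * stride + zi0] += gcol[orow0 + zo];
            }
          }
        }
      }
    }
  }
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_nn(NumericVector x, int f) {
  IntegerVector d = x.attr("dim");
  int Z = d[0], Y = d[1], X = d[2], C = d[3];
  int Zo = Z * f, Yo = Y * f, Xo = X * f;
  NumericVector y((R_xlen_t)Zo * Yo * Xo * C);
  y.attr("dim") = IntegerVector::create(Zo, Yo, Xo, C);
  const double *px = x.begin();
  double *py = y.begin();
  for (int c = 0; c < C; ++c)
    for (int xo = 0; xo < Xo; ++xo)
      for (int yo = 0; yo < Yo; ++yo) {
        const double *irow = px + (R_xlen_t)Z * ((yo / f) + (R_xlen_t)Y * ((xo / f) + (R_xlen_t)X * c));
        double *orow = py + (R_xlen_t)Zo * (yo + (R_xlen_t)Yo * (xo + (R_xlen_t)Xo * c));
        for (int zo = 0; zo < Zo; ++zo) orow[zo] = irow[zo / f];
      }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_nn_bwd(NumericVector gy, int f) {
  IntegerVector d = gy.attr("dim");
  int Zo = d[0], Yo = d[1], Xo = d[2], C = d[3];
  int Z = Zo / f, Y = Yo / f, X = Xo / f;
  NumericVector gx((R_xlen_t)Z * Y * X * C);
  gx.attr("dim") = IntegerVector::create(Z, Y, X, C);
  const double *pg = gy.begin();
  double *po = gx.begin();
  for (int c = 0; c < C; ++c)
    for (int xo = 0; xo < Xo; ++xo)
      for (int yo = 0; yo < Yo; ++yo) {
        const double *grow = pg + (R_xlen_t)Zo * (yo + (R_xlen_t)Yo * (xo + (R_xlen_t)Xo * c));
        double *irow = po + (R_xlen_t)Z * ((yo / f) + (R_xlen_t)Y * ((xo / f) + (R_xlen_t)X * c));
        for (int zo = 0; zo < Zo; ++zo) irow[zo / f] += grow[zo];
      }
  return gx;
}

// Direct convolution, forward only, used for inference on large tiles where
// an unfolded im2col matrix would not fit in memory. No temporaries beyond
// the output.
// [[Rcpp::export]]
NumericVector cpp_conv3d_direct(NumericVector x, NumericVector w,
                                NumericVector b, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  int Z = d[0], Y = d[1], X = d[2];
  IntegerVector wd = w.attr("dim");
  int K = wd[0], Cin = wd[3], Cout = wd[4];
  int Zo = (Z + 2 * pad - K) / stride + 1;
  int Yo = (Y + 2 * pad - K) / stride + 1;
  int Xo = (X + 2 * pad - K) / stride + 1;
  NumericVector y((R_xlen_t)Zo * Yo * Xo * Cout);
  y.attr("dim") = IntegerVector::create(Zo, Yo, Xo, Cout);
  const double *px = x.begin(), *pw = w.begin();
  double *py = y.begin();
  for (int co = 0; co < Cout; ++co) {
    double bias = b[co];
    for (int xo = 0; xo < Xo; ++xo) {
      for (int yo = 0; yo < Yo; ++yo) {
        double *orow = py + (R_xlen_t)Zo * (yo + (R_xlen_t)Yo * (xo + (R_xlen_t)Xo * co));
        for (int zo = 0; zo < Zo; ++zo) orow[zo] = bias;
        for (int ci = 0; ci < Cin; ++ci) {
          for (int kx = 0; kx < K; ++kx) {
            int xi = xo * stride - pad + kx;
            if (xi < 0 || xi >= X) continue;
            for (int ky = 0; ky < K; ++ky) {
              int yi = yo * stride - pad + ky;
              if (yi < 0 || yi >= Y) continue;
              const double *irow = px + (R_xlen_t)Z * (yi + (R_xlen_t)Y * (xi + (R_xlen_t)X * ci));
              const double *wcol = pw + (R_xlen_t)K * (ky + (R_xlen_t)K * (kx + (R_xlen_t)K * (ci + (R_xlen_t)Cin * co)));
              for (int kz = 0; kz < K; ++kz) {
                double wv = wcol[kz];
                if (wv == 0.0) continue;
                int zi0 = -pad + kz;
                int zo_lo = 0, zo_hi = Zo - 1;
                while (zo_lo <= zo_hi && zo_lo * stride + zi0 < 0) ++zo_lo;
                while (zo_hi >= zo_lo && zo_hi * stride + zi0 >= Z) --zo_hi;
                for (int zo = zo_lo; zo <= zo_hi; ++zo)
                  orow[zo] += wv * irow[zo * stride + zi0];
              }
            }
          }
        }
      }
    }
  }
  return y;
}
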