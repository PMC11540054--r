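#include <Rcpp.h>
#include "sampling.h"
using namespace Rcpp;

// One pass of demons-type flow updates: `iterations` inner steps, each
// re-warping the moving image under the current DVF, then adding the force
//   du = (F - Mw) * grad(Mw) / (|grad|^2 + alpha * (F - Mw)^2 / msq)
// where msq is the mean squared voxel spacing (ITK-style normaliser) so the
// per-step displacement is bounded near half a voxel. The DVF is modified in
// a copy and returned together with the SSD of the final warp.
// [[Rcpp::export]]
List cpp_demons_pass(NumericVector fixedv, IntegerVector fdim,
                     NumericVector fsp, NumericVector forg,
                     NumericVector mov, IntegerVector mdim,
                     NumericVector msp, NumericVector mor,
                     NumericVector dvf0, int iterations, double alpha,
                     double background) {
  int nx = fdim[0], ny = fdim[1], nz = fdim[2];
  long n = (long)nx * ny * nz, nxy = (long)nx * ny;
  NumericVector dvf = clone(dvf0);
  double* ux = dvf.begin();
  double* uy = ux + n;
  double* uz = uy + n;
  const double* F = fixedv.begin();
  const double* M = mov.begin();
  int mnx = mdim[0], mny = mdim[1], mnz = mdim[2];
  double msq = (fsp[0] * fsp[0] + fsp[1] * fsp[1] + fsp[2] * fsp[2]) / 3.0;
  std::vector<double> w(n);
  double ssd = 0.0;

  for (int it = 0; it < iterations; ++it) {
    // warp moving onto fixed grid
    long id = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++id) {
          double wx = forg[0] + i * fsp[0] + ux[id];
          double wy = forg[1] + j * fsp[1] + uy[id];
          double wz = forg[2] + k * fsp[2] + uz[id];
          w[id] = trilinear_sample(M, mnx, mny, mnz, (wx - mor[0]) / msp[0],
                                   (wy - mor[1]) / msp[1],
                                   (wz - mor[2]) / msp[2], background);
        }
    ssd = 0.0;
    for (long q = 0; q < n; ++q) {
      double d = w[q] - F[q];
      ssd += d * d;
    }
    // force from gradient of the warped moving image
    id = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++id) {
          int ip = i + 1 > nx - 1 ? nx - 1 : i + 1, im = i - 1 < 0 ? 0 : i - 1;
          int jp = j + 1 > ny - 1 ? ny - 1 : j + 1, jm = j - 1 < 0 ? 0 : j - 1;
          int kp = k + 1 > nz - 1 ? nz - 1 : k + 1, km = k - 1 < 0 ? 0 : k - 1;
          double gx = (w[ip + (long)nx * j + nxy * k] - w[im + (long)nx * j + nxy * k]) /
                      ((ip - im) * fsp[0]);
          double gy = (w[i + (long)nx * jp + nxy * k] - w[i + (long)nx * jm + nxy * k]) /
                      ((jp - jm) * fsp[1]);
          double gz = (w[i + (long)nx * j + nxy * kp] - w[i + (long)nx * j + nxy * km]) /
                      ((kp - km) * fsp[2]);
          double diff = F[id] - w[id];
          double denom = gx * gx + gy * gy + gz * gz + alpha * diff * diff / msq;
          if (denom > 1e-12) {
            double f = diff / denom;
            ux[id] += f * gx;
            uy[id] += f * gy;
            uz[id] += f * gz;
          }
        }
  }
  return List::create(_["dvf"] = dvf, _["ssd"] = ssd);
}

// SSD between a fixed image and the moving image warped under a DVF.
// [[Rcpp::export]]
double cpp_ssd_warp(NumericVector fixedv, IntegerVector fdim, NumericVector fsp,
                    NumericVector forg, NumericVector mov, IntegerVector mdim,
                    NumericVector msp, NumericVector mor, NumericVector dvf,
                    double background) {
  int nx = fdim[0], ny = fdim[1], nz = fdim[2];
  long n = (long)nx * ny * nz;
  const double* ux = dvf.begin();
  const double* uy = ux + n;
  const double* uz = uy + n;
  const double* M = mov.begin();
  double ssd = 0.0;
  long id = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++id) {
        double wx = forg[0] + i * fsp[0] + ux[id];
        double wy = forg[1] + j * fsp[1] + uy[id];
        double wz = forg[2] + k * fsp[2] + uz[id];
        double v = trilinear_sample(M, mdim[0], mdim[1], mdim[2],
                                    (wx - mor[0]) / msp[0],
                                    (wy - mor[1]) / msp[1],
                                    (wz - mor[2]) / msp[2], background);
        double d = v - fixedv[id];
        ssd += d * d;
      }
  return ssd;
}
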