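#include <Rcpp.h>
#include "sampling.h"
using namespace Rcpp;

// Sample a volume at arbitrary world-mm points.
// interp: 0 linear, 1 nearest, 2 linear with edge clamp (no background).
// [[Rcpp::export]]
NumericVector cpp_resample_world(NumericVector vol, IntegerVector dim,
                                 NumericVector spacing, NumericVector origin,
                                 NumericMatrix pts, int interp,
                                 double background) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = pts.nrow();
  NumericVector out(n);
  const double* v = vol.begin();
  for (long i = 0; i < n; ++i) {
    double x = (pts(i, 0) - origin[0]) / spacing[0];
    double y = (pts(i, 1) - origin[1]) / spacing[1];
    double z = (pts(i, 2) - origin[2]) / spacing[2];
    if (interp == 2) {
      if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
      if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
      if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
      out[i] = trilinear_sample(v, nx, ny, nz, x, y, z, background);
    } else if (interp == 1) {
      out[i] = nearest_sample(v, nx, ny, nz, x, y, z, background);
    } else {
      out[i] = trilinear_sample(v, nx, ny, nz, x, y, z, background);
    }
  }
  return out;
}

// Warp a moving volume onto a fixed grid under a pull-convention DVF (mm).
// dvf holds ux,uy,uz as three contiguous blocks of length nfix.
// [[Rcpp::export]]
NumericVector cpp_warp_to_grid(NumericVector mov, IntegerVector mdim,
                               NumericVector msp, NumericVector mor,
                               IntegerVector fdim, NumericVector fsp,
                               NumericVector forg, NumericVector dvf,
                               int interp, double background) {
  int nx = mdim[0], ny = mdim[1], nz = mdim[2];
  long nfix = (long)fdim[0] * fdim[1] * fdim[2];
  NumericVector out(nfix);
  const double* v = mov.begin();
  const double* ux = dvf.begin();
  const double* uy = ux + nfix;
  const double* uz = uy + nfix;
  long idx = 0;
  for (int k = 0; k < fdim[2]; ++k) {
    double wz0 = forg[2] + k * fsp[2];
    for (int j = 0; j < fdim[1]; ++j) {
      double wy0 = forg[1] + j * fsp[1];
      for (int i = 0; i < fdim[0]; ++i, ++idx) {
        double wx = forg[0] + i * fsp[0] + ux[idx];
        double wy = wy0 + uy[idx];
        double wz = wz0 + uz[idx];
        double x = (wx - mor[0]) / msp[0];
        double y = (wy - mor[1]) / msp[1];
        double z = (wz - mor[2]) / msp[2];
        out[idx] = interp == 1
                       ? nearest_sample(v, nx, ny, nz, x, y, z, background)
                       : trilinear_sample(v, nx, ny, nz, x, y, z, background);
      }
    }
  }
  return out;
}

// Central-difference gradient (per mm) of a volume on its own grid.
// Returns 3*n vector (gx, gy, gz blocks). One-sided at faces.
// [[Rcpp::export]]
NumericVector cpp_gradient3(NumericVector vol, IntegerVector dim,
                            NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = (long)nx * ny * nz, nxy = (long)nx * ny;
  NumericVector out(3 * n);
  const double* v = vol.begin();
  double* gx = out.begin();
  double* gy = gx + n;
  double* gz = gy + n;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        long id = i + (long)nx * j + nxy * k;
        int ip = i + 1 > nx - 1 ? nx - 1 : i + 1, im = i - 1 < 0 ? 0 : i - 1;
        int jp = j + 1 > ny - 1 ? ny - 1 : j + 1, jm = j - 1 < 0 ? 0 : j - 1;
        int kp = k + 1 > nz - 1 ? nz - 1 : k + 1, km = k - 1 < 0 ? 0 : k - 1;
        gx[id] = (v[ip + (long)nx * j + nxy * k] - v[im + (long)nx * j + nxy * k]) /
                 ((ip - im) * spacing[0]);
        gy[id] = (v[i + (long)nx * jp + nxy * k] - v[i + (long)nx * jm + nxy * k]) /
                 ((jp - jm) * spacing[1]);
        gz[id] = (v[i + (long)nx * j + nxy * kp] - v[i + (long)nx * j + nxy * km]) /
                 ((kp - km) * spacing[2]);
      }
  return out;
}
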