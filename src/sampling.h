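#pragma once
#include <Rcpp.h>
#include <cmath>

// Trilinear sample of a volume (dims nx,ny,nz; x fastest) at continuous
// 0-based voxel coordinates. Coordinates outside [0, n-1] return background.
inline double trilinear_sample(const double* v, int nx, int ny, int nz,
                               double x, double y, double z, double background) {
  if (!(x >= 0.0 && y >= 0.0 && z >= 0.0 &&
        x <= nx - 1.0 && y <= ny - 1.0 && z <= nz - 1.0))
    return background;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  int x1 = x0 + 1 > nx - 1 ? nx - 1 : x0 + 1;
  int y1 = y0 + 1 > ny - 1 ? ny - 1 : y0 + 1;
  int z1 = z0 + 1 > nz - 1 ? nz - 1 : z0 + 1;
  long nxy = (long)nx * ny;
  const double* p00 = v + x0 + (long)nx * y0 + nxy * z0;
  double c000 = v[x0 + (long)nx * y0 + nxy * z0];
  double c100 = v[x1 + (long)nx * y0 + nxy * z0];
  double c010 = v[x0 + (long)nx * y1 + nxy * z0];
  double c110 = v[x1 + (long)nx * y1 + nxy * z0];
  double c001 = v[x0 + (long)nx * y0 + nxy * z1];
  double c101 = v[x1 + (long)nx * y0 + nxy * z1];
  double c011 = v[x0 + (long)nx * y1 + nxy * z1];
  double c111 = v[x1 + (long)nx * y1 + nxy * z1];
  (void)p00;
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

inline double nearest_sample(const double* v, int nx, int ny, int nz,
                             double x, double y, double z, double background) {
  if (!(x >= -0.5 && y >= -0.5 && z >= -0.5 &&
        x < nx - 0.5 && y < ny - 0.5 && z < nz - 0.5))
    return background;
  int xi = (int)std::floor(x + 0.5), yi = (int)std::floor(y + 0.5), zi = (int)std::floor(z + 0.5);
  if (xi < 0) xi = 0; if (xi > nx - 1) xi = nx - 1;
  if (yi < 0) yi = 0; if (yi > ny - 1) yi = ny - 1;
  if (zi < 0) zi = 0; if (zi > nz - 1) zi = nz - 1;
  return v[xi + (long)nx * yi + (long)nx * ny * zi];
}
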