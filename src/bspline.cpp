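#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cubic B-spline basis on [0,1) local coordinate, weights for control points
// at offsets -1, 0, 1, 2.
static inline void bspline_weights(double t, double* w) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = (1 - 3 * t + 3 * t2 - t3) / 6.0;
  w[1] = (4 - 6 * t2 + 3 * t3) / 6.0;
  w[2] = (1 + 3 * t + 3 * t2 - 3 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

// Densify a free-form-deformation control lattice to a per-voxel DVF on the
// target grid. coef: 3*nc vector (x,y,z blocks) of control-point
// displacements (mm); lattice node l sits at cp_origin + l * cp_spacing.
// [[Rcpp::export]]
NumericVector cpp_ffd_dense(NumericVector coef, IntegerVector cdim,
                            NumericVector cspacing, NumericVector corigin,
                            IntegerVector fdim, NumericVector fsp,
                            NumericVector forg) {
  int ncx = cdim[0], ncy = cdim[1], ncz = cdim[2];
  long nc = (long)ncx * ncy * ncz;
  long n = (long)fdim[0] * fdim[1] * fdim[2];
  NumericVector out(3 * n);
  const double* cx = coef.begin();
  const double* cy = cx + nc;
  const double* cz = cy + nc;
  double* ox = out.begin();
  double* oy = ox + n;
  double* oz = oy + n;
  double wx[4], wy[4], wz[4];
  long id = 0;
  for (int k = 0; k < fdim[2]; ++k) {
    double tz = (forg[2] + k * fsp[2] - corigin[2]) / cspacing[2];
    int iz = (int)std::floor(tz);
    if (iz < 1) iz = 1;
    if (iz > ncz - 3) iz = ncz - 3;
    bspline_weights(tz - iz, wz);
    for (int j = 0; j < fdim[1]; ++j) {
      double ty = (forg[1] + j * fsp[1] - corigin[1]) / cspacing[1];
      int iy = (int)std::floor(ty);
      if (iy < 1) iy = 1;
      if (iy > ncy - 3) iy = ncy - 3;
      bspline_weights(ty - iy, wy);
      for (int i = 0; i < fdim[0]; ++i, ++id) {
        double tx = (forg[0] + i * fsp[0] - corigin[0]) / cspacing[0];
        int ix = (int)std::floor(tx);
        if (ix < 1) ix = 1;
        if (ix > ncx - 3) ix = ncx - 3;
        bspline_weights(tx - ix, wx);
        double sx = 0, sy = 0, sz = 0;
        for (int c = 0; c < 4; ++c) {
          long kz = (long)ncx * ncy * (iz - 1 + c);
          double wzc = wz[c];
          for (int b = 0; b < 4; ++b) {
            long ky = kz + (long)ncx * (iy - 1 + b);
            double wyb = wzc * wy[b];
            for (int a = 0; a < 4; ++a) {
              double w = wyb * wx[a];
              long l = ky + ix - 1 + a;
              sx += w * cx[l];
              sy += w * cy[l];
              sz += w * cz[l];
            }
          }
        }
        ox[id] = sx;
        oy[id] = sy;
        oz[id] = sz;
      }
    }
  }
  return out;
}

// Adjoint of cpp_ffd_dense: scatter a per-voxel 3-vector field back onto the
// control lattice with the same tensor-product weights (used for the SSD
// gradient with respect to control-point displacements).
// [[Rcpp::export]]
NumericVector cpp_ffd_adjoint(NumericVector field, IntegerVector cdim,
                              NumericVector cspacing, NumericVector corigin,
                              IntegerVector fdim, NumericVector fsp,
                              NumericVector forg) {
  int ncx = cdim[0], ncy = cdim[1], ncz = cdim[2];
  long nc = (long)ncx * ncy * ncz;
  long n = (long)fdim[0] * fdim[1] * fdim[2];
  NumericVector out(3 * nc);
  const double* fx = field.begin();
  const double* fy = fx + n;
  const double* fz = fy + n;
  double* gx = out.begin();
  double* gy = gx + nc;
  double* gz = gy + nc;
  double wx[4], wy[4], wz[4];
  long id = 0;
  for (int k = 0; k < fdim[2]; ++k) {
    double tz = (forg[2] + k * fsp[2] - corigin[2]) / cspacing[2];
    int iz = (int)std::floor(tz);
    if (iz < 1) iz = 1;
    if (iz > ncz - 3) iz = ncz - 3;
    bspline_weights(tz - iz, wz);
    for (int j = 0; j < fdim[1]; ++j) {
      double ty = (forg[1] + j * fsp[1] - corigin[1]) / cspacing[1];
      int iy = (int)std::floor(ty);
      if (iy < 1) iy = 1;
      if (iy > ncy - 3) iy = ncy - 3;
      bspline_weights(ty - iy, wy);
      for (int i = 0; i < fdim[0]; ++i, ++id) {
        double tx = (forg[0] + i * fsp[0] - corigin[0]) / cspacing[0];
        int ix = (int)std::floor(tx);
        if (ix < 1) ix = 1;
        if (ix > ncx - 3) ix = ncx - 3;
        bspline_weights(tx - ix, wx);
        for (int c = 0; c < 4; ++c) {
          long kz = (long)ncx * ncy * (iz - 1 + c);
          for (int b = 0; b < 4; ++b) {
            long ky = kz + (long)ncx * (iy - 1 + b);
            double wcb = wz[c] * wy[b];
            for (int a = 0; a < 4; ++a) {
              double w = wcb * wx[a];
              long l = ky + ix - 1 + a;
              gx[l] += w * fx[id];
              gy[l] += w * fy[id];
              gz[l] += w * fz[id];
            }
          }
        }
      }
    }
  }
  return out;
}
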