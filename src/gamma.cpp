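#include <Rcpp.h>
#include "sampling.h"
using namespace Rcpp;

// Gamma index map. For every reference voxel with eval_mask = 1 the minimum
// over candidate displacements d (rows of `offsets`, mm, sorted by increasing
// norm; dist2 = |d|^2) of
//   sqrt( (D_eval(x+d) - D_ref(x))^2 / dd_abs(x)^2 + |d|^2 / dta^2 )
// with D_eval trilinearly interpolated in world space. The sorted candidate
// list allows the classic early exit once |d|/dta exceeds the best gamma so
// far. Voxels with eval_mask = 0 return NA.
// [[Rcpp::export]]
NumericVector cpp_gamma_map(NumericVector ref, IntegerVector rdim,
                            NumericVector rsp, NumericVector rorg,
                            NumericVector ev, IntegerVector edim,
                            NumericVector esp, NumericVector eorg,
                            NumericMatrix offsets, NumericVector dist2,
                            double dta, NumericVector dd_abs,
                            IntegerVector eval_mask) {
  int nx = rdim[0], ny = rdim[1], nz = rdim[2];
  long n = (long)nx * ny * nz;
  int noff = offsets.nrow();
  NumericVector out(n, NA_REAL);
  const double* E = ev.begin();
  double dta2 = dta * dta;
  long id = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++id) {
        if (!eval_mask[id]) continue;
        double wx = rorg[0] + i * rsp[0];
        double wy = rorg[1] + j * rsp[1];
        double wz = rorg[2] + k * rsp[2];
        double dr = ref[id];
        double dd2 = dd_abs[id] * dd_abs[id];
        double best = R_PosInf;
        for (int o = 0; o < noff; ++o) {
          double dterm = dist2[o] / dta2;
          if (dterm >= best) break;
          double x = (wx + offsets(o, 0) - eorg[0]) / esp[0];
          double y = (wy + offsets(o, 1) - eorg[1]) / esp[1];
          double z = (wz + offsets(o, 2) - eorg[2]) / esp[2];
          double de = trilinear_sample(E, edim[0], edim[1], edim[2], x, y, z,
                                       NA_REAL);
          if (ISNAN(de)) continue;
          double diff = de - dr;
          double g = dterm + diff * diff / dd2;
          if (g < best) best = g;
        }
        out[id] = R_FINITE(best) ? std::sqrt(best) : NA_REAL;
      }
  return out;
}
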