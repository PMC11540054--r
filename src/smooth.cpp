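#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n - 2;
  i = ((i % period) + period) % period;
  return i < n ? i : period - i;
}

static std::vector<double> gauss_kernel(double sigma) {
  int r = (int)std::ceil(3.5 * sigma);
  if (r < 1) r = 1;
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& x : k) x /= s;
  return k;
}

// Separable Gaussian filter with mirror boundary; sigma given in voxels per
// axis, sigma <= 0 skips that axis.
// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector vol, IntegerVector dim,
                         NumericVector sigma_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = (long)nx * ny * nz, nxy = (long)nx * ny;
  std::vector<double> a(vol.begin(), vol.end()), b(n);

  if (sigma_vox[0] > 0) {
    std::vector<double> k = gauss_kernel(sigma_vox[0]);
    int r = ((int)k.size() - 1) / 2;
    for (int kz = 0; kz < nz; ++kz)
      for (int j = 0; j < ny; ++j) {
        long base = (long)nx * j + nxy * kz;
        for (int i = 0; i < nx; ++i) {
          double s = 0.0;
          for (int t = -r; t <= r; ++t)
            s += k[t + r] * a[base + reflect_idx(i + t, nx)];
          b[base + i] = s;
        }
      }
    std::swap(a, b);
  }
  if (sigma_vox[1] > 0) {
    std::vector<double> k = gauss_kernel(sigma_vox[1]);
    int r = ((int)k.size() - 1) / 2;
    for (int kz = 0; kz < nz; ++kz)
      for (int i = 0; i < nx; ++i) {
        long base = i + nxy * kz;
        for (int j = 0; j < ny; ++j) {
          double s = 0.0;
          for (int t = -r; t <= r; ++t)
            s += k[t + r] * a[base + (long)nx * reflect_idx(j + t, ny)];
          b[base + (long)nx * j] = s;
        }
      }
    std::swap(a, b);
  }
  if (sigma_vox[2] > 0) {
    std::vector<double> k = gauss_kernel(sigma_vox[2]);
    int r = ((int)k.size() - 1) / 2;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        long base = i + (long)nx * j;
        for (int kz = 0; kz < nz; ++kz) {
          double s = 0.0;
          for (int t = -r; t <= r; ++t)
            s += k[t + r] * a[base + nxy * reflect_idx(kz + t, nz)];
          b[base + nxy * kz] = s;
        }
      }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}
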