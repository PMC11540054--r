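#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

// Binary dilation by a ball of integer voxel radius.
// [[Rcpp::export]]
IntegerVector cpp_dilate_ball(IntegerVector mask, IntegerVector dim, int radius) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long nxy = (long)nx * ny;
  std::vector<std::array<int, 3>> off;
  for (int dz = -radius; dz <= radius; ++dz)
    for (int dy = -radius; dy <= radius; ++dy)
      for (int dx = -radius; dx <= radius; ++dx)
        if (dx * dx + dy * dy + dz * dz <= radius * radius)
          off.push_back({dx, dy, dz});
  IntegerVector out(mask.size());
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        long id = i + (long)nx * j + nxy * k;
        if (!mask[id]) continue;
        for (auto& o : off) {
          int x = i + o[0], y = j + o[1], z = k + o[2];
          if (x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz)
            out[x + (long)nx * y + nxy * z] = 1;
        }
      }
  return out;
}

// 26-connected component labelling of a binary volume.
// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long nxy = (long)nx * ny, n = nxy * nz;
  IntegerVector lab(n);
  int next = 0;
  std::vector<long> stack;
  for (long s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    stack.push_back(s);
    while (!stack.empty()) {
      long c = stack.back();
      stack.pop_back();
      int ci = c % nx, cj = (c / nx) % ny, ck = c / nxy;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int x = ci + dx, y = cj + dy, z = ck + dz;
            if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
              continue;
            long q = x + (long)nx * y + nxy * z;
            if (mask[q] && !lab[q]) {
              lab[q] = next;
              stack.push_back(q);
            }
          }
    }
  }
  return lab;
}

// Fill enclosed holes slice by slice (z): background 4-connected flood from
// the slice border; unreachable background becomes foreground.
// [[Rcpp::export]]
IntegerVector cpp_fill_holes_2d(IntegerVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long nxy = (long)nx * ny;
  IntegerVector out(clone(mask));
  std::vector<char> reach(nxy);
  std::vector<long> stack;
  for (int k = 0; k < nz; ++k) {
    std::fill(reach.begin(), reach.end(), 0);
    long base = nxy * (long)k;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i != 0 && i != nx - 1 && j != 0 && j != ny - 1) continue;
        long p = i + (long)nx * j;
        if (!mask[base + p] && !reach[p]) {
          reach[p] = 1;
          stack.push_back(p);
        }
      }
    while (!stack.empty()) {
      long c = stack.back();
      stack.pop_back();
      int ci = c % nx, cj = c / nx;
      const int dx[4] = {1, -1, 0, 0}, dy[4] = {0, 0, 1, -1};
      for (int t = 0; t < 4; ++t) {
        int x = ci + dx[t], y = cj + dy[t];
        if (x < 0 || x >= nx || y < 0 || y >= ny) continue;
        long q = x + (long)nx * y;
        if (!mask[base + q] && !reach[q]) {
          reach[q] = 1;
          stack.push_back(q);
        }
      }
    }
    for (long p = 0; p < nxy; ++p)
      if (!mask[base + p] && !reach[p]) out[base + p] = 1;
  }
  return out;
}

// For each row of A (points, mm) the distance to the nearest row of B.
// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericMatrix A, NumericMatrix B) {
  long n = A.nrow(), m = B.nrow();
  NumericVector out(n);
  for (long i = 0; i < n; ++i) {
    double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    double best = R_PosInf;
    for (long j = 0; j < m; ++j) {
      double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
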