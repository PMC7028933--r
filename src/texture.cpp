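#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Pair/run accumulation for gray-level texture matrices over a discretized
// 3D label array (0 = outside mask, 1..nbins = gray level). Statistics are
// computed in R; these kernels only count.

// [[Rcpp::export(name = ".glcm_counts_cpp")]]
List glcm_counts_cpp(IntegerVector lab, IntegerVector dim, int nbins,
                     IntegerMatrix offs) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int no = offs.nrow();
  List out(no);
  for (int o = 0; o < no; ++o) {
    const int dx = offs(o, 0), dy = offs(o, 1), dz = offs(o, 2);
    NumericMatrix M(nbins, nbins);
    for (int z = 0; z < nz; ++z) {
      const int z2 = z + dz;
      if (z2 < 0 || z2 >= nz) continue;
      for (int y = 0; y < ny; ++y) {
        const int y2 = y + dy;
        if (y2 < 0 || y2 >= ny) continue;
        for (int x = 0; x < nx; ++x) {
          const int x2 = x + dx;
          if (x2 < 0 || x2 >= nx) continue;
          const int a = lab[x + (int64_t)nx * (y + (int64_t)ny * z)];
          if (!a) continue;
          const int b = lab[x2 + (int64_t)nx * (y2 + (int64_t)ny * z2)];
          if (!b) continue;
          M(a - 1, b - 1) += 1.0; // symmetrized below
          M(b - 1, a - 1) += 1.0;
        }
      }
    }
    out[o] = M;
  }
  return out;
}

// [[Rcpp::export(name = ".glrlm_counts_cpp")]]
List glrlm_counts_cpp(IntegerVector lab, IntegerVector dim, int nbins,
                      IntegerMatrix offs, int maxrun) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int no = offs.nrow();
  auto at = [&](int x, int y, int z) -> int {
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return 0;
    return lab[x + (int64_t)nx * (y + (int64_t)ny * z)];
  };
  List out(no);
  for (int o = 0; o < no; ++o) {
    const int dx = offs(o, 0), dy = offs(o, 1), dz = offs(o, 2);
    NumericMatrix M(nbins, maxrun);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const int a = at(x, y, z);
          if (!a) continue;
          if (at(x - dx, y - dy, z - dz) == a) continue; // not a run start
          int len = 1;
          int cx = x + dx, cy = y + dy, cz = z + dz;
          while (at(cx, cy, cz) == a) {
            ++len; cx += dx; cy += dy; cz += dz;
          }
          if (len > maxrun) len = maxrun;
          M(a - 1, len - 1) += 1.0;
        }
    out[o] = M;
  }
  return out;
}

// separable circular convolution of a 3D array with a 1D kernel
// [[Rcpp::export(name = ".conv3d_sep_cpp")]]
NumericVector conv3d_sep_cpp(NumericVector x, IntegerVector dim,
                             NumericVector kern) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int kh = (kern.size() - 1) / 2;
  NumericVector cur(clone(x)), tmp(x.size());
  const int n[3] = {nx, ny, nz};
  const int64_t stride[3] = {1, nx, (int64_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    const int len = n[ax];
    const int64_t st = stride[ax];
    const int64_t nlines = (int64_t)nx * ny * nz / len;
    for (int64_t line = 0; line < nlines; ++line) {
      // base index of this line
      int64_t rem = line, base = 0;
      for (int a = 0; a < 3; ++a) {
        if (a == ax) continue;
        const int64_t c = rem % n[a];
        rem /= n[a];
        base += c * stride[a];
      }
      for (int i = 0; i < len; ++i) {
        double s = 0.0;
        for (int k = -kh; k <= kh; ++k) {
          int j = i + k;
          j %= len;
          if (j < 0) j += len;
          s += kern[k + kh] * cur[base + (int64_t)j * st];
        }
        tmp[base + (int64_t)i * st] = s;
      }
    }
    std::swap(cur, tmp);
  }
  return cur;
}
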