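#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Fused count + statistic kernels for the texture features. The R-level
// implementations of the same statistics (glcm_stat_vector /
// glrlm_stat_vector) are retained as reference implementations and the two
// routes are cross-checked in the test suite.

namespace {

inline double log2s(double x) { return std::log(x) / std::log(2.0); }

// 24 GLCM statistics in the order of glcm_stats_d1 (R/radiomics.R)
void glcm_stats_from_counts(const std::vector<double> &C, int ng,
                            double *out) {
  double tot = 0.0;
  for (double c : C) tot += c;
  std::vector<double> P(ng * ng, 0.0);
  if (tot == 0) {
    P[0] = 1.0;
  } else {
    for (int k = 0; k < ng * ng; ++k) P[k] = C[k] / tot;
  }
  std::vector<double> px(ng, 0.0), py(ng, 0.0);
  std::vector<double> psum(2 * ng - 1, 0.0), pdiff(ng, 0.0);
  double mux = 0, muy = 0;
  for (int j = 0; j < ng; ++j)
    for (int i = 0; i < ng; ++i) {
      const double p = P[i + ng * j];
      px[i] += p; py[j] += p;
      psum[i + j] += p; pdiff[std::abs(i - j)] += p;
    }
  for (int i = 0; i < ng; ++i) { mux += (i + 1) * px[i]; muy += (i + 1) * py[i]; }
  double sx = 0, sy = 0;
  for (int i = 0; i < ng; ++i) {
    sx += (i + 1 - mux) * (i + 1 - mux) * px[i];
    sy += (i + 1 - muy) * (i + 1 - muy) * py[i];
  }
  sx = std::sqrt(sx); sy = std::sqrt(sy);

  double autoc = 0, clpro = 0, clsha = 0, clten = 0, contrast = 0, ent = 0,
         je = 0, idm = 0, idmn = 0, id = 0, idn = 0, invvar = 0, maxp = 0,
         ssq = 0, dissim = 0, hxy1 = 0, hxy2 = 0;
  for (int j = 0; j < ng; ++j)
    for (int i = 0; i < ng; ++i) {
      const double p = P[i + ng * j];
      const double di = double(i - j);
      const double s = double(i + j + 2) - mux - muy;
      if (p > 0) {
        ent -= p * log2s(p);
        autoc += double(i + 1) * double(j + 1) * p;
        clpro += s * s * s * s * p;
        clsha += s * s * s * p;
        clten += s * s * p;
        contrast += di * di * p;
        je += p * p;
        idm += p / (1.0 + di * di);
        idmn += p / (1.0 + (di / ng) * (di / ng));
        id += p / (1.0 + std::fabs(di));
        idn += p / (1.0 + std::fabs(di) / ng);
        if (i != j) invvar += p / (di * di);
        if (p > maxp) maxp = p;
        ssq += (i + 1 - mux) * (i + 1 - mux) * p;
        dissim += std::fabs(di) * p;
      }
      const double pq = px[i] * py[j];
      if (pq > 0) {
        if (p > 0) hxy1 -= p * log2s(pq);
        hxy2 -= pq * log2s(pq);
      }
    }
  double hx = 0, hy = 0;
  for (int i = 0; i < ng; ++i) {
    if (px[i] > 0) hx -= px[i] * log2s(px[i]);
    if (py[i] > 0) hy -= py[i] * log2s(py[i]);
  }
  double corr = 1.0;
  if (sx > 0 && sy > 0) corr = (autoc - mux * muy) / (sx * sy);
  double da = 0, de = 0;
  for (int k = 0; k < ng; ++k) {
    da += k * pdiff[k];
    if (pdiff[k] > 0) de -= pdiff[k] * log2s(pdiff[k]);
  }
  double dv = 0;
  for (int k = 0; k < ng; ++k) dv += (k - da) * (k - da) * pdiff[k];
  double sa = 0, se = 0;
  for (int k = 0; k < 2 * ng - 1; ++k) {
    sa += (k + 2) * psum[k];
    if (psum[k] > 0) se -= psum[k] * log2s(psum[k]);
  }
  const double hmax = std::max(hx, hy);
  const double imc1 = hmax > 0 ? (ent - hxy1) / hmax : 0.0;
  double imc2arg = 1.0 - std::exp(-2.0 * (hxy2 - ent));
  const double imc2 = std::sqrt(imc2arg > 0 ? imc2arg : 0.0);

  out[0] = autoc; out[1] = mux; out[2] = clpro; out[3] = clsha;
  out[4] = clten; out[5] = contrast; out[6] = corr; out[7] = da;
  out[8] = de; out[9] = dv; out[10] = je; out[11] = ent; out[12] = imc1;
  out[13] = imc2; out[14] = idm; out[15] = idmn; out[16] = id;
  out[17] = idn; out[18] = invvar; out[19] = maxp; out[20] = sa;
  out[21] = se; out[22] = ssq; out[23] = dissim;
}

// 16 GLRLM statistics in the order of glrlm_stats (R/radiomics.R)
void glrlm_stats_from_counts(const std::vector<double> &M, int ng, int nr,
                             double *out) {
  double ns = 0;
  for (double m : M) ns += m;
  if (ns == 0) {
    for (int k = 0; k < 16; ++k) out[k] = 0.0;
    return;
  }
  std::vector<double> pg(ng, 0.0), pl(nr, 0.0);
  double nvox = 0, re = 0;
  double srl = 0, srh = 0, lrl = 0, lrh = 0;
  for (int l = 0; l < nr; ++l)
    for (int g = 0; g < ng; ++g) {
      const double m = M[g + ng * l];
      if (m == 0) continue;
      const double p = m / ns;
      pg[g] += p; pl[l] += p;
      nvox += m * (l + 1);
      re -= p * log2s(p);
      const double g2 = double(g + 1) * double(g + 1);
      const double l2 = double(l + 1) * double(l + 1);
      srl += p / (g2 * l2);
      srh += p * g2 / l2;
      lrl += p * l2 / g2;
      lrh += p * g2 * l2;
    }
  double sre = 0, lre = 0, glnn = 0, rlnn = 0, glv = 0, rlv = 0;
  double mug = 0, mul = 0, gln = 0, rln = 0;
  for (int g = 0; g < ng; ++g) { mug += (g + 1) * pg[g]; glnn += pg[g] * pg[g]; gln += pg[g] * pg[g]; }
  for (int l = 0; l < nr; ++l) {
    sre += pl[l] / (double(l + 1) * double(l + 1));
    lre += pl[l] * double(l + 1) * double(l + 1);
    mul += (l + 1) * pl[l];
    rlnn += pl[l] * pl[l];
    rln += pl[l] * pl[l];
  }
  gln *= ns; rln *= ns; // sum of squared counts / ns
  for (int g = 0; g < ng; ++g) glv += (g + 1 - mug) * (g + 1 - mug) * pg[g];
  for (int l = 0; l < nr; ++l) rlv += (l + 1 - mul) * (l + 1 - mul) * pl[l];
  double lgl = 0, hgl = 0;
  for (int g = 0; g < ng; ++g) {
    lgl += pg[g] / (double(g + 1) * double(g + 1));
    hgl += pg[g] * double(g + 1) * double(g + 1);
  }
  out[0] = sre; out[1] = lre; out[2] = gln; out[3] = glnn; out[4] = rln;
  out[5] = rlnn; out[6] = ns / nvox; out[7] = glv; out[8] = rlv; out[9] = re;
  out[10] = lgl; out[11] = hgl; out[12] = srl; out[13] = srh; out[14] = lrl;
  out[15] = lrh;
}

} // namespace

// [[Rcpp::export(name = ".glcm_stats_cpp")]]
NumericMatrix glcm_stats_all_cpp(IntegerVector lab, IntegerVector dim,
                                 int nbins, IntegerMatrix offs) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int no = offs.nrow();
  NumericMatrix out(24, no);
  std::vector<double> C(nbins * nbins);
  for (int o = 0; o < no; ++o) {
    std::fill(C.begin(), C.end(), 0.0);
    const int dx = offs(o, 0), dy = offs(o, 1), dz = offs(o, 2);
    for (int z = 0; z < nz; ++z) {
      const int z2 = z + dz;
      if (z2 < 0 || z2 >= nz) continue;
      for (int y = 0; y < ny; ++y) {
        const int y2 = y + dy;
        if (y2 < 0 || y2 >= ny) continue;
        const int64_t base = (int64_t)ny * z + y;
        for (int x = 0; x < nx; ++x) {
          const int x2 = x + dx;
          if (x2 < 0 || x2 >= nx) continue;
          const int a = lab[x + nx * base];
          if (!a) continue;
          const int b = lab[x2 + (int64_t)nx * (y2 + (int64_t)ny * z2)];
          if (!b) continue;
          C[(a - 1) + nbins * (b - 1)] += 1.0;
          C[(b - 1) + nbins * (a - 1)] += 1.0;
        }
      }
    }
    glcm_stats_from_counts(C, nbins, &out(0, o));
  }
  return out;
}

// [[Rcpp::export(name = ".glrlm_stats_cpp")]]
NumericMatrix glrlm_stats_all_cpp(IntegerVector lab, IntegerVector dim,
                                  int nbins, IntegerMatrix offs, int maxrun) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int no = offs.nrow();
  auto at = [&](int x, int y, int z) -> int {
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return 0;
    return lab[x + (int64_t)nx * (y + (int64_t)ny * z)];
  };
  NumericMatrix out(16, no);
  std::vector<double> M(nbins * maxrun);
  for (int o = 0; o < no; ++o) {
    std::fill(M.begin(), M.end(), 0.0);
    const int dx = offs(o, 0), dy = offs(o, 1), dz = offs(o, 2);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const int a = at(x, y, z);
          if (!a) continue;
          if (at(x - dx, y - dy, z - dz) == a) continue;
          int len = 1;
          int cx = x + dx, cy = y + dy, cz = z + dz;
          while (at(cx, cy, cz) == a) { ++len; cx += dx; cy += dy; cz += dz; }
          if (len > maxrun) len = maxrun;
          M[(a - 1) + nbins * (len - 1)] += 1.0;
        }
    glrlm_stats_from_counts(M, nbins, maxrun, &out(0, o));
  }
  return out;
}
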