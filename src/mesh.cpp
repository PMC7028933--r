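#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Triangulated isosurface of a binary voxel mask at the 0.5 level by marching
// tetrahedra. The scalar field lives on voxel centers (index coordinates);
// each lattice cell is split into 6 tetrahedra sharing the main diagonal.
// Triangle winding is fixed per element so that normals point away from the
// interior (mask == 1) side. The caller pads the mask so the surface closes.

namespace {

struct Key {
  int64_t v;
  bool operator==(const Key &o) const { return v == o.v; }
};
struct KeyHash {
  std::size_t operator()(const Key &k) const {
    return std::hash<int64_t>()(k.v);
  }
};

// edge midpoints sit on half-integer coordinates; quantize by doubling
inline int64_t enc(double x, double y, double z) {
  int64_t ix = (int64_t)std::llround(2.0 * x);
  int64_t iy = (int64_t)std::llround(2.0 * y);
  int64_t iz = (int64_t)std::llround(2.0 * z);
  return ((ix & 0x1FFFFF) << 42) | ((iy & 0x1FFFFF) << 21) | (iz & 0x1FFFFF);
}

} // namespace

// [[Rcpp::export(name = ".march_tets_cpp")]]
List march_tets_cpp(IntegerVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  auto at = [&](int x, int y, int z) -> int {
    return mask[x + (int64_t)nx * (y + (int64_t)ny * z)];
  };

  // 6-tet decomposition of the unit cube, all sharing diagonal c0-c7.
  // cube corner k has offsets (k&1, (k>>1)&1, (k>>2)&1)
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
    {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};

  std::unordered_map<Key, int, KeyHash> vmap;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;

  double cx[8], cy[8], cz[8];
  int cv[8];

  auto vertex_on_edge = [&](int a, int b) -> int {
    // midpoint between an inside and an outside corner (iso = 0.5 on {0,1})
    double px = 0.5 * (cx[a] + cx[b]);
    double py = 0.5 * (cy[a] + cy[b]);
    double pz = 0.5 * (cz[a] + cz[b]);
    Key k{enc(px, py, pz)};
    auto it = vmap.find(k);
    if (it != vmap.end()) return it->second;
    int id = (int)vx.size();
    vmap.emplace(k, id);
    vx.push_back(px); vy.push_back(py); vz.push_back(pz);
    return id;
  };

  auto emit = [&](int a, int b, int c, double inx, double iny, double inz) {
    // orient (a,b,c) so the normal points away from the interior point
    double ax = vx[a], ay = vy[a], az = vz[a];
    double ux = vx[b] - ax, uy = vy[b] - ay, uz = vz[b] - az;
    double wx2 = vx[c] - ax, wy2 = vy[c] - ay, wz2 = vz[c] - az;
    double nxn = uy * wz2 - uz * wy2;
    double nyn = uz * wx2 - ux * wz2;
    double nzn = ux * wy2 - uy * wx2;
    double gx = (ax + vx[b] + vx[c]) / 3.0 - inx;
    double gy = (ay + vy[b] + vy[c]) / 3.0 - iny;
    double gz = (az + vz[b] + vz[c]) / 3.0 - inz;
    if (nxn * gx + nyn * gy + nzn * gz < 0) std::swap(b, c);
    f0.push_back(a); f1.push_back(b); f2.push_back(c);
  };

  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        int sum = 0;
        for (int k = 0; k < 8; ++k) {
          int ox = k & 1, oy = (k >> 1) & 1, oz = (k >> 2) & 1;
          cv[k] = at(x + ox, y + oy, z + oz);
          cx[k] = x + ox; cy[k] = y + oy; cz[k] = z + oz;
          sum += cv[k];
        }
        if (sum == 0 || sum == 8) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = tets[t];
          int in[4], nin = 0, out[4], nout = 0;
          for (int k = 0; k < 4; ++k) {
            if (cv[T[k]]) in[nin++] = T[k]; else out[nout++] = T[k];
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1) {
            int p = in[0];
            int e0 = vertex_on_edge(p, out[0]);
            int e1 = vertex_on_edge(p, out[1]);
            int e2 = vertex_on_edge(p, out[2]);
            emit(e0, e1, e2, cx[p], cy[p], cz[p]);
          } else if (nin == 3) {
            int q = out[0];
            int e0 = vertex_on_edge(in[0], q);
            int e1 = vertex_on_edge(in[1], q);
            int e2 = vertex_on_edge(in[2], q);
            double ix = (cx[in[0]] + cx[in[1]] + cx[in[2]]) / 3.0;
            double iy = (cy[in[0]] + cy[in[1]] + cy[in[2]]) / 3.0;
            double iz = (cz[in[0]] + cz[in[1]] + cz[in[2]]) / 3.0;
            emit(e0, e1, e2, ix, iy, iz);
          } else { // nin == 2: quad split into two triangles
            int a = in[0], b = in[1], p = out[0], q = out[1];
            int e_ap = vertex_on_edge(a, p);
            int e_aq = vertex_on_edge(a, q);
            int e_bp = vertex_on_edge(b, p);
            int e_bq = vertex_on_edge(b, q);
            double ix = 0.5 * (cx[a] + cx[b]);
            double iy = 0.5 * (cy[a] + cy[b]);
            double iz = 0.5 * (cz[a] + cz[b]);
            emit(e_ap, e_aq, e_bq, ix, iy, iz);
            emit(e_ap, e_bq, e_bp, ix, iy, iz);
          }
        }
      }

  int nv = (int)vx.size(), nf = (int)f0.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = vx[i]; V(i, 1) = vy[i]; V(i, 2) = vz[i];
  }
  for (int i = 0; i < nf; ++i) {
    F(i, 0) = f0[i] + 1; F(i, 1) = f1[i] + 1; F(i, 2) = f2[i] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Batched solver for the small symmetric normal-equation systems of the
// per-vertex quadric fits: row i of M holds the upper triangle (15 values,
// column-major pairs (1,1),(1,2),(2,2),(1,3)...) of a 5x5 SPD matrix.
// [[Rcpp::export(name = ".solve_sym5_cpp")]]
NumericMatrix solve_sym5_cpp(NumericMatrix M, NumericMatrix b) {
  const int n = M.nrow();
  NumericMatrix out(n, 5);
  for (int r = 0; r < n; ++r) {
    double A[5][5];
    int k = 0;
    for (int j = 0; j < 5; ++j)
      for (int i = 0; i <= j; ++i) {
        A[i][j] = M(r, k);
        A[j][i] = M(r, k);
        ++k;
      }
    double x[5];
    for (int i = 0; i < 5; ++i) x[i] = b(r, i);
    bool ok = true;
    for (int col = 0; col < 5 && ok; ++col) {
      int piv = col;
      for (int i = col + 1; i < 5; ++i)
        if (std::fabs(A[i][col]) > std::fabs(A[piv][col])) piv = i;
      if (std::fabs(A[piv][col]) < 1e-14) { ok = false; break; }
      if (piv != col) {
        for (int j = 0; j < 5; ++j) std::swap(A[col][j], A[piv][j]);
        std::swap(x[col], x[piv]);
      }
      for (int i = col + 1; i < 5; ++i) {
        const double fac = A[i][col] / A[col][col];
        for (int j = col; j < 5; ++j) A[i][j] -= fac * A[col][j];
        x[i] -= fac * x[col];
      }
    }
    if (!ok) {
      for (int i = 0; i < 5; ++i) out(r, i) = 0.0;
      continue;
    }
    for (int i = 4; i >= 0; --i) {
      double s = x[i];
      for (int j = i + 1; j < 5; ++j) s -= A[i][j] * out(r, j);
      out(r, i) = s / A[i][i];
    }
  }
  return out;
}

// BFS ring neighborhoods (pairs within `ring` graph steps, excluding self)
// [[Rcpp::export(name = ".ring_pairs_cpp")]]
List ring_pairs_cpp(IntegerMatrix faces, int nvert, int ring) {
  std::vector<std::vector<int>> adj(nvert);
  auto add_edge = [&](int a, int b) {
    adj[a].push_back(b);
    adj[b].push_back(a);
  };
  for (int i = 0; i < faces.nrow(); ++i) {
    add_edge(faces(i, 0) - 1, faces(i, 1) - 1);
    add_edge(faces(i, 1) - 1, faces(i, 2) - 1);
    add_edge(faces(i, 2) - 1, faces(i, 0) - 1);
  }
  for (auto &v : adj) {
    std::sort(v.begin(), v.end());
    v.erase(std::unique(v.begin(), v.end()), v.end());
  }
  std::vector<int> pi, pj;
  std::vector<int> mark(nvert, -1);
  std::vector<int> frontier, next, seen;
  for (int s = 0; s < nvert; ++s) {
    mark[s] = s;
    frontier.assign(1, s);
    seen.clear();
    for (int depth = 0; depth < ring; ++depth) {
      next.clear();
      for (int u : frontier)
        for (int w : adj[u])
          if (mark[w] != s) {
            mark[w] = s;
            next.push_back(w);
            seen.push_back(w);
          }
      frontier = next;
    }
    for (int w : seen) { pi.push_back(s + 1); pj.push_back(w + 1); }
  }
  return List::create(_["i"] = IntegerVector(pi.begin(), pi.end()),
                      _["j"] = IntegerVector(pj.begin(), pj.end()));
}

// Taubin lambda/mu smoothing with uniform 1-ring weights
// [[Rcpp::export(name = ".taubin_cpp")]]
NumericMatrix taubin_cpp(NumericMatrix V, IntegerMatrix faces, int iterations,
                         double lambda, double mu) {
  const int n = V.nrow();
  std::vector<std::vector<int>> adj(n);
  auto add_edge = [&](int a, int b) {
    adj[a].push_back(b);
    adj[b].push_back(a);
  };
  for (int i = 0; i < faces.nrow(); ++i) {
    add_edge(faces(i, 0) - 1, faces(i, 1) - 1);
    add_edge(faces(i, 1) - 1, faces(i, 2) - 1);
    add_edge(faces(i, 2) - 1, faces(i, 0) - 1);
  }
  for (auto &v : adj) {
    std::sort(v.begin(), v.end());
    v.erase(std::unique(v.begin(), v.end()), v.end());
  }
  NumericMatrix cur(clone(V));
  NumericMatrix tmp(n, 3);
  auto pass = [&](double w) {
    for (int i = 0; i < n; ++i) {
      const auto &nb = adj[i];
      if (nb.empty()) {
        for (int c = 0; c < 3; ++c) tmp(i, c) = cur(i, c);
        continue;
      }
      double mx = 0, my = 0, mz = 0;
      for (int u : nb) { mx += cur(u, 0); my += cur(u, 1); mz += cur(u, 2); }
      const double inv = 1.0 / nb.size();
      tmp(i, 0) = cur(i, 0) + w * (mx * inv - cur(i, 0));
      tmp(i, 1) = cur(i, 1) + w * (my * inv - cur(i, 1));
      tmp(i, 2) = cur(i, 2) + w * (mz * inv - cur(i, 2));
    }
    std::swap(cur, tmp);
  };
  for (int it = 0; it < iterations; ++it) {
    pass(lambda);
    pass(mu);
  }
  return cur;
}

// column-wise scatter-add: out[idx[k], c] += vals[k, c]
// [[Rcpp::export(name = ".scatter_add_cpp")]]
NumericMatrix scatter_add_cpp(IntegerVector idx, NumericMatrix vals, int n) {
  const int m = idx.size(), p = vals.ncol();
  NumericMatrix out(n, p);
  for (int c = 0; c < p; ++c) {
    const double *vc = &vals(0, c);
    double *oc = &out(0, c);
    for (int k = 0; k < m; ++k) oc[idx[k] - 1] += vc[k];
  }
  return out;
}

// fused normal-equation accumulation for the per-vertex quadric fits:
// G = (x^2, xy, y^2, x, y); returns [sum G_i G_j (15 cols) | sum G_i z (5)]
// [[Rcpp::export(name = ".quadric_accum_cpp")]]
NumericMatrix quadric_accum_cpp(IntegerVector pv, NumericVector xl,
                                NumericVector yl, NumericVector zl, int n) {
  NumericMatrix out(n, 20);
  const int m = pv.size();
  for (int k = 0; k < m; ++k) {
    const int v = pv[k] - 1;
    const double x = xl[k], y = yl[k], z = zl[k];
    const double g[5] = {x * x, x * y, y * y, x, y};
    int c = 0;
    for (int j = 0; j < 5; ++j)
      for (int i = 0; i <= j; ++i) out(v, c++) += g[i] * g[j];
    for (int i = 0; i < 5; ++i) out(v, 15 + i) += g[i] * z;
  }
  return out;
}

// fused quadric-fit accumulation: BFS ring neighborhoods + local tangent
// coordinates + normal-equation sums, without materializing pair arrays
// [[Rcpp::export(name = ".quadric_fit_accum_cpp")]]
NumericMatrix quadric_fit_accum_cpp(IntegerMatrix faces, NumericMatrix V,
                                    NumericMatrix VN, NumericMatrix T1,
                                    NumericMatrix T2, int ring) {
  const int n = V.nrow();
  std::vector<std::vector<int>> adj(n);
  auto add_edge = [&](int a, int b) {
    adj[a].push_back(b);
    adj[b].push_back(a);
  };
  for (int i = 0; i < faces.nrow(); ++i) {
    add_edge(faces(i, 0) - 1, faces(i, 1) - 1);
    add_edge(faces(i, 1) - 1, faces(i, 2) - 1);
    add_edge(faces(i, 2) - 1, faces(i, 0) - 1);
  }
  for (auto &v : adj) {
    std::sort(v.begin(), v.end());
    v.erase(std::unique(v.begin(), v.end()), v.end());
  }
  NumericMatrix out(n, 20);
  std::vector<int> mark(n, -1), frontier, next, seen;
  for (int s = 0; s < n; ++s) {
    mark[s] = s;
    frontier.assign(1, s);
    seen.clear();
    for (int depth = 0; depth < ring; ++depth) {
      next.clear();
      for (int u : frontier)
        for (int w : adj[u])
          if (mark[w] != s) {
            mark[w] = s;
            next.push_back(w);
            seen.push_back(w);
          }
      frontier = next;
    }
    const double sx = V(s, 0), sy = V(s, 1), sz = V(s, 2);
    for (int w : seen) {
      const double dx = V(w, 0) - sx, dy = V(w, 1) - sy, dz = V(w, 2) - sz;
      const double x = dx * T1(s, 0) + dy * T1(s, 1) + dz * T1(s, 2);
      const double y = dx * T2(s, 0) + dy * T2(s, 1) + dz * T2(s, 2);
      const double z = dx * VN(s, 0) + dy * VN(s, 1) + dz * VN(s, 2);
      const double g[5] = {x * x, x * y, y * y, x, y};
      int c = 0;
      for (int j = 0; j < 5; ++j)
        for (int i = 0; i <= j; ++i) out(s, c++) += g[i] * g[j];
      for (int i = 0; i < 5; ++i) out(s, 15 + i) += g[i] * z;
    }
  }
  return out;
}

// area-weighted neighbor-average diffusion of per-vertex scalar fields
// [[Rcpp::export(name = ".diffuse_fields_cpp")]]
NumericMatrix diffuse_fields_cpp(IntegerMatrix faces, NumericMatrix fields,
                                 NumericVector w, int passes) {
  const int n = fields.nrow(), p = fields.ncol();
  std::vector<std::vector<int>> adj(n);
  auto add_edge = [&](int a, int b) {
    adj[a].push_back(b);
    adj[b].push_back(a);
  };
  for (int i = 0; i < faces.nrow(); ++i) {
    add_edge(faces(i, 0) - 1, faces(i, 1) - 1);
    add_edge(faces(i, 1) - 1, faces(i, 2) - 1);
    add_edge(faces(i, 2) - 1, faces(i, 0) - 1);
  }
  for (auto &v : adj) {
    std::sort(v.begin(), v.end());
    v.erase(std::unique(v.begin(), v.end()), v.end());
  }
  std::vector<double> den(n);
  for (int i = 0; i < n; ++i) {
    double s = w[i];
    for (int u : adj[i]) s += w[u];
    den[i] = s > 0 ? s : 1.0;
  }
  NumericMatrix cur(clone(fields));
  NumericMatrix tmp(n, p);
  for (int it = 0; it < passes; ++it) {
    for (int c = 0; c < p; ++c)
      for (int i = 0; i < n; ++i) {
        double s = cur(i, c) * w[i];
        for (int u : adj[i]) s += cur(u, c) * w[u];
        tmp(i, c) = s / den[i];
      }
    std::swap(cur, tmp);
  }
  return cur;
}
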