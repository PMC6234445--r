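// Watertight isosurface extraction from a scalar field sampled on a uniform
// node lattice, by marching tetrahedra on a Kuhn (6-tet) subdivision of each
// cube.  Tetrahedral subdivision is used instead of marching cubes because it
// has no ambiguous sign configurations: the result is a closed orientable
// manifold whenever the isosurface does not touch the lattice boundary.

#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

namespace {

inline int64_t node_id(int i, int j, int k, int nx, int ny) {
  return (int64_t)i + (int64_t)nx * ((int64_t)j + (int64_t)ny * (int64_t)k);
}

struct EdgeKey {
  int64_t a, b;
  bool operator==(const EdgeKey& o) const { return a == o.a && b == o.b; }
};
struct EdgeHash {
  size_t operator()(const EdgeKey& e) const {
    return std::hash<int64_t>()(e.a * 2654435761LL ^ (e.b + 40503LL));
  }
};

} // namespace

// [[Rcpp::export(name = ".cpp_marching_tets")]]
List cpp_marching_tets(NumericVector phi, IntegerVector dims,
                       NumericVector origin, double h) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  // Kuhn subdivision of the unit cube around the 0-7 diagonal.
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
    {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};
  static const int off[8][3] = {
    {0, 0, 0}, {1, 0, 0}, {0, 1, 0}, {1, 1, 0},
    {0, 0, 1}, {1, 0, 1}, {0, 1, 1}, {1, 1, 1}};

  std::unordered_map<EdgeKey, int, EdgeHash> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;

  auto vertex_on_edge = [&](int64_t na, int64_t nb, double pa, double pb,
                            double ax, double ay, double az,
                            double bx, double by, double bz) -> int {
    EdgeKey key{std::min(na, nb), std::max(na, nb)};
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = pa / (pa - pb);
    if (t < 1e-8) t = 1e-8;
    if (t > 1 - 1e-8) t = 1 - 1e-8;
    vx.push_back(ax + t * (bx - ax));
    vy.push_back(ay + t * (by - ay));
    vz.push_back(az + t * (bz - az));
    int id = (int)vx.size() - 1;
    edge_vertex.emplace(key, id);
    return id;
  };

  double cphi[8], cx[8], cy[8], cz[8];
  int64_t cid[8];

  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + off[c][0], jj = j + off[c][1], kk = k + off[c][2];
          cid[c] = node_id(ii, jj, kk, nx, ny);
          double p = phi[cid[c]];
          if (p == 0) p = 1e-300; // treat exact zeros as outside
          cphi[c] = p;
          cx[c] = origin[0] + ii * h;
          cy[c] = origin[1] + jj * h;
          cz[c] = origin[2] + kk * h;
          (p < 0 ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int v[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int inside[4], nin = 0;
          for (int m = 0; m < 4; ++m)
            if (cphi[v[m]] < 0) inside[nin++] = m;
          if (nin == 0 || nin == 4) continue;

          auto emit = [&](int e0a, int e0b, int e1a, int e1b, int e2a, int e2b,
                          int ref_inside) {
            int p0 = vertex_on_edge(cid[v[e0a]], cid[v[e0b]], cphi[v[e0a]],
                                    cphi[v[e0b]], cx[v[e0a]], cy[v[e0a]],
                                    cz[v[e0a]], cx[v[e0b]], cy[v[e0b]],
                                    cz[v[e0b]]);
            int p1 = vertex_on_edge(cid[v[e1a]], cid[v[e1b]], cphi[v[e1a]],
                                    cphi[v[e1b]], cx[v[e1a]], cy[v[e1a]],
                                    cz[v[e1a]], cx[v[e1b]], cy[v[e1b]],
                                    cz[v[e1b]]);
            int p2 = vertex_on_edge(cid[v[e2a]], cid[v[e2b]], cphi[v[e2a]],
                                    cphi[v[e2b]], cx[v[e2a]], cy[v[e2a]],
                                    cz[v[e2a]], cx[v[e2b]], cy[v[e2b]],
                                    cz[v[e2b]]);
            // orient so the normal points away from the inside vertex
            double ux = vx[p1] - vx[p0], uy = vy[p1] - vy[p0],
                   uz = vz[p1] - vz[p0];
            double wx = vx[p2] - vx[p0], wy = vy[p2] - vy[p0],
                   wz = vz[p2] - vz[p0];
            double nxv = uy * wz - uz * wy, nyv = uz * wx - ux * wz,
                   nzv = ux * wy - uy * wx;
            double rx = cx[v[ref_inside]] - vx[p0],
                   ry = cy[v[ref_inside]] - vy[p0],
                   rz = cz[v[ref_inside]] - vz[p0];
            bool flip = (nxv * rx + nyv * ry + nzv * rz) > 0;
            tri.push_back(p0);
            tri.push_back(flip ? p2 : p1);
            tri.push_back(flip ? p1 : p2);
          };

          if (nin == 1) {
            int a = inside[0];
            int o[3], n = 0;
            for (int m = 0; m < 4; ++m)
              if (m != a) o[n++] = m;
            emit(a, o[0], a, o[1], a, o[2], a);
          } else if (nin == 3) {
            int a = -1; // the single outside vertex
            bool is_in[4] = {false, false, false, false};
            for (int m = 0; m < nin; ++m) is_in[inside[m]] = true;
            for (int m = 0; m < 4; ++m)
              if (!is_in[m]) a = m;
            int o[3], n = 0;
            for (int m = 0; m < 4; ++m)
              if (m != a) o[n++] = m;
            emit(o[0], a, o[1], a, o[2], a, o[0]);
          } else { // nin == 2: quad split into two triangles
            int a = inside[0], b = inside[1];
            int o[2], n = 0;
            for (int m = 0; m < 4; ++m)
              if (m != a && m != b) o[n++] = m;
            emit(a, o[0], a, o[1], b, o[1], a);
            emit(a, o[0], b, o[1], b, o[0], a);
          }
        }
      }
    }
  }

  int nv = (int)vx.size();
  NumericMatrix V(nv, 3);
  for (int m = 0; m < nv; ++m) {
    V(m, 0) = vx[m];
    V(m, 1) = vy[m];
    V(m, 2) = vz[m];
  }
  int nt = (int)tri.size() / 3;
  IntegerMatrix T(nt, 3);
  for (int m = 0; m < nt; ++m) {
    T(m, 0) = tri[3 * m] + 1;
    T(m, 1) = tri[3 * m + 1] + 1;
    T(m, 2) = tri[3 * m + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["triangles"] = T);
}
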