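// Masked trilinear interpolation of cell-centred lattice fields and
// streamline tracing.  Interpolation weights of non-fluid cells are zeroed
// and the remainder renormalized, so values never bleed in from solid cells.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

struct Lat {
  int nx, ny, nz;
  double ox, oy, oz, h;
  inline int64_t cid(int i, int j, int k) const {
    return i + (int64_t)nx * (j + (int64_t)ny * k);
  }
  inline bool in(int i, int j, int k) const {
    return i >= 0 && j >= 0 && k >= 0 && i < nx && j < ny && k < nz;
  }
};

// masked trilinear sample; returns false if no fluid support
bool sample(const Lat& L, const double* f, const int* ct, double x, double y,
            double z, bool fluid_only, double& out) {
  double gx = (x - L.ox) / L.h, gy = (y - L.oy) / L.h, gz = (z - L.oz) / L.h;
  int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy),
      k0 = (int)std::floor(gz);
  double fx = gx - i0, fy = gy - j0, fz = gz - k0;
  double wsum = 0.0, vsum = 0.0;
  for (int dk = 0; dk < 2; ++dk)
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        int i = i0 + di, j = j0 + dj, k = k0 + dk;
        if (!L.in(i, j, k)) continue;
        int64_t c = L.cid(i, j, k);
        if (fluid_only && ct[c] != 0) continue;
        double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) *
                   (dk ? fz : 1 - fz);
        wsum += w;
        vsum += w * f[c];
      }
  if (wsum < 1e-12) return false;
  out = vsum / wsum;
  return true;
}

} // namespace

// [[Rcpp::export(name = ".cpp_interp_cells")]]
NumericVector cpp_interp_cells(IntegerVector dims, NumericVector origin,
                               double h, NumericVector field,
                               IntegerVector celltype, NumericMatrix pts,
                               bool fluid_only) {
  Lat L{dims[0], dims[1], dims[2], origin[0], origin[1], origin[2], h};
  int n = pts.nrow();
  NumericVector out(n);
  for (int m = 0; m < n; ++m) {
    double v;
    if (sample(L, &field[0], &celltype[0], pts(m, 0), pts(m, 1), pts(m, 2),
               fluid_only, v))
      out[m] = v;
    else
      out[m] = NA_REAL;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_trace_streamlines")]]
List cpp_trace_streamlines(IntegerVector dims, NumericVector origin, double h,
                           NumericVector uc, NumericVector vc,
                           NumericVector wc, IntegerVector celltype,
                           NumericMatrix seeds, double cfl, int max_steps,
                           int store_every) {
  Lat L{dims[0], dims[1], dims[2], origin[0], origin[1], origin[2], h};
  int ns = seeds.nrow();
  List lines(ns);
  IntegerVector exit_patch(ns);  // 0 = stalled/max-steps, k = ghost patch k
  NumericVector lengths(ns);

  auto vel = [&](double x, double y, double z, double* v) -> bool {
    return sample(L, &uc[0], &celltype[0], x, y, z, true, v[0]) &&
           sample(L, &vc[0], &celltype[0], x, y, z, true, v[1]) &&
           sample(L, &wc[0], &celltype[0], x, y, z, true, v[2]);
  };
  auto cell_of = [&](double x, double y, double z) -> int {
    int i = (int)std::floor((x - L.ox) / L.h + 0.5);
    int j = (int)std::floor((y - L.oy) / L.h + 0.5);
    int k = (int)std::floor((z - L.oz) / L.h + 0.5);
    if (!L.in(i, j, k)) return -1;
    return celltype[L.cid(i, j, k)];
  };

  for (int m = 0; m < ns; ++m) {
    double x = seeds(m, 0), y = seeds(m, 1), z = seeds(m, 2);
    std::vector<double> px, py, pz;
    px.push_back(x); py.push_back(y); pz.push_back(z);
    double arclen = 0.0;
    int code = 0;
    for (int step = 0; step < max_steps; ++step) {
      double v1[3];
      if (!vel(x, y, z, v1)) { code = 0; break; }
      double sp = std::sqrt(v1[0] * v1[0] + v1[1] * v1[1] + v1[2] * v1[2]);
      if (sp < 1e-12) { code = 0; break; }
      double dt = cfl * h / sp;
      // RK4
      double v2[3], v3[3], v4[3];
      double x2 = x + 0.5 * dt * v1[0], y2 = y + 0.5 * dt * v1[1],
             z2 = z + 0.5 * dt * v1[2];
      if (!vel(x2, y2, z2, v2)) { v2[0] = v1[0]; v2[1] = v1[1]; v2[2] = v1[2]; }
      double x3 = x + 0.5 * dt * v2[0], y3 = y + 0.5 * dt * v2[1],
             z3 = z + 0.5 * dt * v2[2];
      if (!vel(x3, y3, z3, v3)) { v3[0] = v2[0]; v3[1] = v2[1]; v3[2] = v2[2]; }
      double x4 = x + dt * v3[0], y4 = y + dt * v3[1], z4 = z + dt * v3[2];
      if (!vel(x4, y4, z4, v4)) { v4[0] = v3[0]; v4[1] = v3[1]; v4[2] = v3[2]; }
      double nxp = x + dt / 6.0 * (v1[0] + 2 * v2[0] + 2 * v3[0] + v4[0]);
      double nyp = y + dt / 6.0 * (v1[1] + 2 * v2[1] + 2 * v3[1] + v4[1]);
      double nzp = z + dt / 6.0 * (v1[2] + 2 * v2[2] + 2 * v3[2] + v4[2]);
      arclen += std::sqrt((nxp - x) * (nxp - x) + (nyp - y) * (nyp - y) +
                          (nzp - z) * (nzp - z));
      x = nxp; y = nyp; z = nzp;
      if (step % store_every == 0) {
        px.push_back(x); py.push_back(y); pz.push_back(z);
      }
      int ct = cell_of(x, y, z);
      if (ct >= 1) { code = ct; break; } // reached a cap ghost region
      if (ct < 0) { code = 0; break; }   // left the lumen (wall/outside)
    }
    px.push_back(x); py.push_back(y); pz.push_back(z);
    NumericMatrix line(px.size(), 3);
    for (size_t r = 0; r < px.size(); ++r) {
      line(r, 0) = px[r]; line(r, 1) = py[r]; line(r, 2) = pz[r];
    }
    lines[m] = line;
    exit_patch[m] = code;
    lengths[m] = arclen;
  }
  return List::create(_["lines"] = lines, _["exit_patch"] = exit_patch,
                      _["length"] = lengths);
}
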