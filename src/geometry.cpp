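// Voxel / mesh geometry kernels.
// Conventions: arrays are R arrays dim = c(nx, ny, nz), x fastest (R linear
// order); world(i,j,k) = origin + (i,j,k) * spacing with 0-based indices and
// the voxel-center convention. All lengths in mm.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <unordered_map>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

static const double BIG = 1e20;

// ---------------------------------------------------------------- 1D squared
// distance transform (Felzenszwalb & Huttenlocher), sample positions k*s.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n, double s) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; q++) {
    double qs = q * s;
    double sInt;
    while (true) {
      int p = v[k];
      double ps = p * s;
      sInt = ((f[q] + qs * qs) - (f[p] + ps * ps)) / (2.0 * qs - 2.0 * ps);
      if (sInt <= z[k] && k > 0) {
        k--;
      } else {
        break;
      }
    }
    if (sInt <= z[k] && k == 0) {
      v[0] = q;
      z[0] = -BIG;
      z[1] = BIG;
    } else {
      k++;
      v[k] = q;
      z[k] = sInt;
      z[k + 1] = BIG;
    }
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double qs = q * s;
    while (z[k + 1] < qs) k++;
    double ps = v[k] * s;
    d[q] = (qs - ps) * (qs - ps) + f[v[k]];
  }
}

// Euclidean distance (mm) from every voxel to the nearest TRUE voxel.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector feature, IntegerVector dims,
                      NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> d(n);
  for (R_xlen_t i = 0; i < n; i++) d[i] = feature[i] ? 0.0 : BIG;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; i++) f[i] = d[base + i];
      dt1d(f, dd, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; i++) d[base + i] = dd[i];
    }
  // y pass
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; j++) f[j] = d[base + (R_xlen_t)nx * j];
      dt1d(f, dd, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; j++) d[base + (R_xlen_t)nx * j] = dd[j];
    }
  // z pass
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; k++) f[k] = d[base + nxy * k];
      dt1d(f, dd, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; k++) d[base + nxy * k] = dd[k];
    }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++)
    out[i] = d[i] >= BIG ? R_PosInf : std::sqrt(d[i]);
  return out;
}

// ------------------------------------------------------- connected components
// Labels assigned in scan (linear index) order of each component's first voxel.
// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dims,
                        int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> off_i, off_j, off_k;
  for (int dk = -1; dk <= 1; dk++)
    for (int dj = -1; dj <= 1; dj++)
      for (int di = -1; di <= 1; di++) {
        int m = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (m == 0) continue;
        if (connectivity == 6 && m != 1) continue;
        off_i.push_back(di); off_j.push_back(dj); off_k.push_back(dk);
      }
  int nl = 0;
  std::vector<R_xlen_t> queue;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s] != 0) continue;
    nl++;
    lab[s] = nl;
    queue.clear();
    queue.push_back(s);
    while (!queue.empty()) {
      R_xlen_t cur = queue.back();
      queue.pop_back();
      int i = (int)(cur % nx);
      int j = (int)((cur / nx) % ny);
      int k = (int)(cur / ((R_xlen_t)nx * ny));
      for (size_t t = 0; t < off_i.size(); t++) {
        int ii = i + off_i[t], jj = j + off_j[t], kk = k + off_k[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        R_xlen_t q = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (mask[q] && lab[q] == 0) {
          lab[q] = nl;
          queue.push_back(q);
        }
      }
    }
  }
  return lab;
}

// -------------------------------------------------------- binary median filter
// Majority vote over a window^3 neighborhood truncated at the borders.
// Ties (possible only in truncated windows) keep the original value.
// [[Rcpp::export]]
LogicalVector cpp_binary_median(LogicalVector mask, IntegerVector dims,
                                int window) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int r = window / 2;
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        int cnt = 0, tot = 0;
        for (int dk = std::max(0, k - r); dk <= std::min(nz - 1, k + r); dk++)
          for (int dj = std::max(0, j - r); dj <= std::min(ny - 1, j + r); dj++)
            for (int di = std::max(0, i - r); di <= std::min(nx - 1, i + r); di++) {
              tot++;
              if (mask[di + (R_xlen_t)nx * (dj + (R_xlen_t)ny * dk)]) cnt++;
            }
        R_xlen_t lin = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (2 * cnt > tot) out[lin] = true;
        else if (2 * cnt < tot) out[lin] = false;
        else out[lin] = mask[lin];
      }
  return out;
}

// ------------------------------------------------------- marching tetrahedra
// Isosurface of a scalar field at `iso`. Each grid cube is split into the six
// tetrahedra sharing the main diagonal; intersection vertices are deduplicated
// on the tetrahedral edge (pair of grid nodes) they lie on, which makes the
// surface watertight by construction. Triangles are wound so normals point
// from field > iso (inside) to field < iso (outside).
// [[Rcpp::export]]
List cpp_march_tets(NumericVector field, IntegerVector dims,
                    NumericVector spacing, NumericVector origin, double iso) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  // six tets around diagonal c0-c7; corners numbered by bit (x,y,z)
  static const int tets[6][4] = {
      {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
      {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};
  std::unordered_map<uint64_t, int> vmap;
  std::vector<double> vx, vy, vz;
  std::vector<int> faces;

  R_xlen_t corner_lin[8];
  double cx[8], cy[8], cz[8], cf[8];

  for (int k = 0; k + 1 < nz; k++)
    for (int j = 0; j + 1 < ny; j++)
      for (int i = 0; i + 1 < nx; i++) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; c++) {
          int ii = i + (c & 1), jj = j + ((c >> 1) & 1), kk = k + ((c >> 2) & 1);
          R_xlen_t lin = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
          corner_lin[c] = lin;
          cf[c] = field[lin];
          cx[c] = origin[0] + ii * spacing[0];
          cy[c] = origin[1] + jj * spacing[1];
          cz[c] = origin[2] + kk * spacing[2];
          if (cf[c] > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; t++) {
          int vid[4];
          int nin = 0;
          for (int c = 0; c < 4; c++) {
            vid[c] = tets[t][c];
            if (cf[vid[c]] > iso) nin++;
          }
          if (nin == 0 || nin == 4) continue;
          // reference point inside the region (mean of inside tet vertices)
          double rx = 0, ry = 0, rz = 0;
          for (int c = 0; c < 4; c++)
            if (cf[vid[c]] > iso) { rx += cx[vid[c]]; ry += cy[vid[c]]; rz += cz[vid[c]]; }
          rx /= nin; ry /= nin; rz /= nin;
          // collect crossing-edge vertex ids
          int evid[4];
          int ne = 0;
          for (int a = 0; a < 4; a++)
            for (int b = a + 1; b < 4; b++) {
              int ca = vid[a], cb = vid[b];
              bool ia = cf[ca] > iso, ib = cf[cb] > iso;
              if (ia == ib) continue;
              R_xlen_t la = corner_lin[ca], lb = corner_lin[cb];
              int lo = la < lb ? ca : cb, hi = la < lb ? cb : ca;
              uint64_t key = (uint64_t)std::min(la, lb) * (uint64_t)nvox +
                             (uint64_t)std::max(la, lb);
              auto it = vmap.find(key);
              int id;
              if (it == vmap.end()) {
                double fl = cf[lo], fh = cf[hi];
                double tt = (iso - fl) / (fh - fl);
                vx.push_back(cx[lo] + tt * (cx[hi] - cx[lo]));
                vy.push_back(cy[lo] + tt * (cy[hi] - cy[lo]));
                vz.push_back(cz[lo] + tt * (cz[hi] - cz[lo]));
                id = (int)vx.size() - 1;
                vmap[key] = id;
              } else {
                id = it->second;
              }
              evid[ne++] = id;
            }
          // ne is 3 (one tri) or 4 (quad -> two tris)
          int tris[2][3];
          int ntri = 0;
          if (ne == 3) {
            tris[0][0] = evid[0]; tris[0][1] = evid[1]; tris[0][2] = evid[2];
            ntri = 1;
          } else if (ne == 4) {
            // edges found in order AC,AD,BC,BD for inside {A,B}: quad AC,AD,BD,BC
            tris[0][0] = evid[0]; tris[0][1] = evid[1]; tris[0][2] = evid[3];
            tris[1][0] = evid[0]; tris[1][1] = evid[3]; tris[1][2] = evid[2];
            ntri = 2;
          }
          for (int q = 0; q < ntri; q++) {
            int a = tris[q][0], b = tris[q][1], c = tris[q][2];
            double ux = vx[b] - vx[a], uy = vy[b] - vy[a], uz = vz[b] - vz[a];
            double wx = vx[c] - vx[a], wy = vy[c] - vy[a], wz = vz[c] - vz[a];
            double nxn = uy * wz - uz * wy;
            double nyn = uz * wx - ux * wz;
            double nzn = ux * wy - uy * wx;
            double gx = (vx[a] + vx[b] + vx[c]) / 3.0 - rx;
            double gy = (vy[a] + vy[b] + vy[c]) / 3.0 - ry;
            double gz = (vz[a] + vz[b] + vz[c]) / 3.0 - rz;
            if (nxn * gx + nyn * gy + nzn * gz < 0) std::swap(b, c);
            faces.push_back(a); faces.push_back(b); faces.push_back(c);
          }
        }
      }
  int nvert = (int)vx.size();
  int nface = (int)faces.size() / 3;
  NumericMatrix V(nvert, 3);
  for (int i = 0; i < nvert; i++) { V(i,0)=vx[i]; V(i,1)=vy[i]; V(i,2)=vz[i]; }
  IntegerMatrix Fm(nface, 3);
  for (int i = 0; i < nface; i++) {
    Fm(i,0)=faces[3*i]+1; Fm(i,1)=faces[3*i+1]+1; Fm(i,2)=faces[3*i+2]+1;
  }
  return List::create(_["vertices"] = V, _["faces"] = Fm);
}

// --------------------------------------------------------------- mesh slicing
// Cross-sections at the given z values; returns, per z, a list of closed
// loops (n x 2 matrices). Intersection points are keyed by the mesh edge they
// lie on so shared edges chain exactly.
// [[Rcpp::export]]
List cpp_slice_mesh(NumericMatrix V, IntegerMatrix F, NumericVector zs) {
  int nf = F.nrow();
  R_xlen_t nv = V.nrow();
  List out(zs.size());
  for (int zi = 0; zi < zs.size(); zi++) {
    double z = zs[zi];
    std::unordered_map<uint64_t, int> pmap;
    std::vector<double> px, py;
    std::vector<std::pair<int,int>> segs;
    for (int f = 0; f < nf; f++) {
      int idx[3] = {F(f,0) - 1, F(f,1) - 1, F(f,2) - 1};
      int pts[3], np = 0;
      for (int e = 0; e < 3; e++) {
        int a = idx[e], b = idx[(e + 1) % 3];
        double za = V(a,2), zb = V(b,2);
        if ((za - z) * (zb - z) >= 0) continue;
        int lo = a < b ? a : b, hi = a < b ? b : a;
        uint64_t key = (uint64_t)lo * (uint64_t)nv + (uint64_t)hi;
        auto it = pmap.find(key);
        int id;
        if (it == pmap.end()) {
          double t = (z - V(lo,2)) / (V(hi,2) - V(lo,2));
          px.push_back(V(lo,0) + t * (V(hi,0) - V(lo,0)));
          py.push_back(V(lo,1) + t * (V(hi,1) - V(lo,1)));
          id = (int)px.size() - 1;
          pmap[key] = id;
        } else id = it->second;
        if (np < 3) pts[np++] = id;
      }
      if (np == 2) segs.push_back(std::make_pair(pts[0], pts[1]));
    }
    // chain segments into loops
    int npts = (int)px.size();
    std::vector<std::vector<int>> adj(npts);
    for (size_t s = 0; s < segs.size(); s++) {
      adj[segs[s].first].push_back((int)s);
      adj[segs[s].second].push_back((int)s);
    }
    std::vector<bool> used(segs.size(), false);
    List loops;
    for (size_t s0 = 0; s0 < segs.size(); s0++) {
      if (used[s0]) continue;
      std::vector<int> loop;
      int cur = segs[s0].first;
      int seg = (int)s0;
      loop.push_back(cur);
      while (true) {
        used[seg] = true;
        int nxt = (segs[seg].first == cur) ? segs[seg].second : segs[seg].first;
        if (nxt == loop[0]) break;
        loop.push_back(nxt);
        int nseg = -1;
        for (size_t t = 0; t < adj[nxt].size(); t++)
          if (!used[adj[nxt][t]]) { nseg = adj[nxt][t]; break; }
        if (nseg < 0) break; // open chain (degenerate); emit as-is
        cur = nxt;
        seg = nseg;
      }
      if (loop.size() >= 3) {
        NumericMatrix L((int)loop.size(), 2);
        for (size_t t = 0; t < loop.size(); t++) {
          L((int)t,0) = px[loop[t]];
          L((int)t,1) = py[loop[t]];
        }
        loops.push_back(L);
      }
    }
    out[zi] = loops;
  }
  return out;
}

// ------------------------------------------------------------ marching squares
// Contours of a 2D field (nx x ny, node positions origin + index*h) at `level`,
// chained into loops. Saddle cells resolved by the cell-center average.
// [[Rcpp::export]]
List cpp_marching_squares(NumericMatrix field, double level,
                          NumericVector origin2, double h) {
  int nx = field.nrow(), ny = field.ncol();
  // edge id: horizontal (i,j)-(i+1,j): 2*(i + nx*j); vertical (i,j)-(i,j+1): 2*lin+1
  std::unordered_map<int64_t, int> pmap;
  std::vector<double> px, py;
  std::vector<std::pair<int,int>> segs;
  auto getpt = [&](int i, int j, bool vertical) -> int {
    int64_t key = 2 * ((int64_t)i + (int64_t)nx * j) + (vertical ? 1 : 0);
    auto it = pmap.find(key);
    if (it != pmap.end()) return it->second;
    double fa = field(i, j);
    double fb = vertical ? field(i, j + 1) : field(i + 1, j);
    double t = (level - fa) / (fb - fa);
    double x = origin2[0] + (vertical ? i : i + t) * h;
    double y = origin2[1] + (vertical ? j + t : j) * h;
    px.push_back(x); py.push_back(y);
    pmap[key] = (int)px.size() - 1;
    return (int)px.size() - 1;
  };
  for (int j = 0; j + 1 < ny; j++)
    for (int i = 0; i + 1 < nx; i++) {
      double f00 = field(i, j), f10 = field(i + 1, j);
      double f11 = field(i + 1, j + 1), f01 = field(i, j + 1);
      bool b00 = f00 > level, b10 = f10 > level, b11 = f11 > level, b01 = f01 > level;
      int code = (b00 ? 1 : 0) | (b10 ? 2 : 0) | (b11 ? 4 : 0) | (b01 ? 8 : 0);
      if (code == 0 || code == 15) continue;
      // crossing points on cell edges
      int e_bot = (b00 != b10) ? getpt(i, j, false) : -1;
      int e_rgt = (b10 != b11) ? getpt(i + 1, j, true) : -1;
      int e_top = (b01 != b11) ? getpt(i, j + 1, false) : -1;
      int e_lft = (b00 != b01) ? getpt(i, j, true) : -1;
      if (code == 5 || code == 10) { // saddle
        bool centerIn = (f00 + f10 + f11 + f01) / 4.0 > level;
        if (b00 == centerIn) {
          segs.push_back(std::make_pair(e_bot, e_rgt));
          segs.push_back(std::make_pair(e_top, e_lft));
        } else {
          segs.push_back(std::make_pair(e_lft, e_bot));
          segs.push_back(std::make_pair(e_rgt, e_top));
        }
      } else {
        int pts[4], np = 0;
        if (e_bot >= 0) pts[np++] = e_bot;
        if (e_rgt >= 0) pts[np++] = e_rgt;
        if (e_top >= 0) pts[np++] = e_top;
        if (e_lft >= 0) pts[np++] = e_lft;
        if (np == 2) segs.push_back(std::make_pair(pts[0], pts[1]));
      }
    }
  // chain
  int npts = (int)px.size();
  std::vector<std::vector<int>> adj(npts);
  for (size_t s = 0; s < segs.size(); s++) {
    adj[segs[s].first].push_back((int)s);
    adj[segs[s].second].push_back((int)s);
  }
  std::vector<bool> used(segs.size(), false);
  List loops;
  for (size_t s0 = 0; s0 < segs.size(); s0++) {
    if (used[s0]) continue;
    std::vector<int> loop;
    int cur = segs[s0].first, seg = (int)s0;
    loop.push_back(cur);
    while (true) {
      used[seg] = true;
      int nxt = (segs[seg].first == cur) ? segs[seg].second : segs[seg].first;
      if (nxt == loop[0]) break;
      loop.push_back(nxt);
      int nseg = -1;
      for (size_t t = 0; t < adj[nxt].size(); t++)
        if (!used[adj[nxt][t]]) { nseg = adj[nxt][t]; break; }
      if (nseg < 0) break;
      cur = nxt;
      seg = nseg;
    }
    if (loop.size() >= 3) {
      NumericMatrix L((int)loop.size(), 2);
      for (size_t t = 0; t < loop.size(); t++) {
        L((int)t,0) = px[loop[t]];
        L((int)t,1) = py[loop[t]];
      }
      loops.push_back(L);
    }
  }
  return loops;
}

// --------------------------------------------------- nearest neighbour (grid)
// For each query point, index (1-based) of and distance to the nearest
// reference point. Uniform-grid bucketing with expanding ring search.
// [[Rcpp::export]]
List cpp_nn(NumericMatrix query, NumericMatrix ref) {
  int nq = query.nrow(), nr = ref.nrow();
  IntegerVector idx(nq);
  NumericVector dist(nq);
  if (nr == 0) stop("empty reference cloud");
  double mn[3], mx[3];
  for (int d = 0; d < 3; d++) { mn[d] = R_PosInf; mx[d] = R_NegInf; }
  for (int i = 0; i < nr; i++)
    for (int d = 0; d < 3; d++) {
      if (ref(i,d) < mn[d]) mn[d] = ref(i,d);
      if (ref(i,d) > mx[d]) mx[d] = ref(i,d);
    }
  double ext = 0;
  for (int d = 0; d < 3; d++) ext = std::max(ext, mx[d] - mn[d]);
  double cell = ext > 0 ? ext / std::max(1.0, std::cbrt((double)nr)) : 1.0;
  if (cell <= 0) cell = 1.0;
  auto cellkey = [&](double x, double y, double zc) -> int64_t {
    int64_t gx = (int64_t)std::floor((x - mn[0]) / cell) + 4;
    int64_t gy = (int64_t)std::floor((y - mn[1]) / cell) + 4;
    int64_t gz = (int64_t)std::floor((zc - mn[2]) / cell) + 4;
    return (gx & 0xFFFFF) | ((gy & 0xFFFFF) << 20) | ((gz & 0xFFFFF) << 40);
  };
  std::unordered_map<int64_t, std::vector<int>> grid;
  grid.reserve(nr * 2);
  for (int i = 0; i < nr; i++)
    grid[cellkey(ref(i,0), ref(i,1), ref(i,2))].push_back(i);
  int maxr = (int)std::ceil(ext / cell) + 2;
  for (int q = 0; q < nq; q++) {
    double qx = query(q,0), qy = query(q,1), qz = query(q,2);
    int64_t gx = (int64_t)std::floor((qx - mn[0]) / cell) + 4;
    int64_t gy = (int64_t)std::floor((qy - mn[1]) / cell) + 4;
    int64_t gz = (int64_t)std::floor((qz - mn[2]) / cell) + 4;
    double best = R_PosInf;
    int besti = -1;
    for (int r = 0; r <= maxr; r++) {
      if (besti >= 0 && (double)(r - 1) * cell > std::sqrt(best)) break;
      for (int dz = -r; dz <= r; dz++)
        for (int dy = -r; dy <= r; dy++)
          for (int dx = -r; dx <= r; dx++) {
            if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz))) != r)
              continue;
            int64_t key = ((gx + dx) & 0xFFFFF) | (((gy + dy) & 0xFFFFF) << 20) |
                          (((gz + dz) & 0xFFFFF) << 40);
            auto it = grid.find(key);
            if (it == grid.end()) continue;
            for (size_t t = 0; t < it->second.size(); t++) {
              int i = it->second[t];
              double ddx = ref(i,0) - qx, ddy = ref(i,1) - qy, ddz = ref(i,2) - qz;
              double d2 = ddx*ddx + ddy*ddy + ddz*ddz;
              if (d2 < best) { best = d2; besti = i; }
            }
          }
    }
    idx[q] = besti + 1;
    dist[q] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["dist"] = dist);
}

// ---------------------------------------------------------------- voxelization
// Parity ray casting along +z through a slightly jittered column lattice;
// voxel centers inside the (watertight) mesh become TRUE.
// [[Rcpp::export]]
LogicalVector cpp_voxelize(NumericMatrix V, IntegerMatrix F, IntegerVector dims,
                           NumericVector spacing, NumericVector origin) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  double jx = 0.1291712 * hx, jy = 0.0716253 * hy;
  std::vector<std::vector<double>> cols((size_t)nx * ny);
  int nf = F.nrow();
  for (int f = 0; f < nf; f++) {
    int a = F(f,0) - 1, b = F(f,1) - 1, c = F(f,2) - 1;
    double ax = V(a,0), ay = V(a,1), az = V(a,2);
    double bx = V(b,0), by = V(b,1), bz = V(b,2);
    double cx = V(c,0), cy = V(c,1), cz = V(c,2);
    double det = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
    if (std::fabs(det) < 1e-14) continue; // vertical face: no parity effect
    double xmin = std::min(ax, std::min(bx, cx)), xmax = std::max(ax, std::max(bx, cx));
    double ymin = std::min(ay, std::min(by, cy)), ymax = std::max(ay, std::max(by, cy));
    int i0 = std::max(0, (int)std::ceil((xmin - jx - origin[0]) / hx));
    int i1 = std::min(nx - 1, (int)std::floor((xmax - jx - origin[0]) / hx));
    int j0 = std::max(0, (int)std::ceil((ymin - jy - origin[1]) / hy));
    int j1 = std::min(ny - 1, (int)std::floor((ymax - jy - origin[1]) / hy));
    for (int j = j0; j <= j1; j++) {
      double yy = origin[1] + j * hy + jy;
      for (int i = i0; i <= i1; i++) {
        double xx = origin[0] + i * hx + jx;
        double l1 = ((xx - ax) * (cy - ay) - (yy - ay) * (cx - ax)) / det;
        double l2 = ((bx - ax) * (yy - ay) - (by - ay) * (xx - ax)) / det;
        if (l1 < 0 || l2 < 0 || l1 + l2 > 1) continue;
        double zc = az + l1 * (bz - az) + l2 * (cz - az);
        cols[(size_t)i + (size_t)nx * j].push_back(zc);
      }
    }
  }
  LogicalVector out((R_xlen_t)nx * ny * nz, false);
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      std::vector<double> &cs = cols[(size_t)i + (size_t)nx * j];
      if (cs.empty()) continue;
      std::sort(cs.begin(), cs.end());
      for (int k = 0; k < nz; k++) {
        double zc = origin[2] + k * hz;
        int above = (int)(cs.end() - std::upper_bound(cs.begin(), cs.end(), zc));
        if (above % 2 == 1)
          out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = true;
      }
    }
  return out;
}

// ------------------------------------------------------------- loop rasterizer
// Even-odd scanline fill of closed 2D loops onto an nx x ny pixel-center grid.
// [[Rcpp::export]]
LogicalVector cpp_rasterize_loops(List loops, IntegerVector dims2,
                                  NumericVector origin2, double h) {
  int nx = dims2[0], ny = dims2[1];
  LogicalVector out((R_xlen_t)nx * ny, false);
  double eps = 1e-7 * h;
  for (int j = 0; j < ny; j++) {
    double y = origin2[1] + j * h + eps;
    std::vector<double> xs;
    for (int l = 0; l < loops.size(); l++) {
      NumericMatrix L = loops[l];
      int n = L.nrow();
      for (int s = 0; s < n; s++) {
        double y1 = L(s,1), y2 = L((s + 1) % n, 1);
        if ((y1 - y) * (y2 - y) >= 0) continue;
        double t = (y - y1) / (y2 - y1);
        xs.push_back(L(s,0) + t * (L((s + 1) % n, 0) - L(s,0)));
      }
    }
    if (xs.empty()) continue;
    std::sort(xs.begin(), xs.end());
    for (size_t p = 0; p + 1 < xs.size(); p += 2) {
      int i0 = std::max(0, (int)std::ceil((xs[p] - origin2[0]) / h));
      int i1 = std::min(nx - 1, (int)std::floor((xs[p + 1] - origin2[0]) / h));
      for (int i = i0; i <= i1; i++) out[i + (R_xlen_t)nx * j] = true;
    }
  }
  return out;
}
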