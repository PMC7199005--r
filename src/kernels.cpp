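#include <Rcpp.h>
#include <queue>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

// Voxel grids arrive as R arrays with dim = (n1, n2, n3), first index fastest
// (axis order z, y, x everywhere in this package). Linear index:
//   i = z + n1 * (y + n2 * x)

static inline R_xlen_t lin(int z, int y, int x, int n1, int n2) {
  return (R_xlen_t)z + (R_xlen_t)n1 * ((R_xlen_t)y + (R_xlen_t)n2 * (R_xlen_t)x);
}

// neighbour offsets for 6/18/26 connectivity
static void conn_offsets(int connectivity, std::vector<std::array<int,3>> &off) {
  off.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        off.push_back({dz, dy, dx});
      }
}

// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  std::vector<std::array<int,3>> off;
  conn_offsets(connectivity, off);
  IntegerVector lab(mask.size(), 0);
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (int x = 0; x < n3; ++x)
    for (int y = 0; y < n2; ++y)
      for (int z = 0; z < n1; ++z) {
        R_xlen_t i = lin(z, y, x, n1, n2);
        if (!mask[i] || lab[i]) continue;
        ++cur;
        lab[i] = cur;
        stack.push_back(i);
        while (!stack.empty()) {
          R_xlen_t j = stack.back(); stack.pop_back();
          int zz = (int)(j % n1);
          R_xlen_t r = j / n1;
          int yy = (int)(r % n2);
          int xx = (int)(r / n2);
          for (auto &o : off) {
            int az = zz + o[0], ay = yy + o[1], ax = xx + o[2];
            if (az < 0 || ay < 0 || ax < 0 || az >= n1 || ay >= n2 || ax >= n3)
              continue;
            R_xlen_t k = lin(az, ay, ax, n1, n2);
            if (mask[k] && !lab[k]) { lab[k] = cur; stack.push_back(k); }
          }
        }
      }
  lab.attr("n_components") = cur;
  return lab;
}

// background voxels 6-connected to the grid border; cavities are the
// background voxels this flood never reaches
// [[Rcpp::export(name = ".reach_border")]]
LogicalVector reach_border(LogicalVector mask, IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  LogicalVector vis(mask.size(), false);
  std::vector<R_xlen_t> stack;
  auto seed = [&](int z, int y, int x) {
    R_xlen_t i = lin(z, y, x, n1, n2);
    if (!mask[i] && !vis[i]) { vis[i] = true; stack.push_back(i); }
  };
  for (int y = 0; y < n2; ++y)
    for (int z = 0; z < n1; ++z) { seed(z, y, 0); seed(z, y, n3 - 1); }
  for (int x = 0; x < n3; ++x)
    for (int z = 0; z < n1; ++z) { seed(z, 0, x); seed(z, n2 - 1, x); }
  for (int x = 0; x < n3; ++x)
    for (int y = 0; y < n2; ++y) { seed(0, y, x); seed(n1 - 1, y, x); }
  const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!stack.empty()) {
    R_xlen_t j = stack.back(); stack.pop_back();
    int zz = (int)(j % n1);
    R_xlen_t r = j / n1;
    int yy = (int)(r % n2);
    int xx = (int)(r / n2);
    for (int o = 0; o < 6; ++o) {
      int az = zz + off[o][0], ay = yy + off[o][1], ax = xx + off[o][2];
      if (az < 0 || ay < 0 || ax < 0 || az >= n1 || ay >= n2 || ax >= n3)
        continue;
      R_xlen_t k = lin(az, ay, ax, n1, n2);
      if (!mask[k] && !vis[k]) { vis[k] = true; stack.push_back(k); }
    }
  }
  return vis;
}

// morphological dilation/erosion; the structuring element is either a
// Euclidean digital ball (dz^2+dy^2+dx^2 <= r^2) or a Chebyshev ball (cube
// of side 2r+1, the dual of 26-connected foreground). Erosion treats outside
// the grid as background.
// [[Rcpp::export(name = ".ball_morph")]]
LogicalVector ball_morph(LogicalVector mask, IntegerVector dim, int radius,
                         bool dilate, bool chebyshev) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  std::vector<std::array<int,3>> off;
  for (int dz = -radius; dz <= radius; ++dz)
    for (int dy = -radius; dy <= radius; ++dy)
      for (int dx = -radius; dx <= radius; ++dx)
        if (chebyshev || dz*dz + dy*dy + dx*dx <= radius*radius)
          off.push_back({dz, dy, dx});
  LogicalVector out(mask.size());
  for (int x = 0; x < n3; ++x)
    for (int y = 0; y < n2; ++y)
      for (int z = 0; z < n1; ++z) {
        R_xlen_t i = lin(z, y, x, n1, n2);
        bool acc = !dilate;
        for (auto &o : off) {
          int az = z + o[0], ay = y + o[1], ax = x + o[2];
          bool v;
          if (az < 0 || ay < 0 || ax < 0 || az >= n1 || ay >= n2 || ax >= n3)
            v = false;
          else
            v = mask[lin(az, ay, ax, n1, n2)];
          if (dilate) { if (v) { acc = true; break; } }
          else        { if (!v) { acc = false; break; } }
        }
        out[i] = acc;
      }
  return out;
}

// separable Gaussian blur, constant boundary value; sigma in voxel units,
// sigma <= 0 skips that axis
// [[Rcpp::export(name = ".gauss_blur3")]]
NumericVector gauss_blur3(NumericVector vol, IntegerVector dim,
                          NumericVector sigma_vox, double boundary) {
  const int n[3] = {dim[0], dim[1], dim[2]};
  NumericVector cur = clone(vol);
  const R_xlen_t n1 = n[0], n2 = n[1];
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int rad = (int)std::ceil(4.0 * s);
    std::vector<double> k(2 * rad + 1);
    double sum = 0;
    for (int t = -rad; t <= rad; ++t) {
      k[t + rad] = std::exp(-0.5 * t * t / (s * s));
      sum += k[t + rad];
    }
    for (auto &v : k) v /= sum;
    NumericVector nxt(cur.size());
    for (int x = 0; x < n[2]; ++x)
      for (int y = 0; y < n[1]; ++y)
        for (int z = 0; z < n[0]; ++z) {
          double acc = 0;
          for (int t = -rad; t <= rad; ++t) {
            int az = z, ay = y, axx = x;
            if (ax == 0) az += t; else if (ax == 1) ay += t; else axx += t;
            double v;
            if (az < 0 || ay < 0 || axx < 0 ||
                az >= n[0] || ay >= n[1] || axx >= n[2])
              v = boundary;
            else
              v = cur[lin(az, ay, axx, (int)n1, (int)n2)];
            acc += k[t + rad] * v;
          }
          nxt[lin(z, y, x, (int)n1, (int)n2)] = acc;
        }
    cur = nxt;
  }
  return cur;
}

// ---- isosurface of a binary mask -------------------------------------------
// Freudenthal decomposition of each grid cell into 6 tetrahedra sharing the
// main diagonal; face diagonals agree between neighbouring cells, so the
// triangulation is crack-free. Iso-vertices sit at midpoints of tetrahedron
// edges whose endpoints straddle the surface. Mask is padded by one
// background voxel on each face so surfaces close.

static const int CN[8][3] = {
  {0,0,0},{0,0,1},{0,1,1},{0,1,0},{1,0,0},{1,0,1},{1,1,1},{1,1,0}};
static const int TETS[6][4] = {
  {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}};

// [[Rcpp::export(name = ".mask_mesh")]]
List mask_mesh(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const int p1 = n1 + 2, p2 = n2 + 2, p3 = n3 + 2;
  std::vector<char> v((R_xlen_t)p1 * p2 * p3, 0);
  for (int x = 0; x < n3; ++x)
    for (int y = 0; y < n2; ++y)
      for (int z = 0; z < n1; ++z)
        if (mask[lin(z, y, x, n1, n2)])
          v[lin(z + 1, y + 1, x + 1, p1, p2)] = 1;

  std::unordered_map<uint64_t, int> vid;
  std::vector<double> vz, vy, vx;
  std::vector<int> f0, f1, f2;
  const double dz = spacing[0], dy = spacing[1], dx = spacing[2];

  auto corner_lin = [&](int cz, int cy, int cx) {
    return (uint64_t)lin(cz, cy, cx, p1, p2);
  };
  auto vertex = [&](int azc, int ayc, int axc, int bzc, int byc, int bxc) {
    uint64_t a = corner_lin(azc, ayc, axc), b = corner_lin(bzc, byc, bxc);
    if (a > b) std::swap(a, b);
    uint64_t key = (a << 32) | b;
    auto it = vid.find(key);
    if (it != vid.end()) return it->second;
    int id = (int)vz.size();
    vid.emplace(key, id);
    // midpoint, shifted back by the 1-voxel pad, scaled to physical units
    vz.push_back((0.5 * (azc + bzc) - 1.0) * dz);
    vy.push_back((0.5 * (ayc + byc) - 1.0) * dy);
    vx.push_back((0.5 * (axc + bxc) - 1.0) * dx);
    return id;
  };

  int cz[4], cy[4], cx[4];
  for (int x = 0; x < p3 - 1; ++x)
    for (int y = 0; y < p2 - 1; ++y)
      for (int z = 0; z < p1 - 1; ++z) {
        char cv[8];
        int s8 = 0;
        for (int c = 0; c < 8; ++c) {
          cv[c] = v[lin(z + CN[c][0], y + CN[c][1], x + CN[c][2], p1, p2)];
          s8 += cv[c];
        }
        if (s8 == 0 || s8 == 8) continue;
        for (int t = 0; t < 6; ++t) {
          int ins[4], s = 0;
          for (int m = 0; m < 4; ++m) {
            ins[m] = cv[TETS[t][m]];
            s += ins[m];
            cz[m] = z + CN[TETS[t][m]][0];
            cy[m] = y + CN[TETS[t][m]][1];
            cx[m] = x + CN[TETS[t][m]][2];
          }
          if (s == 0 || s == 4) continue;
          if (s == 1 || s == 3) {
            int a = -1;
            for (int m = 0; m < 4; ++m)
              if ((s == 1 && ins[m]) || (s == 3 && !ins[m])) a = m;
            int ids[3], j = 0;
            for (int m = 0; m < 4; ++m)
              if (m != a)
                ids[j++] = vertex(cz[a], cy[a], cx[a], cz[m], cy[m], cx[m]);
            f0.push_back(ids[0]); f1.push_back(ids[1]); f2.push_back(ids[2]);
          } else { // 2 in, 2 out: quad split into two triangles
            int a = -1, b = -1, c = -1, d = -1;
            for (int m = 0; m < 4; ++m) {
              if (ins[m]) { if (a < 0) a = m; else b = m; }
              else        { if (c < 0) c = m; else d = m; }
            }
            int q0 = vertex(cz[a], cy[a], cx[a], cz[c], cy[c], cx[c]);
            int q1 = vertex(cz[a], cy[a], cx[a], cz[d], cy[d], cx[d]);
            int q2 = vertex(cz[b], cy[b], cx[b], cz[d], cy[d], cx[d]);
            int q3 = vertex(cz[b], cy[b], cx[b], cz[c], cy[c], cx[c]);
            f0.push_back(q0); f1.push_back(q1); f2.push_back(q2);
            f0.push_back(q0); f1.push_back(q2); f2.push_back(q3);
          }
        }
      }

  int nv = (int)vz.size(), nf = (int)f0.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) { V(i,0) = vz[i]; V(i,1) = vy[i]; V(i,2) = vx[i]; }
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) { F(i,0) = f0[i]; F(i,1) = f1[i]; F(i,2) = f2[i]; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Taubin lambda/mu smoothing with uniform weights; shrink-free low-pass on
// the mesh, used to remove voxelization staircase before measuring area.
// clamp (per axis, physical units) bounds each vertex's total displacement
// from its initial position: staircase relief needs ~half a voxel, so a
// sub-voxel clamp removes aliasing without letting small meshes collapse.
// clamp <= 0 disables the bound on that axis.
// [[Rcpp::export(name = ".taubin_smooth")]]
NumericMatrix taubin_smooth(NumericMatrix V, IntegerMatrix F, int iterations,
                            double lambda, double mu, NumericVector clamp) {
  int nv = V.nrow(), nf = F.nrow();
  std::vector<std::vector<int>> nbr(nv);
  for (int i = 0; i < nf; ++i) {
    int a = F(i,0), b = F(i,1), c = F(i,2);
    nbr[a].push_back(b); nbr[a].push_back(c);
    nbr[b].push_back(a); nbr[b].push_back(c);
    nbr[c].push_back(a); nbr[c].push_back(b);
  }
  for (auto &v : nbr) {
    std::sort(v.begin(), v.end());
    v.erase(std::unique(v.begin(), v.end()), v.end());
  }
  std::vector<double> X(nv * 3), Y(nv * 3), X0(nv * 3);
  for (int i = 0; i < nv; ++i)
    for (int d = 0; d < 3; ++d) X0[i + d * nv] = X[i + d * nv] = V(i, d);
  const double step[2] = {lambda, mu};
  for (int it = 0; it < iterations; ++it)
    for (int ph = 0; ph < 2; ++ph) {
      for (int i = 0; i < nv; ++i) {
        const auto &nb = nbr[i];
        if (nb.empty()) {
          for (int d = 0; d < 3; ++d) Y[i + d * nv] = X[i + d * nv];
          continue;
        }
        for (int d = 0; d < 3; ++d) {
          double m = 0;
          for (int j : nb) m += X[j + d * nv];
          m /= nb.size();
          double y = X[i + d * nv] + step[ph] * (m - X[i + d * nv]);
          if (clamp[d] > 0) {
            double lo = X0[i + d * nv] - clamp[d], hi = X0[i + d * nv] + clamp[d];
            if (y < lo) y = lo; else if (y > hi) y = hi;
          }
          Y[i + d * nv] = y;
        }
      }
      std::swap(X, Y);
    }
  NumericMatrix out(nv, 3);
  for (int i = 0; i < nv; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = X[i + d * nv];
  return out;
}

// [[Rcpp::export(name = ".mesh_area")]]
double mesh_area(NumericMatrix V, IntegerMatrix F) {
  double area = 0;
  for (int i = 0; i < F.nrow(); ++i) {
    int a = F(i,0), b = F(i,1), c = F(i,2);
    double u0 = V(b,0)-V(a,0), u1 = V(b,1)-V(a,1), u2 = V(b,2)-V(a,2);
    double w0 = V(c,0)-V(a,0), w1 = V(c,1)-V(a,1), w2 = V(c,2)-V(a,2);
    double x0 = u1*w2 - u2*w1, x1 = u2*w0 - u0*w2, x2 = u0*w1 - u1*w0;
    area += 0.5 * std::sqrt(x0*x0 + x1*x1 + x2*x2);
  }
  return area;
}
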