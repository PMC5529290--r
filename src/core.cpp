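#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Arrays are R arrays with dim = c(nz, ny, nx), column-major:
// linear index = z + nz * (y + ny * x).

static inline R_xlen_t lin(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * x);
}

// Separable 1D convolution along one axis with edge-replication padding.
// axis: 0 = z, 1 = y, 2 = x. Kernel must be odd-length, normalized by caller.
// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector arr, IntegerVector dims,
                            NumericVector kernel, int axis) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int klen = kernel.size();
  const int half = klen / 2;
  NumericVector out(arr.size());
  out.attr("dim") = dims;

  const int n_axis = (axis == 0) ? nz : (axis == 1) ? ny : nx;
  // stride along the convolved axis
  const R_xlen_t stride = (axis == 0) ? 1 :
    (axis == 1) ? (R_xlen_t)nz : (R_xlen_t)nz * ny;

  // iterate over all lines
  const int d1 = (axis == 0) ? ny : nz;
  const int d2 = (axis == 2) ? ny : nx;
  std::vector<double> line(n_axis);
  for (int j = 0; j < d2; ++j) {
    for (int i = 0; i < d1; ++i) {
      R_xlen_t base;
      if (axis == 0)      base = lin(0, i, j, nz, ny);
      else if (axis == 1) base = lin(i, 0, j, nz, ny);
      else                base = lin(i, j, 0, nz, ny);
      for (int k = 0; k < n_axis; ++k) line[k] = arr[base + stride * k];
      for (int k = 0; k < n_axis; ++k) {
        double acc = 0.0;
        for (int t = 0; t < klen; ++t) {
          int src = k + t - half;
          if (src < 0) src = 0;
          else if (src >= n_axis) src = n_axis - 1;
          acc += kernel[t] * line[src];
        }
        out[base + stride * k] = acc;
      }
    }
  }
  return out;
}

// ---- 3D topology helpers -------------------------------------------------

// offsets of the 26-neighborhood in (dz, dy, dx)
static const int OFF26[26][3] = {
  {-1,-1,-1},{-1,-1,0},{-1,-1,1},{-1,0,-1},{-1,0,0},{-1,0,1},
  {-1,1,-1},{-1,1,0},{-1,1,1},{0,-1,-1},{0,-1,0},{0,-1,1},
  {0,0,-1},{0,0,1},{0,1,-1},{0,1,0},{0,1,1},{1,-1,-1},
  {1,-1,0},{1,-1,1},{1,0,-1},{1,0,0},{1,0,1},{1,1,-1},{1,1,0},{1,1,1}
};

// neighborhood cube index (0..26): (dz+1) + 3*(dy+1) + 9*(dx+1); center = 13
static inline int cubeIdx(int dz, int dy, int dx) {
  return (dz + 1) + 3 * (dy + 1) + 9 * (dx + 1);
}

static void getNeighborhood(const int* mask, int z, int y, int x,
                            int nz, int ny, int nx, bool nb[27]) {
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz, yy = y + dy, xx = x + dx;
        bool v = false;
        if (zz >= 0 && zz < nz && yy >= 0 && yy < ny && xx >= 0 && xx < nx)
          v = mask[lin(zz, yy, xx, nz, ny)] != 0;
        nb[cubeIdx(dz, dy, dx)] = v;
      }
}

// number of 26-connected foreground components in N26 (center excluded);
// characterization of a simple point requires exactly one.
static int fgComponents26(const bool nb[27]) {
  bool visited[27] = {false};
  int ncomp = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || visited[s]) continue;
    ++ncomp;
    std::queue<int> q; q.push(s); visited[s] = true;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int cz = c % 3 - 1, cy = (c / 3) % 3 - 1, cx = c / 9 - 1;
      for (int t = 0; t < 26; ++t) {
        int z2 = cz + OFF26[t][0], y2 = cy + OFF26[t][1], x2 = cx + OFF26[t][2];
        if (z2 < -1 || z2 > 1 || y2 < -1 || y2 > 1 || x2 < -1 || x2 > 1) continue;
        int s2 = cubeIdx(z2, y2, x2);
        if (s2 == 13 || visited[s2] || !nb[s2]) continue;
        visited[s2] = true; q.push(s2);
      }
    }
  }
  return ncomp;
}

// number of 6-connected background components in the 18-neighborhood that are
// 6-adjacent to the center; a simple point requires exactly one.
static int bgComponents6(const bool nb[27]) {
  // N18 membership: |dz|+|dy|+|dx| <= 2, excluding center
  bool visited[27] = {false};
  int ncomp = 0;
  static const int FACE[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  for (int f = 0; f < 6; ++f) {
    int s = cubeIdx(FACE[f][0], FACE[f][1], FACE[f][2]);
    if (nb[s] || visited[s]) continue;
    ++ncomp;
    std::queue<int> q; q.push(s); visited[s] = true;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int cz = c % 3 - 1, cy = (c / 3) % 3 - 1, cx = c / 9 - 1;
      for (int f2 = 0; f2 < 6; ++f2) {
        int z2 = cz + FACE[f2][0], y2 = cy + FACE[f2][1], x2 = cx + FACE[f2][2];
        if (z2 < -1 || z2 > 1 || y2 < -1 || y2 > 1 || x2 < -1 || x2 > 1) continue;
        if (std::abs(z2) + std::abs(y2) + std::abs(x2) > 2) continue; // stay in N18
        int s2 = cubeIdx(z2, y2, x2);
        if (s2 == 13 || visited[s2] || nb[s2]) continue;
        visited[s2] = true; q.push(s2);
      }
    }
  }
  return ncomp;
}

static inline bool isSimple(const bool nb[27]) {
  return fgComponents26(nb) == 1 && bgComponents6(nb) == 1;
}

static inline int fgNeighborCount(const bool nb[27]) {
  int n = 0;
  for (int s = 0; s < 27; ++s) if (s != 13 && nb[s]) ++n;
  return n;
}

// Topology-preserving curve thinning (medial axis by iterative border
// peeling with simple-point checks; curve endpoints preserved).
// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  std::vector<int> m(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) m[i] = mask[i] ? 1 : 0;

  static const int DIRS[6][3] = { // border direction checked each subiteration
    {0,-1,0},{0,1,0},{0,0,-1},{0,0,1},{-1,0,0},{1,0,0}
  };
  bool nb[27];
  bool changed = true;
  std::vector<R_xlen_t> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y)
          for (int z = 0; z < nz; ++z) {
            R_xlen_t idx = lin(z, y, x, nz, ny);
            if (!m[idx]) continue;
            int zz = z + DIRS[d][0], yy = y + DIRS[d][1], xx = x + DIRS[d][2];
            bool border = !(zz >= 0 && zz < nz && yy >= 0 && yy < ny &&
                            xx >= 0 && xx < nx) ||
                          m[lin(zz, yy, xx, nz, ny)] == 0;
            if (!border) continue;
            getNeighborhood(m.data(), z, y, x, nz, ny, nx, nb);
            int nn = fgNeighborCount(nb);
            if (nn <= 1) continue;           // endpoint or isolated: keep
            if (isSimple(nb)) cand.push_back(idx);
          }
      // sequential deletion with re-check (deleting one point can make a
      // neighboring candidate non-simple)
      for (size_t c = 0; c < cand.size(); ++c) {
        R_xlen_t idx = cand[c];
        int x = (int)(idx / ((R_xlen_t)nz * ny));
        int y = (int)((idx / nz) % ny);
        int z = (int)(idx % nz);
        getNeighborhood(m.data(), z, y, x, nz, ny, nx, nb);
        if (fgNeighborCount(nb) <= 1) continue;
        if (isSimple(nb)) { m[idx] = 0; changed = true; }
      }
    }
  }
  LogicalVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = m[i] != 0;
  out.attr("dim") = dims;
  return out;
}

// Binary dilation/erosion with an explicit offset list (rows of (dz,dy,dx)).
// For erosion, voxels outside the grid count as foreground so that objects
// flush with the image border are not eroded from that side.
// [[Rcpp::export]]
LogicalVector cpp_morph(LogicalVector mask, IntegerVector dims,
                        IntegerMatrix offsets, bool dilate) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int noff = offsets.nrow();
  LogicalVector out(mask.size());
  out.attr("dim") = dims;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t idx = lin(z, y, x, nz, ny);
        bool acc = !dilate;
        for (int t = 0; t < noff; ++t) {
          int zz = z + offsets(t, 0), yy = y + offsets(t, 1), xx = x + offsets(t, 2);
          bool inside = zz >= 0 && zz < nz && yy >= 0 && yy < ny && xx >= 0 && xx < nx;
          bool v = inside ? (mask[lin(zz, yy, xx, nz, ny)] != 0) : !dilate;
          if (dilate) { if (v) { acc = true; break; } }
          else        { if (!v) { acc = false; break; } }
        }
        out[idx] = acc;
      }
  return out;
}

// Largest connected component of a binary mask (BFS).
// connectivity: 6 or 26.
// [[Rcpp::export]]
LogicalVector cpp_largest_component(LogicalVector mask, IntegerVector dims,
                                    int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  std::vector<int> label(mask.size(), 0);
  int best_label = 0;
  R_xlen_t best_size = 0;
  int cur = 0;
  const int nconn = (connectivity == 6) ? 6 : 26;
  static const int FACE[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  std::queue<R_xlen_t> q;
  for (R_xlen_t start = 0; start < mask.size(); ++start) {
    if (!mask[start] || label[start]) continue;
    ++cur;
    R_xlen_t sz = 0;
    label[start] = cur; q.push(start);
    while (!q.empty()) {
      R_xlen_t idx = q.front(); q.pop(); ++sz;
      int x = (int)(idx / ((R_xlen_t)nz * ny));
      int y = (int)((idx / nz) % ny);
      int z = (int)(idx % nz);
      for (int t = 0; t < nconn; ++t) {
        int dz, dy, dx;
        if (nconn == 6) { dz = FACE[t][0]; dy = FACE[t][1]; dx = FACE[t][2]; }
        else { dz = OFF26[t][0]; dy = OFF26[t][1]; dx = OFF26[t][2]; }
        int zz = z + dz, yy = y + dy, xx = x + dx;
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        R_xlen_t idx2 = lin(zz, yy, xx, nz, ny);
        if (!mask[idx2] || label[idx2]) continue;
        label[idx2] = cur; q.push(idx2);
      }
    }
    if (sz > best_size) { best_size = sz; best_label = cur; }
  }
  LogicalVector out(mask.size());
  out.attr("dim") = dims;
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = (label[i] == best_label);
  return out;
}

// For each target voxel (0-based (z,y,x) rows), the value at the nearest
// candidate voxel in physical units (voxel sizes in um, order z,y,x).
// Ties broken by lowest z, then y, then x index. Expanding-box search.
// [[Rcpp::export]]
NumericVector cpp_nearest_value(IntegerMatrix targets, LogicalVector cand,
                                NumericVector values, IntegerVector dims,
                                NumericVector vs) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double vz = vs[0], vy = vs[1], vx = vs[2];
  const double vmin = std::min(vz, std::min(vy, vx));
  const int rmax = std::max(nz, std::max(ny, nx));
  NumericVector out(targets.nrow());
  for (int t = 0; t < targets.nrow(); ++t) {
    int z0 = targets(t, 0), y0 = targets(t, 1), x0 = targets(t, 2);
    double best = R_PosInf;
    int bz = -1, by = -1, bx = -1;
    for (int r = 0; r <= rmax; ++r) {
      if (best < R_PosInf && (double)(r - 1) * vmin > best) break;
      // shell at Chebyshev radius r
      for (int dx = -r; dx <= r; ++dx) {
        int xx = x0 + dx; if (xx < 0 || xx >= nx) continue;
        for (int dy = -r; dy <= r; ++dy) {
          int yy = y0 + dy; if (yy < 0 || yy >= ny) continue;
          bool face = (std::abs(dx) == r) || (std::abs(dy) == r);
          for (int dz = -r; dz <= r; ++dz) {
            if (!face && std::abs(dz) != r) continue;
            int zz = z0 + dz; if (zz < 0 || zz >= nz) continue;
            R_xlen_t idx = lin(zz, yy, xx, nz, ny);
            if (!cand[idx]) continue;
            double d = std::sqrt(dz * vz * dz * vz + dy * vy * dy * vy +
                                 dx * vx * dx * vx);
            bool better = d < best - 1e-12;
            bool tie = std::fabs(d - best) <= 1e-12;
            if (better || (tie && (zz < bz || (zz == bz && (yy < by ||
                (yy == by && xx < bx)))))) {
              best = d; bz = zz; by = yy; bx = xx;
            }
          }
        }
      }
    }
    out[t] = (bz < 0) ? NA_REAL : values[lin(bz, by, bx, nz, ny)];
  }
  return out;
}

// 26-neighbor foreground count per voxel (used for skeleton topology checks).
// [[Rcpp::export]]
IntegerVector cpp_neighbor_count26(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  IntegerVector out(mask.size());
  out.attr("dim") = dims;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t idx = lin(z, y, x, nz, ny);
        if (!mask[idx]) { out[idx] = 0; continue; }
        int n = 0;
        for (int t = 0; t < 26; ++t) {
          int zz = z + OFF26[t][0], yy = y + OFF26[t][1], xx = x + OFF26[t][2];
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          if (mask[lin(zz, yy, xx, nz, ny)]) ++n;
        }
        out[idx] = n;
      }
  return out;
}

// Box median filter computed only at voxels where `where` is true; other
// voxels pass through unchanged. r = half-widths (z, y, x) in voxels.
// [[Rcpp::export]]
NumericVector cpp_median_box(NumericVector arr, IntegerVector dims,
                             IntegerVector r, LogicalVector where) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  NumericVector out = clone(arr);
  out.attr("dim") = dims;
  std::vector<double> buf;
  buf.reserve((2 * r[0] + 1) * (2 * r[1] + 1) * (2 * r[2] + 1));
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t idx = lin(z, y, x, nz, ny);
        if (!where[idx]) continue;
        buf.clear();
        for (int dx = -r[2]; dx <= r[2]; ++dx) {
          int xx = x + dx; if (xx < 0 || xx >= nx) continue;
          for (int dy = -r[1]; dy <= r[1]; ++dy) {
            int yy = y + dy; if (yy < 0 || yy >= ny) continue;
            for (int dz = -r[0]; dz <= r[0]; ++dz) {
              int zz = z + dz; if (zz < 0 || zz >= nz) continue;
              buf.push_back(arr[lin(zz, yy, xx, nz, ny)]);
            }
          }
        }
        size_t mid = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
        double med = buf[mid];
        if (buf.size() % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + mid);
          med = 0.5 * (med + lo);
        }
        out[idx] = med;
      }
  return out;
}

// Separable box dilation/erosion: 1D pass along one axis with half-width r.
// Outside-grid treated as background for dilation, foreground for erosion.
// [[Rcpp::export]]
LogicalVector cpp_box_morph_axis(LogicalVector mask, IntegerVector dims,
                                 int r, int axis, bool dilate) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n_axis = (axis == 0) ? nz : (axis == 1) ? ny : nx;
  const R_xlen_t stride = (axis == 0) ? 1 :
    (axis == 1) ? (R_xlen_t)nz : (R_xlen_t)nz * ny;
  const int d1 = (axis == 0) ? ny : nz;
  const int d2 = (axis == 2) ? ny : nx;
  LogicalVector out(mask.size());
  out.attr("dim") = dims;
  std::vector<int> line(n_axis);
  for (int j = 0; j < d2; ++j) {
    for (int i = 0; i < d1; ++i) {
      R_xlen_t base;
      if (axis == 0)      base = lin(0, i, j, nz, ny);
      else if (axis == 1) base = lin(i, 0, j, nz, ny);
      else                base = lin(i, j, 0, nz, ny);
      for (int k = 0; k < n_axis; ++k) line[k] = mask[base + stride * k] ? 1 : 0;
      // prefix sums for O(1) window queries
      std::vector<int> ps(n_axis + 1, 0);
      for (int k = 0; k < n_axis; ++k) ps[k + 1] = ps[k] + line[k];
      for (int k = 0; k < n_axis; ++k) {
        int lo = std::max(0, k - r), hi = std::min(n_axis - 1, k + r);
        int cnt = ps[hi + 1] - ps[lo];
        int win = hi - lo + 1;
        bool v = dilate ? (cnt > 0) : (cnt == win);
        out[base + stride * k] = v;
      }
    }
  }
  return out;
}
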