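// 3D image kernels shared by the organoid and nuclei segmentation stages.
// All arrays are R arrays with dim = c(z, y, x), column-major (z fastest).
// Connectivity: 6 = face neighbours, 26 = face+edge+corner neighbours.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>

using namespace Rcpp;

static inline long long idx3(int z, int y, int x, int nz, int ny) {
  return (long long)z + (long long)nz * ((long long)y + (long long)ny * x);
}

// Enumerate neighbour offsets for the requested connectivity.
static std::vector<std::array<int, 3>> neighbours(int connectivity) {
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int manhattan = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && manhattan != 1) continue;
        off.push_back({dz, dy, dx});
      }
  return off;
}

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim,
                          int connectivity) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  long long n = (long long)nz * ny * nx;
  IntegerVector labels(n, 0);
  std::vector<std::array<int, 3>> off = neighbours(connectivity);
  std::vector<long long> stack;
  int cur = 0;
  // scan in linear (z-fastest) order so label ids are deterministic
  for (long long i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++cur;
    labels[i] = cur;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      long long p = stack.back();
      stack.pop_back();
      int x = (int)(p / ((long long)nz * ny));
      long long rem = p - (long long)x * nz * ny;
      int y = (int)(rem / nz);
      int z = (int)(rem % nz);
      for (size_t k = 0; k < off.size(); ++k) {
        int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        long long q = idx3(zz, yy, xx, nz, ny);
        if (mask[q] && labels[q] == 0) {
          labels[q] = cur;
          stack.push_back(q);
        }
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}

// Fill cavities: background voxels not reachable (6-conn) from the border
// become foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes3d(LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  long long n = (long long)nz * ny * nx;
  std::vector<char> outside(n, 0);
  std::vector<long long> stack;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        if (z != 0 && z != nz - 1 && y != 0 && y != ny - 1 && x != 0 &&
            x != nx - 1)
          continue;
        long long i = idx3(z, y, x, nz, ny);
        if (!mask[i] && !outside[i]) {
          outside[i] = 1;
          stack.push_back(i);
        }
      }
  std::vector<std::array<int, 3>> off = neighbours(6);
  while (!stack.empty()) {
    long long p = stack.back();
    stack.pop_back();
    int x = (int)(p / ((long long)nz * ny));
    long long rem = p - (long long)x * nz * ny;
    int y = (int)(rem / nz);
    int z = (int)(rem % nz);
    for (size_t k = 0; k < off.size(); ++k) {
      int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      long long q = idx3(zz, yy, xx, nz, ny);
      if (!mask[q] && !outside[q]) {
        outside[q] = 1;
        stack.push_back(q);
      }
    }
  }
  LogicalVector filled(n);
  for (long long i = 0; i < n; ++i) filled[i] = mask[i] || !outside[i];
  filled.attr("dim") = dim;
  return filled;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher) with sample
// spacing w; f is read/written in place through strided access.
static void dt1d(std::vector<double> &f, std::vector<double> &d, int n,
                 double w) {
  static const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0;
  zb[0] = -INF;
  zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double xq = q * w, xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= zb[k]) {
        --k;
      } else
        break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * w;
    while (zb[k + 1] < xq) ++k;
    double dx = xq - v[k] * w;
    d[q] = dx * dx + f[v[k]];
  }
}

// Euclidean distance (physical units) from each foreground voxel to the
// nearest background voxel centre; anisotropic spacing (dz, dy, dx).
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  long long n = (long long)nz * ny * nx;
  const double INF = std::numeric_limits<double>::max() / 4;
  NumericVector g(n);
  for (long long i = 0; i < n; ++i) g[i] = mask[i] ? INF : 0.0;
  // pass along z (stride 1)
  {
    std::vector<double> f(nz), d(nz);
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        long long base = idx3(0, y, x, nz, ny);
        for (int z = 0; z < nz; ++z) f[z] = g[base + z];
        dt1d(f, d, nz, spacing[0]);
        for (int z = 0; z < nz; ++z) g[base + z] = d[z];
      }
  }
  // pass along y (stride nz)
  {
    std::vector<double> f(ny), d(ny);
    for (int x = 0; x < nx; ++x)
      for (int z = 0; z < nz; ++z) {
        for (int y = 0; y < ny; ++y) f[y] = g[idx3(z, y, x, nz, ny)];
        dt1d(f, d, ny, spacing[1]);
        for (int y = 0; y < ny; ++y) g[idx3(z, y, x, nz, ny)] = d[y];
      }
  }
  // pass along x (stride nz*ny)
  {
    std::vector<double> f(nx), d(nx);
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        for (int x = 0; x < nx; ++x) f[x] = g[idx3(z, y, x, nz, ny)];
        dt1d(f, d, nx, spacing[2]);
        for (int x = 0; x < nx; ++x) g[idx3(z, y, x, nz, ny)] = std::sqrt(d[x]);
      }
  }
  g.attr("dim") = dim;
  return g;
}

struct WsEntry {
  double elev;
  long long order;
  long long idx;
  int label;
};
struct WsCmp {
  bool operator()(const WsEntry &a, const WsEntry &b) const {
    if (a.elev != b.elev) return a.elev > b.elev;  // min-heap on elevation
    return a.order > b.order;                      // FIFO tie-break
  }
};

// Seeded watershed by priority flood: ascending elevation from seeds,
// restricted to mask. Deterministic for fixed inputs.
// [[Rcpp::export]]
IntegerVector cpp_watershed3d(NumericVector elev, IntegerVector seeds,
                              LogicalVector mask, IntegerVector dim,
                              int connectivity) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  long long n = (long long)nz * ny * nx;
  IntegerVector labels(n, 0);
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCmp> pq;
  long long counter = 0;
  for (long long i = 0; i < n; ++i) {
    if (seeds[i] > 0 && mask[i]) {
      labels[i] = seeds[i];
      pq.push({elev[i], counter++, i, seeds[i]});
    }
  }
  std::vector<std::array<int, 3>> off = neighbours(connectivity);
  while (!pq.empty()) {
    WsEntry e = pq.top();
    pq.pop();
    long long p = e.idx;
    int x = (int)(p / ((long long)nz * ny));
    long long rem = p - (long long)x * nz * ny;
    int y = (int)(rem / nz);
    int z = (int)(rem % nz);
    for (size_t k = 0; k < off.size(); ++k) {
      int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      long long q = idx3(zz, yy, xx, nz, ny);
      if (mask[q] && labels[q] == 0) {
        labels[q] = labels[p];
        pq.push({elev[q], counter++, q, labels[p]});
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}

// Separable Gaussian smoothing with per-axis sigma in voxels; reflecting
// boundaries. sigma <= 0 skips that axis.
// [[Rcpp::export]]
NumericVector cpp_gaussian3d(NumericVector vol, IntegerVector dim,
                             NumericVector sigma) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector out = clone(vol);
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> ker(2 * r + 1);
    double tot = 0;
    for (int i = -r; i <= r; ++i) {
      ker[i + r] = std::exp(-0.5 * (i * i) / (s * s));
      tot += ker[i + r];
    }
    for (size_t i = 0; i < ker.size(); ++i) ker[i] /= tot;
    int len = (axis == 0) ? nz : (axis == 1) ? ny : nx;
    std::vector<double> line(len), res(len);
    if (axis == 0) {
      for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y) {
          long long base = idx3(0, y, x, nz, ny);
          for (int z = 0; z < nz; ++z) line[z] = out[base + z];
          for (int z = 0; z < nz; ++z) {
            double acc = 0;
            for (int i = -r; i <= r; ++i) {
              int p = z + i;
              if (p < 0) p = -p - 1;
              if (p >= len) p = 2 * len - p - 1;
              acc += ker[i + r] * line[p];
            }
            res[z] = acc;
          }
          for (int z = 0; z < nz; ++z) out[base + z] = res[z];
        }
    } else if (axis == 1) {
      for (int x = 0; x < nx; ++x)
        for (int z = 0; z < nz; ++z) {
          for (int y = 0; y < ny; ++y) line[y] = out[idx3(z, y, x, nz, ny)];
          for (int y = 0; y < ny; ++y) {
            double acc = 0;
            for (int i = -r; i <= r; ++i) {
              int p = y + i;
              if (p < 0) p = -p - 1;
              if (p >= len) p = 2 * len - p - 1;
              acc += ker[i + r] * line[p];
            }
            res[y] = acc;
          }
          for (int y = 0; y < ny; ++y) out[idx3(z, y, x, nz, ny)] = res[y];
        }
    } else {
      for (int y = 0; y < ny; ++y)
        for (int z = 0; z < nz; ++z) {
          for (int x = 0; x < nx; ++x) line[x] = out[idx3(z, y, x, nz, ny)];
          for (int x = 0; x < nx; ++x) {
            double acc = 0;
            for (int i = -r; i <= r; ++i) {
              int p = x + i;
              if (p < 0) p = -p - 1;
              if (p >= len) p = 2 * len - p - 1;
              acc += ker[i + r] * line[p];
            }
            res[x] = acc;
          }
          for (int x = 0; x < nx; ++x) out[idx3(z, y, x, nz, ny)] = res[x];
        }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Voxels that are >= all 26 neighbours (within mask); candidate seeds.
// [[Rcpp::export]]
IntegerVector cpp_local_maxima26(NumericVector v, LogicalVector mask,
                                 IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<int> hits;
  std::vector<std::array<int, 3>> off = neighbours(26);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        long long i = idx3(z, y, x, nz, ny);
        if (!mask[i]) continue;
        double val = v[i];
        bool ok = true;
        for (size_t k = 0; k < off.size() && ok; ++k) {
          int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          if (v[idx3(zz, yy, xx, nz, ny)] > val) ok = false;
        }
        if (ok) hits.push_back((int)(i + 1));  // 1-based for R
      }
  return wrap(hits);
}

// Greedy minimum-separation peak pruning: peaks visited in decreasing value
// order (ties by index), kept if farther than min_sep (physical) from all
// previously kept peaks. coords: n x 3 matrix of physical (z,y,x).
// [[Rcpp::export]]
IntegerVector cpp_prune_peaks(NumericMatrix coords, NumericVector value,
                              double min_sep) {
  int n = coords.nrow();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (value[a] != value[b]) return value[a] > value[b];
    return a < b;
  });
  std::vector<int> kept;
  double s2 = min_sep * min_sep;
  for (int ii = 0; ii < n; ++ii) {
    int i = ord[ii];
    bool ok = true;
    for (size_t k = 0; k < kept.size() && ok; ++k) {
      int j = kept[k];
      double dz = coords(i, 0) - coords(j, 0);
      double dy = coords(i, 1) - coords(j, 1);
      double dx = coords(i, 2) - coords(j, 2);
      if (dz * dz + dy * dy + dx * dx < s2) ok = false;
    }
    if (ok) kept.push_back(i);
  }
  IntegerVector out(kept.size());
  for (size_t k = 0; k < kept.size(); ++k) out[k] = kept[k] + 1;
  return out;
}
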