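// Threshold-free cluster enhancement and connected-component labeling on
// 3D voxel grids, with 6/18/26 connectivity.
#include <Rcpp.h>
#include <array>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny, nz;
  std::vector<std::array<int, 3>> offsets;
  Grid(IntegerVector dims, int connectivity)
      : nx(dims[0]), ny(dims[1]), nz(dims[2]) {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
          if (m == 0) continue;
          if (connectivity == 6 && m > 1) continue;
          if (connectivity == 18 && m > 2) continue;
          offsets.push_back({dx, dy, dz});
        }
  }
};

// flood-fill labeling of the voxels where include[v] is true;
// labels are 1-based, 0 = background; returns number of components and
// fills sizes (indexed by label - 1)
int label_components_impl(const std::vector<char>& include, const Grid& g,
                          std::vector<int>& labels,
                          std::vector<int>& sizes) {
  const int n = g.nx * g.ny * g.nz;
  labels.assign(n, 0);
  sizes.clear();
  std::vector<int> stack;
  int next = 0;
  for (int v = 0; v < n; ++v) {
    if (!include[v] || labels[v]) continue;
    ++next;
    int size = 0;
    stack.push_back(v);
    labels[v] = next;
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      ++size;
      int cx = cur % g.nx, cy = (cur / g.nx) % g.ny, cz = cur / (g.nx * g.ny);
      for (const auto& o : g.offsets) {
        int x = cx + o[0], y = cy + o[1], z = cz + o[2];
        if (x < 0 || x >= g.nx || y < 0 || y >= g.ny || z < 0 || z >= g.nz)
          continue;
        int w = x + g.nx * (y + g.ny * z);
        if (include[w] && !labels[w]) {
          labels[w] = next;
          stack.push_back(w);
        }
      }
    }
    sizes.push_back(size);
  }
  return next;
}

}  // namespace

// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  Grid g(dims, connectivity);
  const int n = g.nx * g.ny * g.nz;
  if (mask.size() != n) stop("mask length does not match dims");
  std::vector<char> include(n);
  for (int v = 0; v < n; ++v) include[v] = mask[v] == TRUE;
  std::vector<int> labels, sizes;
  label_components_impl(include, g, labels, sizes);
  IntegerVector out(n);
  for (int v = 0; v < n; ++v) out[v] = labels[v];
  return out;
}

// TFCE: out[v] = sum over thresholds h = dh, 2dh, ... <= x[v] of
// e(h, v)^E * h^H * dh, where e(h, v) is the size of the connected
// component containing v among voxels with x >= h.
// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector x, IntegerVector dims, double E,
                       double H, double dh, int connectivity) {
  Grid g(dims, connectivity);
  const int n = g.nx * g.ny * g.nz;
  if (x.size() != n) stop("map length does not match dims");
  NumericVector out(n);
  double xmax = -1.0;
  for (int v = 0; v < n; ++v)
    if (x[v] > xmax) xmax = x[v];
  if (xmax <= 0) return out;
  const int kmax = (int) std::floor(xmax / dh + 1e-9);
  std::vector<char> include(n);
  std::vector<int> labels, sizes;
  for (int k = 1; k <= kmax; ++k) {
    const double h = k * dh;
    for (int v = 0; v < n; ++v) include[v] = x[v] >= h - 1e-12;
    label_components_impl(include, g, labels, sizes);
    const double hH = std::pow(h, H) * dh;
    for (int v = 0; v < n; ++v)
      if (labels[v]) out[v] += std::pow((double) sizes[labels[v] - 1], E) * hH;
  }
  return out;
}
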