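#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3-D binary morphology and connected components on logical arrays.
// Voxels outside the array bounds are treated as background throughout.

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// [[Rcpp::export]]
LogicalVector cpp_dilate(LogicalVector mask, IntegerVector dim, IntegerMatrix offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(mask.size());
  const int noff = offsets.nrow();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (!mask[idx3(x, y, z, nx, ny)]) continue;
        for (int o = 0; o < noff; ++o) {
          const int xx = x + offsets(o, 0), yy = y + offsets(o, 1), zz = z + offsets(o, 2);
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
          out[idx3(xx, yy, zz, nx, ny)] = true;
        }
      }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_erode(LogicalVector mask, IntegerVector dim, IntegerMatrix offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(mask.size());
  const int noff = offsets.nrow();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int i = idx3(x, y, z, nx, ny);
        if (!mask[i]) continue;
        bool keep = true;
        for (int o = 0; o < noff && keep; ++o) {
          const int xx = x + offsets(o, 0), yy = y + offsets(o, 1), zz = z + offsets(o, 2);
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            keep = false;          // outside counts as background
          else if (!mask[idx3(xx, yy, zz, nx, ny)])
            keep = false;
        }
        out[i] = keep;
      }
  return out;
}

// Connected-component labelling; connectivity 6 or 26. Labels are 1..k in
// first-encounter order (raster scan), so the labelling is deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = mask.size();
  IntegerVector lab(n);
  std::vector<int> stack;
  stack.reserve(1024);

  std::vector<int> dx, dy, dz;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        if (cx == 0 && cy == 0 && cz == 0) continue;
        const int manh = std::abs(cx) + std::abs(cy) + std::abs(cz);
        if (connectivity == 6 && manh != 1) continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }
  const int noff = (int)dx.size();

  int next = 0;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      const int cur = stack.back();
      stack.pop_back();
      const int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / (nx * ny);
      for (int o = 0; o < noff; ++o) {
        const int xx = cx + dx[o], yy = cy + dy[o], zz = cz + dz[o];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        const int j = idx3(xx, yy, zz, nx, ny);
        if (mask[j] && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
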