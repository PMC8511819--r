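#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Kuhn subdivision of each foreground voxel into 6 tetrahedra sharing the main
// diagonal (0,0,0)-(1,1,1). Every cube uses the same diagonal orientation, so
// the face diagonals of neighbouring cubes coincide and the global mesh is
// conforming. Node coordinates are returned in *grid* units (voxel-corner
// indices, midside nodes at half-integers); the caller applies spacing/origin.

static const int PERMS[6][3] = {
  {0, 1, 2}, {0, 2, 1}, {1, 0, 2}, {1, 2, 0}, {2, 0, 1}, {2, 1, 0}
};
static const int PARITY[6] = {+1, -1, -1, +1, +1, -1};

// local tet corner offsets for permutation p: v0=(0,0,0), v1=v0+e_p0,
// v2=v1+e_p1, v3=(1,1,1); odd permutations get v1/v2 swapped for positive volume
static void tet_corners(int p, int corners[4][3]) {
  int a[3] = {0, 0, 0};
  int b[3] = {0, 0, 0};
  b[PERMS[p][0]] = 1;
  int c[3] = {b[0], b[1], b[2]};
  c[PERMS[p][1]] = 1;
  int d[3] = {1, 1, 1};
  const bool swap = (PARITY[p] < 0);
  for (int k = 0; k < 3; ++k) {
    corners[0][k] = a[k];
    corners[1][k] = swap ? c[k] : b[k];
    corners[2][k] = swap ? b[k] : c[k];
    corners[3][k] = d[k];
  }
}

// edge numbering for TET10 midside nodes: (0,1),(1,2),(0,2),(0,3),(1,3),(2,3)
static const int EDGES[6][2] = {{0,1},{1,2},{0,2},{0,3},{1,3},{2,3}};

// [[Rcpp::export]]
List cpp_voxels_to_tets(IntegerVector labels, IntegerVector dim,
                        IntegerVector fg_codes, int order) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int64_t cx = nx + 1, cy = ny + 1;  // corner grid dims

  std::unordered_map<int, bool> fg;
  for (int i = 0; i < fg_codes.size(); ++i) fg[fg_codes[i]] = true;

  std::vector<int> vox;  // linear voxel indices of foreground
  for (int i = 0; i < labels.size(); ++i)
    if (fg.count(labels[i])) vox.push_back(i);
  if (vox.empty()) stop("no foreground voxels to mesh");

  const size_t ne = vox.size() * 6;
  const int npe = (order == 2) ? 10 : 4;

  std::unordered_map<int64_t, int> corner_id;   // corner grid index -> node
  std::unordered_map<int64_t, int> edge_id;     // packed corner pair -> node
  corner_id.reserve(vox.size() * 2);
  std::vector<double> nx_, ny_, nz_;            // node grid coords

  IntegerMatrix elems(ne, npe);
  IntegerVector part(ne), evox(ne);

  int tet_corner_cache[6][4][3];
  for (int p = 0; p < 6; ++p) tet_corners(p, tet_corner_cache[p]);

  auto corner_node = [&](int64_t gx, int64_t gy, int64_t gz) -> int {
    const int64_t key = gx + cx * (gy + cy * gz);
    auto it = corner_id.find(key);
    if (it != corner_id.end()) return it->second;
    const int id = (int)nx_.size();
    corner_id.emplace(key, id);
    nx_.push_back((double)gx);
    ny_.push_back((double)gy);
    nz_.push_back((double)gz);
    return id;
  };

  size_t e = 0;
  for (size_t v = 0; v < vox.size(); ++v) {
    const int lin = vox[v];
    const int vx = lin % nx, vy = (lin / nx) % ny, vz = lin / (nx * ny);
    for (int p = 0; p < 6; ++p, ++e) {
      int nid[10];
      for (int c = 0; c < 4; ++c) {
        const int *off = tet_corner_cache[p][c];
        nid[c] = corner_node(vx + off[0], vy + off[1], vz + off[2]);
      }
      if (order == 2) {
        for (int ed = 0; ed < 6; ++ed) {
          int a = nid[EDGES[ed][0]], b = nid[EDGES[ed][1]];
          if (a > b) std::swap(a, b);
          const int64_t key = ((int64_t)a << 31) | b;
          auto it = edge_id.find(key);
          int mid;
          if (it != edge_id.end()) mid = it->second;
          else {
            mid = (int)nx_.size();
            edge_id.emplace(key, mid);
            nx_.push_back(0.5 * (nx_[a] + nx_[b]));
            ny_.push_back(0.5 * (ny_[a] + ny_[b]));
            nz_.push_back(0.5 * (nz_[a] + nz_[b]));
          }
          nid[4 + ed] = mid;
        }
      }
      for (int c = 0; c < npe; ++c) elems(e, c) = nid[c] + 1;  // 1-based for R
      part[e] = labels[lin];
      evox[e] = lin + 1;
    }
  }

  const size_t nn = nx_.size();
  NumericMatrix nodes(nn, 3);
  for (size_t i = 0; i < nn; ++i) {
    nodes(i, 0) = nx_[i];
    nodes(i, 1) = ny_[i];
    nodes(i, 2) = nz_[i];
  }
  return List::create(_["nodes_grid"] = nodes, _["elements"] = elems,
                      _["part"] = part, _["voxel"] = evox);
}
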