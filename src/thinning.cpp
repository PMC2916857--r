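// 3D topological thinning for binary volumes: sequential border peeling with
// a simple-point test (26-connectivity for the object, 6-connectivity for the
// background, the standard digital-topology pairing), preserving curve
// endpoints.  Deleting one simple point at a time cannot change the topology
// of the foreground, so the skeleton stays connected wherever the input is.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

// neighborhood cube: 27 cells, center index 13 (dx,dy,dz in {-1,0,1})
inline int cubeIndex(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

// number of 26-connected foreground components among the 26 neighbors
int fgComponents26(const bool cube[27]) {
  bool seen[27] = {false};
  int comps = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !cube[s] || seen[s]) continue;
    ++comps;
    std::vector<int> stack(1, s);
    seen[s] = true;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int nx = cx + dx, ny = cy + dy, nz = cz + dz;
            if (nx < -1 || nx > 1 || ny < -1 || ny > 1 || nz < -1 || nz > 1)
              continue;
            int t = cubeIndex(nx, ny, nz);
            if (t == 13 || t == c || seen[t] || !cube[t]) continue;
            seen[t] = true;
            stack.push_back(t);
          }
    }
  }
  return comps;
}

// number of 6-connected background components within the 18-neighborhood
// that touch a face neighbor of the center
int bgComponents6(const bool cube[27]) {
  auto inN18 = [](int dx, int dy, int dz) {
    return !(dx != 0 && dy != 0 && dz != 0) && !(dx == 0 && dy == 0 && dz == 0);
  };
  bool seen[27] = {false};
  int comps = 0;
  const int faceOff[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int f = 0; f < 6; ++f) {
    int s = cubeIndex(faceOff[f][0], faceOff[f][1], faceOff[f][2]);
    if (cube[s] || seen[s]) continue;   // need a background face neighbor
    ++comps;
    std::vector<int> stack(1, s);
    seen[s] = true;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
      for (int k = 0; k < 6; ++k) {
        int nx = cx + faceOff[k][0], ny = cy + faceOff[k][1],
            nz = cz + faceOff[k][2];
        if (nx < -1 || nx > 1 || ny < -1 || ny > 1 || nz < -1 || nz > 1)
          continue;
        if (!inN18(nx, ny, nz)) continue;
        int t = cubeIndex(nx, ny, nz);
        if (seen[t] || cube[t]) continue;
        seen[t] = true;
        stack.push_back(t);
      }
    }
  }
  return comps;
}

} // namespace

// [[Rcpp::export]]
LogicalVector thin3dCpp(LogicalVector vol, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> v(n);
  for (R_xlen_t i = 0; i < n; ++i) v[i] = vol[i] == TRUE;

  auto at = [&](int x, int y, int z) -> char {
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return 0;
    return v[(R_xlen_t)x + nx * ((R_xlen_t)y + (R_xlen_t)ny * z)];
  };
  auto fillCube = [&](int x, int y, int z, bool cube[27]) {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          cube[cubeIndex(dx, dy, dz)] = at(x + dx, y + dy, z + dz) != 0;
  };
  auto fgNeighbors = [&](const bool cube[27]) {
    int c = 0;
    for (int s = 0; s < 27; ++s) if (s != 13 && cube[s]) ++c;
    return c;
  };

  const int dirOff[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  bool changed = true;
  bool cube[27];
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      // border voxels in direction d, then sequential topology-safe deletion
      std::vector<R_xlen_t> cand;
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            R_xlen_t idx = (R_xlen_t)x + nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
            if (!v[idx]) continue;
            if (!at(x + dirOff[d][0], y + dirOff[d][1], z + dirOff[d][2]))
              cand.push_back(idx);
          }
      for (R_xlen_t idx : cand) {
        if (!v[idx]) continue;
        int x = (int)(idx % nx);
        int y = (int)((idx / nx) % ny);
        int z = (int)(idx / ((R_xlen_t)nx * ny));
        fillCube(x, y, z, cube);
        int nb = fgNeighbors(cube);
        if (nb <= 1) continue;                       // endpoint or isolated
        if (fgComponents26(cube) != 1) continue;     // would split the object
        if (bgComponents6(cube) != 1) continue;      // would open a tunnel
        v[idx] = 0;
        changed = true;
      }
    }
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = v[i] != 0;
  out.attr("dim") = dims;
  return out;
}
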