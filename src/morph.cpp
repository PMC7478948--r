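#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 6-connected component labelling of a binary 3D volume (BFS).
// Returns integer labels, 0 = background, components numbered from 1
// in decreasing order of size.
// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> queue;
  std::vector<std::pair<R_xlen_t,int> > sizes; // (size, provisional label)
  int next = 0;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    queue.clear();
    queue.push_back(s);
    lab[s] = next;
    R_xlen_t size = 0, head = 0;
    while (head < (R_xlen_t)queue.size()) {
      const R_xlen_t p = queue[head++];
      ++size;
      const int x = (int)(p % nx), y = (int)((p / nx) % ny), z = (int)(p / sz);
      if (x > 0      && mask[p-sx] && !lab[p-sx]) { lab[p-sx]=next; queue.push_back(p-sx); }
      if (x < nx - 1 && mask[p+sx] && !lab[p+sx]) { lab[p+sx]=next; queue.push_back(p+sx); }
      if (y > 0      && mask[p-sy] && !lab[p-sy]) { lab[p-sy]=next; queue.push_back(p-sy); }
      if (y < ny - 1 && mask[p+sy] && !lab[p+sy]) { lab[p+sy]=next; queue.push_back(p+sy); }
      if (z > 0      && mask[p-sz] && !lab[p-sz]) { lab[p-sz]=next; queue.push_back(p-sz); }
      if (z < nz - 1 && mask[p+sz] && !lab[p+sz]) { lab[p+sz]=next; queue.push_back(p+sz); }
    }
    sizes.push_back(std::make_pair(size, next));
  }
  // renumber so label 1 is the largest component
  std::sort(sizes.begin(), sizes.end(),
            [](const std::pair<R_xlen_t,int>& a, const std::pair<R_xlen_t,int>& b) {
              return a.first > b.first;
            });
  std::vector<int> remap(next + 1, 0);
  for (size_t r = 0; r < sizes.size(); ++r) remap[sizes[r].second] = (int)r + 1;
  for (R_xlen_t s = 0; s < n; ++s) if (lab[s]) lab[s] = remap[lab[s]];
  return lab;
}

// Fill internal holes of a binary volume: background voxels not 6-connected
// to the grid border become foreground.
// [[Rcpp::export]]
IntegerVector cpp_fill_holes(IntegerVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> outside(n, 0);
  std::vector<R_xlen_t> queue;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  // seed with all border background voxels
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (x != 0 && x != nx-1 && y != 0 && y != ny-1 && z != 0 && z != nz-1)
          continue;
        const R_xlen_t p = (R_xlen_t)z * sz + (R_xlen_t)y * nx + x;
        if (!mask[p] && !outside[p]) { outside[p] = 1; queue.push_back(p); }
      }
  R_xlen_t head = 0;
  while (head < (R_xlen_t)queue.size()) {
    const R_xlen_t p = queue[head++];
    const int x = (int)(p % nx), y = (int)((p / nx) % ny), z = (int)(p / sz);
    if (x > 0      && !mask[p-sx] && !outside[p-sx]) { outside[p-sx]=1; queue.push_back(p-sx); }
    if (x < nx - 1 && !mask[p+sx] && !outside[p+sx]) { outside[p+sx]=1; queue.push_back(p+sx); }
    if (y > 0      && !mask[p-sy] && !outside[p-sy]) { outside[p-sy]=1; queue.push_back(p-sy); }
    if (y < ny - 1 && !mask[p+sy] && !outside[p+sy]) { outside[p+sy]=1; queue.push_back(p+sy); }
    if (z > 0      && !mask[p-sz] && !outside[p-sz]) { outside[p-sz]=1; queue.push_back(p-sz); }
    if (z < nz - 1 && !mask[p+sz] && !outside[p+sz]) { outside[p+sz]=1; queue.push_back(p+sz); }
  }
  IntegerVector out(n);
  for (R_xlen_t s = 0; s < n; ++s) out[s] = (mask[s] || !outside[s]) ? 1 : 0;
  return out;
}
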