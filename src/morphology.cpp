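#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 3-D connected-component labelling, 6-connectivity, iterative flood fill.
// Returns an integer array of the same shape: 0 = background, 1..k = labels
// in decreasing component size (label 1 is the largest component).
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out(n, 0);
  std::vector<R_xlen_t> stack;
  std::vector<std::pair<R_xlen_t, int> > sizes; // (size, provisional label)
  int lab = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (mask[start] != TRUE || out[start] != 0) continue;
    ++lab;
    R_xlen_t count = 0;
    stack.push_back(start);
    out[start] = lab;
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      ++count;
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[w] == TRUE && out[w] == 0) {
          out[w] = lab;
          stack.push_back(w);
        }
      }
    }
    sizes.push_back(std::make_pair(count, lab));
  }
  // relabel so that 1 = largest, ties broken by first occurrence
  std::stable_sort(sizes.begin(), sizes.end(),
                   [](const std::pair<R_xlen_t, int>& a,
                      const std::pair<R_xlen_t, int>& b) {
                     return a.first > b.first;
                   });
  std::vector<int> remap(lab + 1, 0);
  for (size_t i = 0; i < sizes.size(); ++i) remap[sizes[i].second] = (int)i + 1;
  for (R_xlen_t i = 0; i < n; ++i)
    if (out[i] != 0) out[i] = remap[out[i]];
  out.attr("dim") = dim;
  return out;
}

// 1-D squared-distance transform (Felzenszwalb & Huttenlocher), sampled on a
// grid with physical step `h` (mm). f is INF where no source, 0 at sources.
static void dt1d(const double* f, double* d, int n, double h,
                 std::vector<int>& v, std::vector<double>& z) {
  const double INF = std::numeric_limits<double>::infinity();
  // intersection of the parabolas rooted at samples q and p; INF when the
  // parabola at q never undercuts (no source there), -INF when it always
  // does (no source at p)
  auto intersect = [&](int q, int p) -> double {
    double fq = f[q], fp = f[p];
    if (fq == INF && fp == INF) return INF;
    double qq = (double)q * h, pp = (double)p * h;
    return ((fq + qq * qq) - (fp + pp * pp)) / (2 * qq - 2 * pp);
  };
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = intersect(q, v[k]);
    while (k > 0 && s <= z[k]) {
      --k;
      s = intersect(q, v[k]);
    }
    if (s <= z[k]) {      // k == 0: new parabola dominates everywhere
      v[0] = q;
      z[0] = -INF;
      z[1] = INF;
    } else {
      ++k;
      v[k] = q;
      z[k] = s;
      z[k + 1] = INF;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = (double)q * h;
    while (z[k + 1] < qq) ++k;
    double pp = (double)v[k] * h;
    d[q] = (qq - pp) * (qq - pp) + f[v[k]];
  }
}

// Exact Euclidean distance transform of a 3-D mask with anisotropic voxel
// spacing: distance (mm) from every voxel to the nearest TRUE voxel.
// [[Rcpp::export(name = ".edt_3d")]]
NumericVector edt_3d(LogicalVector mask, IntegerVector dim,
                     NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = (mask[i] == TRUE) ? 0.0 : INF;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), g(nmax), zz(nmax + 1);
  std::vector<int> vv(nmax);
  // x pass
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      for (int x = 0; x < nx; ++x) f[x] = d[base + x];
      dt1d(f.data(), g.data(), nx, spacing[0], vv, zz);
      for (int x = 0; x < nx; ++x) d[base + x] = g[x];
    }
  // y pass
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * ny * (R_xlen_t)z;
      for (int y = 0; y < ny; ++y) f[y] = d[base + (R_xlen_t)nx * y];
      dt1d(f.data(), g.data(), ny, spacing[1], vv, zz);
      for (int y = 0; y < ny; ++y) d[base + (R_xlen_t)nx * y] = g[y];
    }
  // z pass
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * y;
      R_xlen_t step = (R_xlen_t)nx * ny;
      for (int z = 0; z < nz; ++z) f[z] = d[base + step * z];
      dt1d(f.data(), g.data(), nz, spacing[2], vv, zz);
      for (int z = 0; z < nz; ++z) d[base + step * z] = g[z];
    }
  for (R_xlen_t i = 0; i < n; ++i) d[i] = std::sqrt(d[i]);
  d.attr("dim") = dim;
  return d;
}
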