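// 3D geometry utilities: anisotropic squared Euclidean distance transform
// (Felzenszwalb & Huttenlocher lower-envelope algorithm, applied separably)
// and 6-connected component labelling for mask cleanup.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

static const double INF = 1e20;

// 1D squared distance transform on samples f at positions i*s, i = 0..n-1.
static void dt1d(std::vector<double>& f, std::vector<double>& d, double s) {
  int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int q = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int i = 1; i < n; ++i) {
    double xi = i * s;
    while (true) {
      double xv = v[q] * s;
      double sint = ((f[i] + xi * xi) - (f[v[q]] + xv * xv)) / (2 * xi - 2 * xv);
      if (sint <= z[q]) { --q; continue; }
      ++q; v[q] = i; z[q] = sint; z[q + 1] = INF; break;
    }
  }
  q = 0;
  for (int i = 0; i < n; ++i) {
    double xi = i * s;
    while (z[q + 1] < xi) ++q;
    double dx = xi - v[q] * s;
    d[i] = dx * dx + f[v[q]];
  }
}

// Distance (mm) from every voxel to the nearest TRUE voxel.
// [[Rcpp::export]]
NumericVector mask_edt(LogicalVector mask, NumericVector spacing) {
  IntegerVector dm = mask.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> g(n);
  for (size_t i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : INF;
  std::vector<double> f, d;
  // axis 1 (fastest-varying)
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      size_t off = (size_t)nx * (y + (size_t)ny * z);
      for (int x = 0; x < nx; ++x) f[x] = g[off + x];
      dt1d(f, d, spacing[0]);
      for (int x = 0; x < nx; ++x) g[off + x] = d[x];
    }
  // axis 2
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      size_t base = x + (size_t)nx * ny * z;
      for (int y = 0; y < ny; ++y) f[y] = g[base + (size_t)nx * y];
      dt1d(f, d, spacing[1]);
      for (int y = 0; y < ny; ++y) g[base + (size_t)nx * y] = d[y];
    }
  // axis 3
  f.resize(nz); d.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      size_t base = x + (size_t)nx * y;
      for (int z = 0; z < nz; ++z) f[z] = g[base + (size_t)nx * ny * z];
      dt1d(f, d, spacing[2]);
      for (int z = 0; z < nz; ++z) g[base + (size_t)nx * ny * z] = d[z];
    }
  NumericVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  out.attr("dim") = dm;
  return out;
}

// Largest 6-connected foreground component of a 3D mask.
// [[Rcpp::export]]
LogicalVector largest_component(LogicalVector mask) {
  IntegerVector dm = mask.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<int> lab(n, 0);
  int nlab = 0, best = 0; size_t bestsz = 0;
  std::queue<size_t> qu;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++nlab; size_t sz = 0;
    lab[s] = nlab; qu.push(s);
    while (!qu.empty()) {
      size_t v = qu.front(); qu.pop(); ++sz;
      int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / ((size_t)nx * ny));
      const int dx[6] = {1,-1,0,0,0,0}, dy[6] = {0,0,1,-1,0,0}, dz[6] = {0,0,0,0,1,-1};
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        size_t u = xx + (size_t)nx * (yy + (size_t)ny * zz);
        if (mask[u] && !lab[u]) { lab[u] = nlab; qu.push(u); }
      }
    }
    if (sz > bestsz) { bestsz = sz; best = nlab; }
  }
  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = (lab[i] == best && best > 0);
  out.attr("dim") = dm;
  return out;
}
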