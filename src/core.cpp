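#include <Rcpp.h>
#include <queue>
#include <map>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Arrays follow R column-major layout with dim = (d1, d2, d3) = (z, y, x):
// linear index = i1 + d1*(i2 + d2*i3), all 0-based here.

static inline int reflect_idx(int i, int n) {
  // symmetric reflection with edge repeated: -1 -> 0, n -> n-1
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

static inline int periodic_idx(int i, int n) {
  i %= n;
  if (i < 0) i += n;
  return i;
}

// [[Rcpp::export]]
NumericVector conv_axis_cpp(NumericVector vol, IntegerVector dims,
                            NumericVector kernel, int axis, int boundary) {
  // axis in 1..3; boundary 0 = reflect, 1 = periodic; kernel length odd
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int klen = kernel.size(), kh = klen / 2;
  NumericVector out(vol.size());
  const int n = (axis == 1) ? d1 : (axis == 2) ? d2 : d3;
  const int stride = (axis == 1) ? 1 : (axis == 2) ? d1 : d1 * d2;

  // iterate over all lines along `axis`
  const int o1 = (axis == 1) ? d2 : d1;
  const int o2 = (axis == 3) ? d2 : d3;
  const int s1 = (axis == 1) ? d1 : 1;
  const int s2 = (axis == 3) ? d1 : d1 * d2;
  for (int b = 0; b < o2; ++b) {
    for (int a = 0; a < o1; ++a) {
      const int base = a * s1 + b * s2;
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int k = 0; k < klen; ++k) {
          int j = i + k - kh;
          j = boundary == 1 ? periodic_idx(j, n) : reflect_idx(j, n);
          acc += kernel[k] * vol[base + j * stride];
        }
        out[base + i * stride] = acc;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// SLIC-style supervoxels
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List slic_cpp(NumericVector vol, IntegerVector dims, IntegerVector shape,
              NumericVector spacing, double compactness, int n_iter) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int s1 = shape[0], s2 = shape[1], s3 = shape[2];
  const int n1 = (d1 + s1 - 1) / s1, n2 = (d2 + s2 - 1) / s2,
            n3 = (d3 + s3 - 1) / s3;
  const int K = n1 * n2 * n3;
  const double w1 = spacing[0], w2 = spacing[1], w3 = spacing[2];
  const double m = compactness / 100.0; // intensity is in [0,1]

  std::vector<double> cz(K), cy(K), cx(K), ci(K);
  // seed at cell centers of the regular grid
  {
    int k = 0;
    for (int k3 = 0; k3 < n3; ++k3)
      for (int k2 = 0; k2 < n2; ++k2)
        for (int k1 = 0; k1 < n1; ++k1, ++k) {
          int z = std::min(d1 - 1, k1 * s1 + s1 / 2);
          int y = std::min(d2 - 1, k2 * s2 + s2 / 2);
          int x = std::min(d3 - 1, k3 * s3 + s3 / 2);
          // perturb to lowest-gradient voxel in the 3x3x3 neighborhood
          double best_g = std::numeric_limits<double>::max();
          int bz = z, by = y, bx = x;
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                int zz = z + dz, yy = y + dy, xx = x + dx;
                if (zz < 0 || zz >= d1 || yy < 0 || yy >= d2 || xx < 0 ||
                    xx >= d3)
                  continue;
                double g = 0.0;
                const double v0 = vol[zz + d1 * (yy + d2 * xx)];
                const int nb[6][3] = {{1, 0, 0},  {-1, 0, 0}, {0, 1, 0},
                                      {0, -1, 0}, {0, 0, 1},  {0, 0, -1}};
                for (int q = 0; q < 6; ++q) {
                  int z2 = reflect_idx(zz + nb[q][0], d1);
                  int y2 = reflect_idx(yy + nb[q][1], d2);
                  int x2 = reflect_idx(xx + nb[q][2], d3);
                  double dv = vol[z2 + d1 * (y2 + d2 * x2)] - v0;
                  g += dv * dv;
                }
                if (g < best_g) {
                  best_g = g;
                  bz = zz; by = yy; bx = xx;
                }
              }
          cz[k] = bz; cy[k] = by; cx[k] = bx;
          ci[k] = vol[bz + d1 * (by + d2 * bx)];
        }
  }

  std::vector<int> lab(vol.size(), -1);
  std::vector<double> dist(vol.size());

  for (int it = 0; it < n_iter; ++it) {
    std::fill(dist.begin(), dist.end(), std::numeric_limits<double>::max());
    std::fill(lab.begin(), lab.end(), -1);
    for (int k = 0; k < K; ++k) {
      const int z0 = std::max(0, (int)std::floor(cz[k]) - s1);
      const int z1 = std::min(d1 - 1, (int)std::floor(cz[k]) + s1);
      const int y0 = std::max(0, (int)std::floor(cy[k]) - s2);
      const int y1 = std::min(d2 - 1, (int)std::floor(cy[k]) + s2);
      const int x0 = std::max(0, (int)std::floor(cx[k]) - s3);
      const int x1 = std::min(d3 - 1, (int)std::floor(cx[k]) + s3);
      for (int x = x0; x <= x1; ++x)
        for (int y = y0; y <= y1; ++y)
          for (int z = z0; z <= z1; ++z) {
            const int idx = z + d1 * (y + d2 * x);
            const double di = std::fabs(vol[idx] - ci[k]);
            const double ez = w1 * (z - cz[k]) / s1;
            const double ey = w2 * (y - cy[k]) / s2;
            const double ex = w3 * (x - cx[k]) / s3;
            const double ds = std::sqrt(ez * ez + ey * ey + ex * ex);
            const double D = di + m * ds;
            // strict < keeps the lowest cluster id on ties (determinism)
            if (D < dist[idx]) {
              dist[idx] = D;
              lab[idx] = k;
            }
          }
    }
    // update centers
    std::vector<double> az(K, 0), ay(K, 0), ax(K, 0), ai(K, 0);
    std::vector<int> cnt(K, 0);
    for (int x = 0; x < d3; ++x)
      for (int y = 0; y < d2; ++y)
        for (int z = 0; z < d1; ++z) {
          const int idx = z + d1 * (y + d2 * x);
          const int k = lab[idx];
          if (k < 0) continue;
          az[k] += z; ay[k] += y; ax[k] += x; ai[k] += vol[idx]; cnt[k]++;
        }
    for (int k = 0; k < K; ++k)
      if (cnt[k] > 0) {
        cz[k] = az[k] / cnt[k]; cy[k] = ay[k] / cnt[k];
        cx[k] = ax[k] / cnt[k]; ci[k] = ai[k] / cnt[k];
      }
  }

  // any voxel missed by all search windows (possible with tiny shapes):
  // assign nearest center by spatial distance
  for (size_t idx = 0; idx < lab.size(); ++idx)
    if (lab[idx] == -1) {
      const int z = idx % d1, y = (idx / d1) % d2, x = idx / (d1 * d2);
      double best = std::numeric_limits<double>::max();
      int bk = 0;
      for (int k = 0; k < K; ++k) {
        const double dz = z - cz[k], dy = y - cy[k], dx = x - cx[k];
        const double d = dz * dz + dy * dy + dx * dx;
        if (d < best) { best = d; bk = k; }
      }
      lab[idx] = bk;
    }

  IntegerVector out(vol.size());
  for (size_t i = 0; i < lab.size(); ++i) out[i] = lab[i] + 1;
  out.attr("dim") = dims;
  return List::create(_["labels"] = out, _["k"] = K);
}

// Relabel a partition so every region is 6-connected; fragments smaller than
// min_size are merged into the adjacent region discovered just before them in
// raster order (standard SLIC connectivity enforcement, deterministic).
// [[Rcpp::export]]
List enforce_connectivity_cpp(IntegerVector labels, IntegerVector dims,
                              int min_size) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int n = labels.size();
  std::vector<int> nl(n, -1);
  IntegerVector out(n);
  const int dz[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, 1, -1};
  int next_label = 0;
  std::vector<int> comp;
  comp.reserve(1024);

  for (int x0 = 0; x0 < d3; ++x0)
    for (int y0 = 0; y0 < d2; ++y0)
      for (int z0 = 0; z0 < d1; ++z0) {
        const int start = z0 + d1 * (y0 + d2 * x0);
        if (nl[start] >= 0) continue;
        const int old = labels[start];
        comp.clear();
        comp.push_back(start);
        nl[start] = next_label;
        int adj = -1; // an already-relabeled neighboring region
        size_t head = 0;
        while (head < comp.size()) {
          const int idx = comp[head++];
          const int z = idx % d1, y = (idx / d1) % d2, x = idx / (d1 * d2);
          for (int q = 0; q < 6; ++q) {
            const int zz = z + dz[q], yy = y + dy[q], xx = x + dx[q];
            if (zz < 0 || zz >= d1 || yy < 0 || yy >= d2 || xx < 0 ||
                xx >= d3)
              continue;
            const int jdx = zz + d1 * (yy + d2 * xx);
            if (nl[jdx] < 0 && labels[jdx] == old) {
              nl[jdx] = next_label;
              comp.push_back(jdx);
            } else if (nl[jdx] >= 0 && nl[jdx] != next_label) {
              adj = nl[jdx];
            }
          }
        }
        if ((int)comp.size() < min_size && adj >= 0) {
          for (int idx : comp) nl[idx] = adj; // absorb fragment
        } else {
          ++next_label;
        }
      }

  for (int i = 0; i < n; ++i) out[i] = nl[i] + 1;
  out.attr("dim") = dims;
  return List::create(_["labels"] = out, _["k"] = next_label);
}

// Connected components of a logical mask; 0 outside, 1..k inside,
// discovery in raster order. connectivity: 6 or 26.
// [[Rcpp::export]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims,
                           int connectivity) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int n = mask.size();
  IntegerVector out(n, 0);
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        if (connectivity == 6 && std::abs(dz) + std::abs(dy) + std::abs(dx) > 1)
          continue;
        offs.push_back({dz, dy, dx});
      }
  int k = 0;
  std::vector<int> stack;
  for (int x0 = 0; x0 < d3; ++x0)
    for (int y0 = 0; y0 < d2; ++y0)
      for (int z0 = 0; z0 < d1; ++z0) {
        const int start = z0 + d1 * (y0 + d2 * x0);
        if (!mask[start] || out[start] != 0) continue;
        ++k;
        out[start] = k;
        stack.clear();
        stack.push_back(start);
        while (!stack.empty()) {
          const int idx = stack.back();
          stack.pop_back();
          const int z = idx % d1, y = (idx / d1) % d2, x = idx / (d1 * d2);
          for (auto &o : offs) {
            const int zz = z + o[0], yy = y + o[1], xx = x + o[2];
            if (zz < 0 || zz >= d1 || yy < 0 || yy >= d2 || xx < 0 ||
                xx >= d3)
              continue;
            const int jdx = zz + d1 * (yy + d2 * xx);
            if (mask[jdx] && out[jdx] == 0) {
              out[jdx] = k;
              stack.push_back(jdx);
            }
          }
        }
      }
  out.attr("dim") = dims;
  return out;
}

// Region adjacency over 6-neighborhood faces: returns matrix (i, j, faces)
// with i < j, labels assumed 1..K.
// [[Rcpp::export]]
IntegerMatrix region_adjacency_cpp(IntegerVector labels, IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  std::map<std::pair<int, int>, int> edges;
  for (int x = 0; x < d3; ++x)
    for (int y = 0; y < d2; ++y)
      for (int z = 0; z < d1; ++z) {
        const int idx = z + d1 * (y + d2 * x);
        const int a = labels[idx];
        if (z + 1 < d1) {
          const int b = labels[idx + 1];
          if (a != b) edges[{std::min(a, b), std::max(a, b)}]++;
        }
        if (y + 1 < d2) {
          const int b = labels[idx + d1];
          if (a != b) edges[{std::min(a, b), std::max(a, b)}]++;
        }
        if (x + 1 < d3) {
          const int b = labels[idx + d1 * d2];
          if (a != b) edges[{std::min(a, b), std::max(a, b)}]++;
        }
      }
  IntegerMatrix out(edges.size(), 3);
  int r = 0;
  for (auto &e : edges) {
    out(r, 0) = e.first.first;
    out(r, 1) = e.first.second;
    out(r, 2) = e.second;
    ++r;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// distance to the nearest TRUE voxel. INF where no seed on the whole grid.
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::max();
  z[1] = std::numeric_limits<double>::max();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) {
        --k;
      } else
        break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::max();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const double INF = 1e20;
  NumericVector g(mask.size());
  for (int i = 0; i < mask.size(); ++i) g[i] = mask[i] ? 0.0 : INF;

  const int dmax = std::max(d1, std::max(d2, d3));
  std::vector<double> f(dmax), d(dmax);

  // pass along each axis
  for (int axis = 1; axis <= 3; ++axis) {
    const int n = (axis == 1) ? d1 : (axis == 2) ? d2 : d3;
    const int stride = (axis == 1) ? 1 : (axis == 2) ? d1 : d1 * d2;
    const int o1 = (axis == 1) ? d2 : d1;
    const int o2 = (axis == 3) ? d2 : d3;
    const int s1 = (axis == 1) ? d1 : 1;
    const int s2 = (axis == 3) ? d1 : d1 * d2;
    for (int b = 0; b < o2; ++b)
      for (int a = 0; a < o1; ++a) {
        const int base = a * s1 + b * s2;
        for (int i = 0; i < n; ++i) f[i] = g[base + i * stride];
        dt1d(f, d, n);
        for (int i = 0; i < n; ++i) g[base + i * stride] = d[i];
      }
  }
  g.attr("dim") = dims;
  return g;
}
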