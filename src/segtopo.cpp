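#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Voxel-grid kernels shared by the metrics and topology modules.
// Index convention: column-major (R order), 0-based internally.

// ---------------------------------------------------------------------------
// Connected-component labeling of a 3D binary mask under 6/18/26 adjacency.
// Returns an integer label grid (0 = background, 1..n = components).
// [[Rcpp::export]]
List cpp_label_components(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbour offsets
  std::vector<int> ox, oy, oz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
      }
  const int nn = (int)ox.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int comp = 0;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++comp;
    labels[i] = comp;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int x = (int)(cur % d1);
      int y = (int)((cur / d1) % d2);
      int z = (int)(cur / ((R_xlen_t)d1 * d2));
      for (int k = 0; k < nn; ++k) {
        int xx = x + ox[k], yy = y + oy[k], zz = z + oz[k];
        if (xx < 0 || xx >= d1 || yy < 0 || yy >= d2 || zz < 0 || zz >= d3) continue;
        R_xlen_t j = xx + (R_xlen_t)d1 * (yy + (R_xlen_t)d2 * zz);
        if (mask[j] && labels[j] == 0) {
          labels[j] = comp;
          stack.push_back(j);
        }
      }
    }
  }
  return List::create(_["count"] = comp, _["labels"] = labels);
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher), with
// anisotropic sample spacing in physical units. Returns, for every voxel,
// the distance (mm) to the nearest site voxel; Inf if there are no sites.

static inline double para_intersect(const std::vector<double>& f, int p, int q, double w) {
  // abscissa where the parabola rooted at sample q overtakes the one at p (p < q)
  const double INF = std::numeric_limits<double>::infinity();
  if (f[p] == INF) return -INF;
  double xp = p * w, xq = q * w;
  return ((f[q] + xq * xq) - (f[p] + xp * xp)) / (2.0 * xq - 2.0 * xp);
}

static void dt1d(std::vector<double>& f, int n, double w) {
  // squared-distance lower envelope of parabolas rooted at x_i = i * w;
  // samples with f == Inf carry no parabola
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> d(n), z(n + 1);
  std::vector<int> v(n);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s = para_intersect(f, v[k], q, w);
    while (k >= 0 && s <= z[k]) {
      --k;
      if (k >= 0) s = para_intersect(f, v[k], q, w);
    }
    if (k < 0) {
      k = 0;
      v[0] = q;
      z[0] = -INF;
    } else {
      ++k;
      v[k] = q;
      z[k] = s;
    }
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * w;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * w;
    d[q] = (f[v[k]] == INF) ? INF : (xq - xv) * (xq - xv) + f[v[k]];
  }
  f.swap(d);
}

// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector sites, IntegerVector dims, NumericVector spacing) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (sites.size() != n) stop("sites length does not match dims");
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = sites[i] ? 0.0 : INF;

  std::vector<double> line;
  // pass along x
  line.resize(d1);
  for (int z = 0; z < d3; ++z)
    for (int y = 0; y < d2; ++y) {
      R_xlen_t base = (R_xlen_t)d1 * (y + (R_xlen_t)d2 * z);
      bool any = false;
      for (int x = 0; x < d1; ++x) { line[x] = out[base + x]; if (line[x] < INF) any = true; }
      if (!any) continue;
      dt1d(line, d1, spacing[0]);
      for (int x = 0; x < d1; ++x) out[base + x] = line[x];
    }
  // pass along y
  line.resize(d2);
  for (int z = 0; z < d3; ++z)
    for (int x = 0; x < d1; ++x) {
      R_xlen_t base = x + (R_xlen_t)d1 * d2 * z;
      bool any = false;
      for (int y = 0; y < d2; ++y) { line[y] = out[base + (R_xlen_t)d1 * y]; if (line[y] < INF) any = true; }
      if (!any) continue;
      dt1d(line, d2, spacing[1]);
      for (int y = 0; y < d2; ++y) out[base + (R_xlen_t)d1 * y] = line[y];
    }
  // pass along z
  line.resize(d3);
  const R_xlen_t plane = (R_xlen_t)d1 * d2;
  for (int y = 0; y < d2; ++y)
    for (int x = 0; x < d1; ++x) {
      R_xlen_t base = x + (R_xlen_t)d1 * y;
      bool any = false;
      for (int z = 0; z < d3; ++z) { line[z] = out[base + plane * z]; if (line[z] < INF) any = true; }
      if (!any) continue;
      dt1d(line, d3, spacing[2]);
      for (int z = 0; z < d3; ++z) out[base + plane * z] = line[z];
    }
  for (R_xlen_t i = 0; i < n; ++i)
    if (out[i] < INF) out[i] = std::sqrt(out[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Rank of a sparse 0/1 incidence matrix over GF(2), by Gaussian elimination
// on bit-packed rows. Backbone of the boundary-matrix homology oracle.
// [[Rcpp::export]]
int cpp_gf2_rank(IntegerVector ri, IntegerVector ci, int nrow, int ncol) {
  if (nrow == 0 || ncol == 0) return 0;
  const int words = (ncol + 63) / 64;
  std::vector<std::vector<uint64_t>> rows(nrow, std::vector<uint64_t>(words, 0));
  for (R_xlen_t k = 0; k < ri.size(); ++k) {
    int r = ri[k] - 1, c = ci[k] - 1;
    if (r < 0 || r >= nrow || c < 0 || c >= ncol) stop("index out of bounds");
    rows[r][c / 64] ^= (uint64_t)1 << (c % 64); // duplicate entries cancel mod 2
  }
  int rank = 0;
  for (int c = 0; c < ncol && rank < nrow; ++c) {
    int w = c / 64;
    uint64_t bit = (uint64_t)1 << (c % 64);
    int pivot = -1;
    for (int r = rank; r < nrow; ++r)
      if (rows[r][w] & bit) { pivot = r; break; }
    if (pivot < 0) continue;
    std::swap(rows[rank], rows[pivot]);
    for (int r = 0; r < nrow; ++r) {
      if (r != rank && (rows[r][w] & bit)) {
        for (int t = w; t < words; ++t) rows[r][t] ^= rows[rank][t];
      }
    }
    ++rank;
  }
  return rank;
}
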