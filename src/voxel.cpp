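// Voxel ownership engine: capsule rasterization, breadth-first fibre radial
// growth with per-fibre Euclidean radius caps, boundary-distance transform
// (6-connectivity) and inner-mask extraction by erosion depth.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline std::int64_t vidx(int x, int y, int z, int nx, int ny) {
  return (std::int64_t)z * nx * ny + (std::int64_t)y * nx + x;
}

// squared distance from point c to segment (P[a], P[a+1]) and interpolation t
static inline double seg_dist2(const double* c, const double* A, const double* B,
                               double& t) {
  double d[3] = {B[0]-A[0], B[1]-A[1], B[2]-A[2]};
  double w[3] = {c[0]-A[0], c[1]-A[1], c[2]-A[2]};
  double a = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
  t = (a > 1e-24) ? (w[0]*d[0] + w[1]*d[1] + w[2]*d[2]) / a : 0.0;
  if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
  double e[3] = {w[0]-t*d[0], w[1]-t*d[1], w[2]-t*d[2]};
  return e[0]*e[0] + e[1]*e[1] + e[2]*e[2];
}

// Rasterize capsule chains.  owner: 0 = unclaimed, k = fibre k (1-based).
// seg: 1-based capsule index that claimed the voxel.  Discretization
// conflicts (only possible between touching fibres) resolve to the lowest
// fibre id.
// [[Rcpp::export]]
List cpp_rasterize(IntegerVector dim, double res, NumericVector origin,
                   NumericMatrix P, NumericVector Rad,
                   IntegerVector capA, IntegerVector capFib) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::int64_t nvox = (std::int64_t)nx * ny * nz;
  IntegerVector owner(nvox, 0), seg(nvox, 0);
  int* ow = owner.begin(); int* sg = seg.begin();
  int nc = capA.size();
  for (int ci = 0; ci < nc; ++ci) {
    int a = capA[ci];
    double A[3] = {P(a,0), P(a,1), P(a,2)};
    double B[3] = {P(a+1,0), P(a+1,1), P(a+1,2)};
    double r0 = Rad[a], r1 = Rad[a+1];
    double rmax = std::max(r0, r1);
    int lo[3], hi[3];
    for (int k = 0; k < 3; ++k) {
      double mn = std::min(A[k], B[k]) - rmax, mx = std::max(A[k], B[k]) + rmax;
      lo[k] = (int)std::floor((mn - origin[k]) / res - 0.5);
      hi[k] = (int)std::ceil((mx - origin[k]) / res - 0.5);
    }
    lo[0] = std::max(lo[0], 0); lo[1] = std::max(lo[1], 0); lo[2] = std::max(lo[2], 0);
    hi[0] = std::min(hi[0], nx - 1); hi[1] = std::min(hi[1], ny - 1); hi[2] = std::min(hi[2], nz - 1);
    int fib = capFib[ci] + 1;
    for (int z = lo[2]; z <= hi[2]; ++z)
      for (int y = lo[1]; y <= hi[1]; ++y) {
        std::int64_t base = vidx(0, y, z, nx, ny);
        double c[3];
        c[1] = origin[1] + (y + 0.5) * res;
        c[2] = origin[2] + (z + 0.5) * res;
        for (int x = lo[0]; x <= hi[0]; ++x) {
          std::int64_t v = base + x;
          if (ow[v] != 0 && ow[v] <= fib) continue;
          c[0] = origin[0] + (x + 0.5) * res;
          double t, d2 = seg_dist2(c, A, B, t);
          double r = (1.0 - t) * r0 + t * r1;
          if (d2 <= r * r) { ow[v] = fib; sg[v] = ci + 1; }
        }
      }
  }
  return List::create(_["owner"] = owner, _["seg"] = seg);
}

// Randomly demote owned voxels to unclaimed with probability 1 - keep
// (random-in-capsule seeding).  Uses R's RNG.
// [[Rcpp::export]]
void cpp_thin_mask(IntegerVector owner, IntegerVector seg, double keep) {
  RNGScope scope;
  std::int64_t n = owner.size();
  int* ow = owner.begin(); int* sg = seg.begin();
  for (std::int64_t v = 0; v < n; ++v)
    if (ow[v] != 0 && R::unif_rand() > keep) { ow[v] = 0; sg[v] = 0; }
}

// Breadth-first radial growth.  Each layer adds, in seeded random order,
// unclaimed voxels 6-adjacent to a fibre's mask whose centre lies within the
// fibre's capped radius (capR, um, already including any overshoot factor)
// of the fibre's skeleton.  Parent capsule indices are tracked so the
// distance query only inspects a window of nearby capsules.  Stops after
// max_layers, when no voxel can be claimed, or when the number of owned
// voxels inside the analysis region reaches stop_count (exact, mid-layer).
// [[Rcpp::export]]
List cpp_grow(IntegerVector owner, IntegerVector seg, IntegerVector dim,
              double res, NumericVector origin,
              NumericMatrix P, NumericVector capR,
              IntegerVector capA, IntegerVector capFib,
              IntegerVector fibCapLo, IntegerVector fibCapHi,
              int max_layers, double stop_count,
              IntegerVector region_lo, IntegerVector region_hi,
              int window = 3) {
  RNGScope scope;
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int* ow = owner.begin(); int* sg = seg.begin();
  std::int64_t nvox = (std::int64_t)nx * ny * nz;
  const int rl0 = region_lo[0], rl1 = region_lo[1], rl2 = region_lo[2];
  const int rh0 = region_hi[0], rh1 = region_hi[1], rh2 = region_hi[2];
  auto in_region = [&](int x, int y, int z) {
    return x >= rl0 && x <= rh0 && y >= rl1 && y <= rh1 && z >= rl2 && z <= rh2;
  };
  // initial region count and frontier
  double region_owned = 0.0;
  std::vector<std::int64_t> frontier;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        std::int64_t v = vidx(x, y, z, nx, ny);
        if (ow[v] == 0) continue;
        if (in_region(x, y, z)) region_owned += 1.0;
        bool edge = (x > 0 && ow[v-1] == 0) || (x < nx-1 && ow[v+1] == 0) ||
                    (y > 0 && ow[v-nx] == 0) || (y < ny-1 && ow[v+nx] == 0) ||
                    (z > 0 && ow[v-(std::int64_t)nx*ny] == 0) ||
                    (z < nz-1 && ow[v+(std::int64_t)nx*ny] == 0);
        if (edge) frontier.push_back(v);
      }
  double claimed = 0.0;
  int layers_done = 0;
  bool hit_target = (stop_count >= 0 && region_owned >= stop_count);
  const std::int64_t stepz = (std::int64_t)nx * ny;
  for (int layer = 0; layer < max_layers && !hit_target && !frontier.empty(); ++layer) {
    // seeded Fisher-Yates shuffle of the frontier
    for (std::int64_t i = (std::int64_t)frontier.size() - 1; i > 0; --i) {
      std::int64_t j = (std::int64_t)std::floor(R::unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(frontier[i], frontier[j]);
    }
    std::vector<std::int64_t> next;
    for (std::int64_t fi = 0; fi < (std::int64_t)frontier.size() && !hit_target; ++fi) {
      std::int64_t u = frontier[fi];
      int f = ow[u];
      if (f == 0) continue;
      int pseg = sg[u] - 1;
      int ux = (int)(u % nx), uy = (int)((u / nx) % ny), uz = (int)(u / stepz);
      const int offs[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
      for (int d = 0; d < 6; ++d) {
        int x = ux + offs[d][0], y = uy + offs[d][1], z = uz + offs[d][2];
        if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) continue;
        std::int64_t v = vidx(x, y, z, nx, ny);
        if (ow[v] != 0) continue;
        double c[3] = {origin[0] + (x + 0.5) * res,
                       origin[1] + (y + 0.5) * res,
                       origin[2] + (z + 0.5) * res};
        int jlo = std::max(pseg - window, fibCapLo[f - 1]);
        int jhi = std::min(pseg + window, fibCapHi[f - 1]);
        double best = R_PosInf; int bestj = -1;
        for (int j = jlo; j <= jhi; ++j) {
          int a = capA[j];
          double A[3] = {P(a,0), P(a,1), P(a,2)};
          double B[3] = {P(a+1,0), P(a+1,1), P(a+1,2)};
          double t, d2 = seg_dist2(c, A, B, t);
          double cap = (1.0 - t) * capR[a] + t * capR[a+1];
          double excess = std::sqrt(d2) - cap;
          if (excess < best) { best = excess; bestj = j; }
        }
        if (bestj >= 0 && best <= 0.0) {
          ow[v] = f; sg[v] = bestj + 1;
          next.push_back(v);
          claimed += 1.0;
          if (in_region(x, y, z)) {
            region_owned += 1.0;
            if (stop_count >= 0 && region_owned >= stop_count) { hit_target = true; break; }
          }
        }
      }
    }
    frontier.swap(next);
    ++layers_done;
  }
  return List::create(_["layers"] = layers_done, _["claimed"] = claimed,
                      _["region_owned"] = region_owned,
                      _["hit_target"] = hit_target);
}

// Distance-to-boundary transform within each fibre mask (6-connectivity).
// depth = 1 on mask voxels touching a different owner, the unclaimed space,
// or the grid boundary; increasing inwards; 0 outside all masks.
// [[Rcpp::export]]
IntegerVector cpp_depth(IntegerVector owner, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::int64_t nvox = (std::int64_t)nx * ny * nz, stepz = (std::int64_t)nx * ny;
  const int* ow = owner.begin();
  IntegerVector depth(nvox, 0);
  int* dp = depth.begin();
  std::vector<std::int64_t> wave;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        std::int64_t v = vidx(x, y, z, nx, ny);
        int f = ow[v];
        if (f == 0) continue;
        bool boundary =
          (x == 0 || ow[v-1] != f) || (x == nx-1 || ow[v+1] != f) ||
          (y == 0 || ow[v-nx] != f) || (y == ny-1 || ow[v+nx] != f) ||
          (z == 0 || ow[v-stepz] != f) || (z == nz-1 || ow[v+stepz] != f);
        if (boundary) { dp[v] = 1; wave.push_back(v); }
      }
  int d = 1;
  while (!wave.empty()) {
    std::vector<std::int64_t> next;
    for (std::int64_t u : wave) {
      int f = ow[u];
      int ux = (int)(u % nx), uy = (int)((u / nx) % ny), uz = (int)(u / stepz);
      const int offs[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
      for (int k = 0; k < 6; ++k) {
        int x = ux + offs[k][0], y = uy + offs[k][1], z = uz + offs[k][2];
        if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) continue;
        std::int64_t v = vidx(x, y, z, nx, ny);
        if (ow[v] == f && dp[v] == 0) { dp[v] = d + 1; next.push_back(v); }
      }
    }
    wave.swap(next);
    ++d;
  }
  return depth;
}

// Per-fibre histogram of erosion depths inside an index region:
// out(f, d-1) = #voxels of fibre f+1 at depth d.  max_depth columns.
// [[Rcpp::export]]
IntegerMatrix cpp_depth_hist(IntegerVector owner, IntegerVector depth, int nfib,
                             IntegerVector dim, IntegerVector lo, IntegerVector hi) {
  int nx = dim[0], ny = dim[1];
  int maxd = 0;
  const int* dp = depth.begin(); const int* ow = owner.begin();
  std::int64_t n = owner.size();
  for (std::int64_t v = 0; v < n; ++v) if (dp[v] > maxd) maxd = dp[v];
  if (maxd == 0) maxd = 1;
  IntegerMatrix out(nfib, maxd);
  for (int z = lo[2]; z <= hi[2]; ++z)
    for (int y = lo[1]; y <= hi[1]; ++y)
      for (int x = lo[0]; x <= hi[0]; ++x) {
        std::int64_t v = vidx(x, y, z, nx, ny);
        if (ow[v] > 0 && dp[v] > 0) out(ow[v] - 1, dp[v] - 1) += 1;
      }
  return out;
}

// Inner (axonal) mask: voxels deeper than the fibre's erosion depth kf.
// [[Rcpp::export]]
IntegerVector cpp_make_inner(IntegerVector owner, IntegerVector depth,
                             IntegerVector kf) {
  std::int64_t n = owner.size();
  IntegerVector inner(n, 0);
  const int* ow = owner.begin(); const int* dp = depth.begin();
  int* in_ = inner.begin();
  for (std::int64_t v = 0; v < n; ++v) {
    int f = ow[v];
    if (f > 0 && dp[v] > kf[f - 1]) in_[v] = f;
  }
  return inner;
}

// Voxel counts inside an index region: total region size, owned (outer) and
// inner counts, plus per-fibre outer counts.
// [[Rcpp::export]]
List cpp_region_counts(IntegerVector owner, Nullable<IntegerVector> inner_,
                       IntegerVector dim, IntegerVector lo, IntegerVector hi,
                       int nfib) {
  int nx = dim[0], ny = dim[1];
  const int* ow = owner.begin();
  const int* in_ = nullptr;
  if (inner_.isNotNull()) { IntegerVector iv(inner_); in_ = iv.begin(); }
  double owned = 0.0, inner_n = 0.0, total = 0.0;
  NumericVector per_fib(nfib);
  for (int z = lo[2]; z <= hi[2]; ++z)
    for (int y = lo[1]; y <= hi[1]; ++y)
      for (int x = lo[0]; x <= hi[0]; ++x) {
        std::int64_t v = vidx(x, y, z, nx, ny);
        total += 1.0;
        if (ow[v] > 0) { owned += 1.0; per_fib[ow[v] - 1] += 1.0; }
        if (in_ && in_[v] > 0) inner_n += 1.0;
      }
  return List::create(_["total"] = total, _["outer"] = owned,
                      _["inner"] = inner_n, _["per_fibre_outer"] = per_fib);
}

// Extract the bounding box of one label (1-based) — used to crop per-fibre
// masks before meshing.  Returns integer lo/hi (0-based) or -1 if absent.
// [[Rcpp::export]]
IntegerVector cpp_label_bbox(IntegerVector mask, IntegerVector dim, int label) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int lo[3] = {nx, ny, nz}, hi[3] = {-1, -1, -1};
  const int* m = mask.begin();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x)
        if (m[vidx(x, y, z, nx, ny)] == label) {
          if (x < lo[0]) lo[0] = x; if (x > hi[0]) hi[0] = x;
          if (y < lo[1]) lo[1] = y; if (y > hi[1]) hi[1] = y;
          if (z < lo[2]) lo[2] = z; if (z > hi[2]) hi[2] = z;
        }
  return IntegerVector::create(lo[0], lo[1], lo[2], hi[0], hi[1], hi[2]);
}

// Crop one label into a logical sub-array given its bbox (0-based, inclusive).
// [[Rcpp::export]]
LogicalVector cpp_crop_label(IntegerVector mask, IntegerVector dim, int label,
                             IntegerVector lo, IntegerVector hi) {
  int nx = dim[0], ny = dim[1];
  int sx = hi[0] - lo[0] + 1, sy = hi[1] - lo[1] + 1, sz = hi[2] - lo[2] + 1;
  LogicalVector out((std::int64_t)sx * sy * sz, false);
  const int* m = mask.begin();
  std::int64_t o = 0;
  for (int z = lo[2]; z <= hi[2]; ++z)
    for (int y = lo[1]; y <= hi[1]; ++y)
      for (int x = lo[0]; x <= hi[0]; ++x)
        out[o++] = (m[vidx(x, y, z, nx, ny)] == label);
  return out;
}
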