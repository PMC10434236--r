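// Surface extraction and mesh processing: marching tetrahedra on the
// Freudenthal (Kuhn) subdivision of the voxel-centre lattice (unambiguous,
// hence watertight and manifold by construction on binary masks), uniform
// Laplacian smoothing with a volume-drift guard, shortest-edge collapse
// decimation with link-condition and normal-flip safeguards, and a
// grid-accelerated triangle-triangle self-intersection count.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <array>
#include <algorithm>
#include <functional>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------- marching tets

// Sample lattice has (nx+2)(ny+2)(nz+2) points (mask padded with 0), sample
// (i,j,k) maps to voxel (i-1,j-1,k-1).  Cells run over all unit cubes of the
// lattice; each splits into the 6 Freudenthal path tetrahedra, which tile
// space consistently so shared faces match across cells.
static const int PERMS[6][3] = {
  {0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}
};

// [[Rcpp::export]]
List cpp_march_tets(LogicalVector mask, IntegerVector dim, double res,
                    NumericVector origin) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int sx = nx + 2, sy = ny + 2, sz = nz + 2;
  const int* m = mask.begin();
  auto sample = [&](int i, int j, int k) -> int {
    int x = i - 1, y = j - 1, z = k - 1;
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return 0;
    return m[(std::int64_t)z * nx * ny + (std::int64_t)y * nx + x] ? 1 : 0;
  };
  auto sid = [&](int i, int j, int k) -> std::int64_t {
    return (std::int64_t)k * sx * sy + (std::int64_t)j * sx + i;
  };
  auto spos = [&](std::int64_t id, double* p) {
    int i = (int)(id % sx), j = (int)((id / sx) % sy), k = (int)(id / ((std::int64_t)sx * sy));
    p[0] = origin[0] + (i - 1 + 0.5) * res;
    p[1] = origin[1] + (j - 1 + 0.5) * res;
    p[2] = origin[2] + (k - 1 + 0.5) * res;
  };
  std::unordered_map<std::uint64_t, int> edge_vertex;
  std::vector<double> VX, VY, VZ;
  std::vector<int> F;  // triples, 0-based
  auto edge_point = [&](std::int64_t a, std::int64_t b) -> int {
    std::int64_t lo = std::min(a, b), hi = std::max(a, b);
    // exact composite key: lattice ids < 2^32 and edge spans are short
    std::uint64_t key = ((std::uint64_t)lo << 32) | (std::uint64_t)(hi - lo);
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double pa[3], pb[3];
    spos(lo, pa); spos(hi, pb);
    VX.push_back(0.5 * (pa[0] + pb[0]));
    VY.push_back(0.5 * (pa[1] + pb[1]));
    VZ.push_back(0.5 * (pa[2] + pb[2]));
    int id = (int)VX.size() - 1;
    edge_vertex[key] = id;
    return id;
  };
  auto emit = [&](int v1, int v2, int v3, const double* inward) {
    // orient so the normal points away from the inside
    double a[3] = {VX[v1], VY[v1], VZ[v1]};
    double b[3] = {VX[v2], VY[v2], VZ[v2]};
    double c[3] = {VX[v3], VY[v3], VZ[v3]};
    double u[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
    double w[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
    double n[3] = {u[1]*w[2]-u[2]*w[1], u[2]*w[0]-u[0]*w[2], u[0]*w[1]-u[1]*w[0]};
    double d = n[0]*inward[0] + n[1]*inward[1] + n[2]*inward[2];
    if (d > 0) { F.push_back(v1); F.push_back(v2); F.push_back(v3); }
    else       { F.push_back(v1); F.push_back(v3); F.push_back(v2); }
  };
  for (int ck = 0; ck < sz - 1; ++ck)
    for (int cj = 0; cj < sy - 1; ++cj)
      for (int ci = 0; ci < sx - 1; ++ci) {
        // skip uniform cells quickly
        int vals[2][2][2], any1 = 0, all1 = 1;
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              int v = sample(ci+dx, cj+dy, ck+dz);
              vals[dx][dy][dz] = v;
              any1 |= v; all1 &= v;
            }
        if (!any1 || all1) continue;
        for (int p = 0; p < 6; ++p) {
          int off[4][3];
          off[0][0] = 0; off[0][1] = 0; off[0][2] = 0;
          for (int step = 0; step < 3; ++step) {
            for (int k = 0; k < 3; ++k) off[step+1][k] = off[step][k];
            off[step+1][PERMS[p][step]] += 1;
          }
          int tv[4]; std::int64_t tid[4]; double tp[4][3];
          for (int k = 0; k < 4; ++k) {
            tv[k] = vals[off[k][0]][off[k][1]][off[k][2]];
            tid[k] = sid(ci + off[k][0], cj + off[k][1], ck + off[k][2]);
            spos(tid[k], tp[k]);
          }
          int nin = tv[0] + tv[1] + tv[2] + tv[3];
          if (nin == 0 || nin == 4) continue;
          int ins[4], outs[4], ni = 0, no = 0;
          for (int k = 0; k < 4; ++k) { if (tv[k]) ins[ni++] = k; else outs[no++] = k; }
          double cin[3] = {0,0,0}, cout[3] = {0,0,0};
          for (int k = 0; k < ni; ++k)
            for (int d = 0; d < 3; ++d) cin[d] += tp[ins[k]][d] / ni;
          for (int k = 0; k < no; ++k)
            for (int d = 0; d < 3; ++d) cout[d] += tp[outs[k]][d] / no;
          double outward[3] = {cout[0]-cin[0], cout[1]-cin[1], cout[2]-cin[2]};
          if (nin == 1) {
            int i0 = ins[0];
            int e1 = edge_point(tid[i0], tid[outs[0]]);
            int e2 = edge_point(tid[i0], tid[outs[1]]);
            int e3 = edge_point(tid[i0], tid[outs[2]]);
            emit(e1, e2, e3, outward);
          } else if (nin == 3) {
            int o0 = outs[0];
            int e1 = edge_point(tid[o0], tid[ins[0]]);
            int e2 = edge_point(tid[o0], tid[ins[1]]);
            int e3 = edge_point(tid[o0], tid[ins[2]]);
            emit(e1, e2, e3, outward);
          } else {
            int i0 = ins[0], i1 = ins[1], o0 = outs[0], o1 = outs[1];
            // planar parallelogram: e(i0,o0), e(i0,o1), e(i1,o1), e(i1,o0)
            int e1 = edge_point(tid[i0], tid[o0]);
            int e2 = edge_point(tid[i0], tid[o1]);
            int e3 = edge_point(tid[i1], tid[o1]);
            int e4 = edge_point(tid[i1], tid[o0]);
            emit(e1, e2, e3, outward);
            emit(e1, e3, e4, outward);
          }
        }
      }
  int nv = (int)VX.size(), nf = (int)F.size() / 3;
  NumericMatrix V(nv, 3);
  IntegerMatrix Fm(nf, 3);
  for (int i = 0; i < nv; ++i) { V(i,0) = VX[i]; V(i,1) = VY[i]; V(i,2) = VZ[i]; }
  for (int i = 0; i < nf; ++i) {
    Fm(i,0) = F[3*i] + 1; Fm(i,1) = F[3*i+1] + 1; Fm(i,2) = F[3*i+2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = Fm);
}

// ---------------------------------------------------------------- helpers

static double mesh_volume_raw(const std::vector<std::array<double,3> >& V,
                              const std::vector<std::array<int,3> >& F,
                              const std::vector<char>& alive) {
  double vol = 0.0;
  for (size_t i = 0; i < F.size(); ++i) {
    if (!alive.empty() && !alive[i]) continue;
    const double* a = V[F[i][0]].data();
    const double* b = V[F[i][1]].data();
    const double* c = V[F[i][2]].data();
    vol += (a[0]*(b[1]*c[2]-b[2]*c[1]) - a[1]*(b[0]*c[2]-b[2]*c[0]) +
            a[2]*(b[0]*c[1]-b[1]*c[0])) / 6.0;
  }
  return vol;
}

// ---------------------------------------------------------------- smoothing

// Uniform Laplacian smoothing x <- x + lambda * (mean(neighbours) - x),
// stopping (with rollback of the offending iteration) if the enclosed volume
// drifts by more than guard relative to the input.
// [[Rcpp::export]]
List cpp_smooth_mesh(NumericMatrix Vin, IntegerMatrix Fin, int iters,
                     double lambda, double guard) {
  int nv = Vin.nrow(), nf = Fin.nrow();
  std::vector<std::array<double,3> > V(nv);
  std::vector<std::array<int,3> > F(nf);
  for (int i = 0; i < nv; ++i) V[i] = {Vin(i,0), Vin(i,1), Vin(i,2)};
  for (int i = 0; i < nf; ++i) F[i] = {Fin(i,0)-1, Fin(i,1)-1, Fin(i,2)-1};
  std::vector<std::vector<int> > nbr(nv);
  for (int i = 0; i < nf; ++i)
    for (int k = 0; k < 3; ++k) {
      int a = F[i][k], b = F[i][(k+1)%3];
      nbr[a].push_back(b);  // each undirected edge appears once per direction
    }
  std::vector<char> none;
  double vol0 = std::fabs(mesh_volume_raw(V, F, none));
  std::vector<std::array<double,3> > prev = V, nxt(nv);
  int done = 0;
  for (int it = 0; it < iters; ++it) {
    prev = V;
    for (int i = 0; i < nv; ++i) {
      if (nbr[i].empty()) { nxt[i] = V[i]; continue; }
      double mx = 0, my = 0, mz = 0;
      for (int j : nbr[i]) { mx += V[j][0]; my += V[j][1]; mz += V[j][2]; }
      double inv = 1.0 / nbr[i].size();
      nxt[i][0] = V[i][0] + lambda * (mx*inv - V[i][0]);
      nxt[i][1] = V[i][1] + lambda * (my*inv - V[i][1]);
      nxt[i][2] = V[i][2] + lambda * (mz*inv - V[i][2]);
    }
    V = nxt;
    double vol = std::fabs(mesh_volume_raw(V, F, none));
    if (vol0 > 0 && std::fabs(vol - vol0) / vol0 > guard) { V = prev; break; }
    ++done;
  }
  NumericMatrix Vout(nv, 3);
  for (int i = 0; i < nv; ++i) { Vout(i,0) = V[i][0]; Vout(i,1) = V[i][1]; Vout(i,2) = V[i][2]; }
  return List::create(_["vertices"] = Vout, _["iterations"] = done);
}

// ---------------------------------------------------------------- decimation

// Shortest-edge collapse to the midpoint.  A collapse is accepted only if it
// keeps the mesh a closed 2-manifold (link condition: the two endpoints
// share exactly two neighbours) and does not flip any incident face normal;
// cumulative volume drift is capped at guard relative to the input.
// [[Rcpp::export]]
List cpp_decimate(NumericMatrix Vin, IntegerMatrix Fin, double target_frac,
                  double guard) {
  int nv = Vin.nrow(), nf = Fin.nrow();
  std::vector<std::array<double,3> > V(nv);
  std::vector<std::array<int,3> > F(nf);
  for (int i = 0; i < nv; ++i) V[i] = {Vin(i,0), Vin(i,1), Vin(i,2)};
  for (int i = 0; i < nf; ++i) F[i] = {Fin(i,0)-1, Fin(i,1)-1, Fin(i,2)-1};
  std::vector<char> falive(nf, 1), valive(nv, 1);
  std::vector<std::vector<int> > vfaces(nv);
  for (int i = 0; i < nf; ++i)
    for (int k = 0; k < 3; ++k) vfaces[F[i][k]].push_back(i);
  std::vector<char> nonec;
  double vol0 = std::fabs(mesh_volume_raw(V, F, falive));
  double vol_drift = 0.0;
  int faces_alive = nf;
  int target_faces = std::max(4, (int)std::floor(nf * target_frac));

  auto edge_len2 = [&](int a, int b) {
    double dx = V[a][0]-V[b][0], dy = V[a][1]-V[b][1], dz = V[a][2]-V[b][2];
    return dx*dx + dy*dy + dz*dz;
  };
  struct QE { double len; int a, b; };
  struct Cmp { bool operator()(const QE& x, const QE& y) const { return x.len > y.len; } };
  std::priority_queue<QE, std::vector<QE>, Cmp> pq;
  for (int i = 0; i < nf; ++i)
    for (int k = 0; k < 3; ++k) {
      int a = F[i][k], b = F[i][(k+1)%3];
      if (a < b) pq.push({edge_len2(a, b), a, b});
    }
  auto neighbours = [&](int a) {
    std::vector<int> out;
    for (int fi : vfaces[a]) {
      if (!falive[fi]) continue;
      for (int k = 0; k < 3; ++k) if (F[fi][k] != a) out.push_back(F[fi][k]);
    }
    std::sort(out.begin(), out.end());
    out.erase(std::unique(out.begin(), out.end()), out.end());
    return out;
  };
  auto face_normal = [&](int fi, double* n) {
    const double* a = V[F[fi][0]].data();
    const double* b = V[F[fi][1]].data();
    const double* c = V[F[fi][2]].data();
    double u[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
    double w[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
    n[0] = u[1]*w[2]-u[2]*w[1]; n[1] = u[2]*w[0]-u[0]*w[2]; n[2] = u[0]*w[1]-u[1]*w[0];
  };
  auto face_signed_vol = [&](int fi) {
    const double* a = V[F[fi][0]].data();
    const double* b = V[F[fi][1]].data();
    const double* c = V[F[fi][2]].data();
    return (a[0]*(b[1]*c[2]-b[2]*c[1]) - a[1]*(b[0]*c[2]-b[2]*c[0]) +
            a[2]*(b[0]*c[1]-b[1]*c[0])) / 6.0;
  };

  while (!pq.empty() && faces_alive > target_faces) {
    QE e = pq.top(); pq.pop();
    int a = e.a, b = e.b;
    if (!valive[a] || !valive[b]) continue;
    if (std::fabs(edge_len2(a, b) - e.len) > 1e-12 * (1.0 + e.len)) continue;  // stale
    // edge must still exist: count shared live faces
    std::vector<int> shared;
    for (int fi : vfaces[a]) {
      if (!falive[fi]) continue;
      for (int k = 0; k < 3; ++k) if (F[fi][k] == b) { shared.push_back(fi); break; }
    }
    if (shared.size() != 2) continue;
    // link condition
    std::vector<int> na = neighbours(a), nb = neighbours(b), common;
    std::set_intersection(na.begin(), na.end(), nb.begin(), nb.end(),
                          std::back_inserter(common));
    if (common.size() != 2) continue;
    // tentative midpoint collapse
    std::array<double,3> olda = V[a], oldb = V[b];
    std::array<double,3> mid = {0.5*(olda[0]+oldb[0]), 0.5*(olda[1]+oldb[1]),
                                0.5*(olda[2]+oldb[2])};
    // faces affected (live faces of a or b, excluding the two shared)
    std::vector<int> affected;
    for (int fi : vfaces[a]) if (falive[fi]) affected.push_back(fi);
    for (int fi : vfaces[b]) if (falive[fi]) affected.push_back(fi);
    std::sort(affected.begin(), affected.end());
    affected.erase(std::unique(affected.begin(), affected.end()), affected.end());
    // normals and volume before
    std::vector<std::array<double,3> > n_before(affected.size());
    double dvol = 0.0;
    for (size_t k = 0; k < affected.size(); ++k) {
      face_normal(affected[k], n_before[k].data());
      dvol -= face_signed_vol(affected[k]);
    }
    V[a] = mid; V[b] = mid;  // b's faces will be remapped to a
    bool ok = true;
    for (size_t k = 0; k < affected.size() && ok; ++k) {
      int fi = affected[k];
      if (fi == shared[0] || fi == shared[1]) continue;
      double n[3]; face_normal(fi, n);
      double dp = n[0]*n_before[k][0] + n[1]*n_before[k][1] + n[2]*n_before[k][2];
      double m1 = std::sqrt(n[0]*n[0]+n[1]*n[1]+n[2]*n[2]);
      double m0 = std::sqrt(n_before[k][0]*n_before[k][0] +
                            n_before[k][1]*n_before[k][1] +
                            n_before[k][2]*n_before[k][2]);
      if (m1 < 1e-18 || dp <= 1e-6 * m0 * m1) ok = false;  // flip or degenerate
    }
    if (ok) {
      for (size_t k = 0; k < affected.size(); ++k) {
        int fi = affected[k];
        if (fi == shared[0] || fi == shared[1]) continue;
        dvol += face_signed_vol(fi);
      }
      if (vol0 > 0 && std::fabs(vol_drift + dvol) / vol0 > guard) ok = false;
    }
    if (!ok) { V[a] = olda; V[b] = oldb; continue; }
    vol_drift += dvol;
    // commit: kill shared faces, remap b -> a
    falive[shared[0]] = 0; falive[shared[1]] = 0;
    faces_alive -= 2;
    for (int fi : vfaces[b]) {
      if (!falive[fi]) continue;
      for (int k = 0; k < 3; ++k) if (F[fi][k] == b) F[fi][k] = a;
      vfaces[a].push_back(fi);
    }
    valive[b] = 0;
    for (int j : neighbours(a)) pq.push({edge_len2(a, j), std::min(a, j), std::max(a, j)});
  }
  // compact
  std::vector<int> vmap(nv, -1);
  int nv2 = 0;
  for (int i = 0; i < nf; ++i)
    if (falive[i])
      for (int k = 0; k < 3; ++k)
        if (vmap[F[i][k]] < 0) vmap[F[i][k]] = nv2++;
  NumericMatrix Vout(nv2, 3);
  for (int i = 0; i < nv; ++i)
    if (vmap[i] >= 0) {
      Vout(vmap[i],0) = V[i][0]; Vout(vmap[i],1) = V[i][1]; Vout(vmap[i],2) = V[i][2];
    }
  IntegerMatrix Fout(faces_alive, 3);
  int fo = 0;
  for (int i = 0; i < nf; ++i)
    if (falive[i]) {
      for (int k = 0; k < 3; ++k) Fout(fo,k) = vmap[F[i][k]] + 1;
      ++fo;
    }
  return List::create(_["vertices"] = Vout, _["faces"] = Fout,
                      _["volume_drift"] = vol_drift);
}

// ---------------------------------------------------------------- self-intersection

static bool tri_tri_overlap(const double* p1, const double* q1, const double* r1,
                            const double* p2, const double* q2, const double* r2);

// Count pairs of triangles (not sharing a vertex index) that intersect.
// [[Rcpp::export]]
int cpp_self_intersections(NumericMatrix Vin, IntegerMatrix Fin) {
  int nf = Fin.nrow();
  std::vector<std::array<int,3> > F(nf);
  for (int i = 0; i < nf; ++i) F[i] = {Fin(i,0)-1, Fin(i,1)-1, Fin(i,2)-1};
  // grid over triangle bboxes
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf}, hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < Vin.nrow(); ++i)
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], Vin(i,k)); hi[k] = std::max(hi[k], Vin(i,k));
    }
  double mean_edge = 0.0;
  for (int i = 0; i < std::min(nf, 200); ++i) {
    double dx = Vin(F[i][0],0)-Vin(F[i][1],0), dy = Vin(F[i][0],1)-Vin(F[i][1],1),
           dz = Vin(F[i][0],2)-Vin(F[i][1],2);
    mean_edge += std::sqrt(dx*dx+dy*dy+dz*dz);
  }
  mean_edge /= std::min(nf, 200);
  double cell = std::max(2.0 * mean_edge, 1e-9);
  int gx = std::max(1, (int)((hi[0]-lo[0])/cell) + 1);
  int gy = std::max(1, (int)((hi[1]-lo[1])/cell) + 1);
  int gz = std::max(1, (int)((hi[2]-lo[2])/cell) + 1);
  std::unordered_map<std::int64_t, std::vector<int> > grid;
  auto cellkey = [&](int x, int y, int z) {
    return (std::int64_t)z * gx * gy + (std::int64_t)y * gx + x;
  };
  std::vector<std::array<int,6> > tb(nf);
  for (int i = 0; i < nf; ++i) {
    double bl[3] = {R_PosInf, R_PosInf, R_PosInf}, bh[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int k = 0; k < 3; ++k)
      for (int d = 0; d < 3; ++d) {
        bl[d] = std::min(bl[d], Vin(F[i][k],d));
        bh[d] = std::max(bh[d], Vin(F[i][k],d));
      }
    for (int d = 0; d < 3; ++d) {
      tb[i][d]   = std::max(0, (int)((bl[d]-lo[d])/cell));
      tb[i][d+3] = std::min((d==0?gx:(d==1?gy:gz)) - 1, (int)((bh[d]-lo[d])/cell));
    }
    for (int z = tb[i][2]; z <= tb[i][5]; ++z)
      for (int y = tb[i][1]; y <= tb[i][4]; ++y)
        for (int x = tb[i][0]; x <= tb[i][3]; ++x)
          grid[cellkey(x,y,z)].push_back(i);
  }
  int count = 0;
  std::vector<int> last_checked(nf, -1);
  for (int i = 0; i < nf; ++i) {
    double t1[3][3];
    for (int k = 0; k < 3; ++k)
      for (int d = 0; d < 3; ++d) t1[k][d] = Vin(F[i][k],d);
    for (int z = tb[i][2]; z <= tb[i][5]; ++z)
      for (int y = tb[i][1]; y <= tb[i][4]; ++y)
        for (int x = tb[i][0]; x <= tb[i][3]; ++x) {
          auto it = grid.find(cellkey(x,y,z));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            if (j <= i || last_checked[j] == i) continue;
            last_checked[j] = i;
            bool share = false;
            for (int a = 0; a < 3 && !share; ++a)
              for (int b = 0; b < 3; ++b)
                if (F[i][a] == F[j][b]) { share = true; break; }
            if (share) continue;
            double t2[3][3];
            for (int k = 0; k < 3; ++k)
              for (int d = 0; d < 3; ++d) t2[k][d] = Vin(F[j][k],d);
            if (tri_tri_overlap(t1[0], t1[1], t1[2], t2[0], t2[1], t2[2])) ++count;
          }
        }
  }
  return count;
}

// Moller-style interval test.
static void cross3(const double* a, const double* b, double* c) {
  c[0] = a[1]*b[2]-a[2]*b[1]; c[1] = a[2]*b[0]-a[0]*b[2]; c[2] = a[0]*b[1]-a[1]*b[0];
}
static double dot3m(const double* a, const double* b) {
  return a[0]*b[0]+a[1]*b[1]+a[2]*b[2];
}

static bool tri_interval(const double* v0, const double* v1, const double* v2,
                         double d0, double d1, double d2,
                         const double* dir, double* t) {
  // project onto dir the crossing points of edges whose endpoints straddle
  double p0 = dot3m(dir, v0), p1 = dot3m(dir, v1), p2 = dot3m(dir, v2);
  int n = 0;
  double tt[3];
  auto add = [&](double pa, double pb, double da, double db) {
    if ((da > 0 && db < 0) || (da < 0 && db > 0) || (da == 0) != (db == 0)) {
      if (da == db) return;
      double s = da / (da - db);
      tt[n++] = pa + s * (pb - pa);
    }
  };
  add(p0, p1, d0, d1); add(p0, p2, d0, d2); add(p1, p2, d1, d2);
  if (n < 2) {
    // a vertex may lie exactly on the plane
    if (d0 == 0 && n < 2) tt[n++] = p0;
    if (d1 == 0 && n < 2) tt[n++] = p1;
    if (d2 == 0 && n < 2) tt[n++] = p2;
  }
  if (n < 2) return false;
  t[0] = std::min(tt[0], tt[1]); t[1] = std::max(tt[0], tt[1]);
  return true;
}

static bool tri_tri_overlap(const double* p1, const double* q1, const double* r1,
                            const double* p2, const double* q2, const double* r2) {
  double e1[3] = {q1[0]-p1[0], q1[1]-p1[1], q1[2]-p1[2]};
  double e2[3] = {r1[0]-p1[0], r1[1]-p1[1], r1[2]-p1[2]};
  double n1[3]; cross3(e1, e2, n1);
  double d1 = -dot3m(n1, p1);
  double dp2 = dot3m(n1, p2) + d1, dq2 = dot3m(n1, q2) + d1, dr2 = dot3m(n1, r2) + d1;
  const double EPS = 1e-12;
  if (std::fabs(dp2) < EPS) dp2 = 0; if (std::fabs(dq2) < EPS) dq2 = 0;
  if (std::fabs(dr2) < EPS) dr2 = 0;
  if ((dp2 > 0 && dq2 > 0 && dr2 > 0) || (dp2 < 0 && dq2 < 0 && dr2 < 0)) return false;
  double f1[3] = {q2[0]-p2[0], q2[1]-p2[1], q2[2]-p2[2]};
  double f2[3] = {r2[0]-p2[0], r2[1]-p2[1], r2[2]-p2[2]};
  double n2[3]; cross3(f1, f2, n2);
  double d2c = -dot3m(n2, p2);
  double dp1 = dot3m(n2, p1) + d2c, dq1 = dot3m(n2, q1) + d2c, dr1 = dot3m(n2, r1) + d2c;
  if (std::fabs(dp1) < EPS) dp1 = 0; if (std::fabs(dq1) < EPS) dq1 = 0;
  if (std::fabs(dr1) < EPS) dr1 = 0;
  if ((dp1 > 0 && dq1 > 0 && dr1 > 0) || (dp1 < 0 && dq1 < 0 && dr1 < 0)) return false;
  if (dp1 == 0 && dq1 == 0 && dr1 == 0) return false;  // coplanar: not counted
  double dir[3]; cross3(n1, n2, dir);
  double i1[2], i2[2];
  if (!tri_interval(p1, q1, r1, dp1, dq1, dr1, dir, i1)) return false;
  if (!tri_interval(p2, q2, r2, dp2, dq2, dr2, dir, i2)) return false;
  double tol = 1e-10 * (std::fabs(i1[0]) + std::fabs(i1[1]) + std::fabs(i2[0]) + std::fabs(i2[1]) + 1.0);
  return std::min(i1[1], i2[1]) - std::max(i1[0], i2[0]) > tol;
}

// Connected components of the face graph (union-find on vertex indices).
// [[Rcpp::export]]
int cpp_mesh_components(int nv, IntegerMatrix Fin) {
  std::vector<int> parent(nv);
  for (int i = 0; i < nv; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (int i = 0; i < Fin.nrow(); ++i)
    for (int k = 0; k < 3; ++k) {
      int a = find(Fin(i,k) - 1), b = find(Fin(i,(k+1)%3) - 1);
      if (a != b) parent[a] = b;
    }
  std::vector<char> seen(nv, 0);
  int used = 0, comps = 0;
  std::vector<char> is_used(nv, 0);
  for (int i = 0; i < Fin.nrow(); ++i)
    for (int k = 0; k < 3; ++k) is_used[Fin(i,k) - 1] = 1;
  for (int i = 0; i < nv; ++i)
    if (is_used[i]) { ++used; int r = find(i); if (!seen[r]) { seen[r] = 1; ++comps; } }
  (void)used;
  return comps;
}
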