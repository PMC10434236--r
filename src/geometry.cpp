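// Capsule geometry kernels: closest approach between segments (closed form,
// clamped to [0,1]^2), the pairwise overlap cost and its analytic gradient
// with respect to all control points and radii, and the fixed-radius-cell
// broad phase used to generate candidate capsule pairs in O(n).
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static const double SEG_EPS = 1e-12;   // squared-length threshold for point-like segments
static const double PAR_EPS = 1e-12;   // relative determinant threshold for parallel segments

struct Closest {
  double s, t;
  // which branch produced (s, t); drives the Jacobian case analysis
  bool s_interior, t_interior, parallel, p_degenerate, q_degenerate;
};

static inline double clamp01(double x) { return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x); }
static inline double dot3(const double* a, const double* b) {
  return a[0]*b[0] + a[1]*b[1] + a[2]*b[2];
}

// Closest parameters between segments p0+s*(p1-p0), q0+t*(q1-q0), s,t in [0,1].
// Parallel overlapping segments use the midrange of the overlap interval so
// that coincident segments return s == t (deterministic tie-break).
static Closest seg_closest(const double* p0, const double* p1,
                           const double* q0, const double* q1) {
  Closest out;
  out.parallel = false;
  double d1[3] = {p1[0]-p0[0], p1[1]-p0[1], p1[2]-p0[2]};
  double d2[3] = {q1[0]-q0[0], q1[1]-q0[1], q1[2]-q0[2]};
  double w[3]  = {p0[0]-q0[0], p0[1]-q0[1], p0[2]-q0[2]};
  double a = dot3(d1, d1), e = dot3(d2, d2);
  double f = dot3(d2, w);
  out.p_degenerate = a < SEG_EPS;
  out.q_degenerate = e < SEG_EPS;
  if (out.p_degenerate && out.q_degenerate) {
    out.s = 0.0; out.t = 0.0; out.s_interior = false; out.t_interior = false;
    return out;
  }
  if (out.p_degenerate) {
    out.s = 0.0; out.s_interior = false;
    out.t = clamp01(f / e);
    out.t_interior = (out.t > 0.0 && out.t < 1.0);
    return out;
  }
  double c = dot3(d1, w);
  if (out.q_degenerate) {
    out.t = 0.0; out.t_interior = false;
    out.s = clamp01(-c / a);
    out.s_interior = (out.s > 0.0 && out.s < 1.0);
    return out;
  }
  double b = dot3(d1, d2);
  double denom = a*e - b*b;
  double s;
  if (denom > PAR_EPS * a * e) {
    s = clamp01((b*f - c*e) / denom);
  } else {
    out.parallel = true;
    // Project q's endpoints on p's axis; take the midrange of the overlap.
    double s0 = -c / a;            // t = 0
    double s1 = (b - c) / a;       // t = 1
    double lo = std::min(s0, s1), hi = std::max(s0, s1);
    lo = std::max(lo, 0.0); hi = std::min(hi, 1.0);
    if (lo <= hi) s = 0.5 * (lo + hi);
    else s = clamp01(std::min(s0, s1) > 1.0 ? 1.0 : 0.0);
  }
  double t = (b*s + f) / e;
  bool t_clamped = false;
  if (t < 0.0)      { t = 0.0; t_clamped = true; s = clamp01(-c / a); }
  else if (t > 1.0) { t = 1.0; t_clamped = true; s = clamp01((b - c) / a); }
  out.s = s; out.t = t;
  out.s_interior = (s > 0.0 && s < 1.0) && !out.parallel;
  out.t_interior = (t > 0.0 && t < 1.0) && !t_clamped;
  if (t_clamped) out.t_interior = false;
  return out;
}

// [[Rcpp::export]]
List cpp_seg_closest(NumericVector p0, NumericVector p1,
                     NumericVector q0, NumericVector q1) {
  Closest cl = seg_closest(p0.begin(), p1.begin(), q0.begin(), q1.begin());
  NumericVector c1(3), c2(3);
  for (int k = 0; k < 3; ++k) {
    c1[k] = (1.0 - cl.s) * p0[k] + cl.s * p1[k];
    c2[k] = (1.0 - cl.t) * q0[k] + cl.t * q1[k];
  }
  return List::create(_["t_p"] = cl.s, _["t_q"] = cl.t,
                      _["c1"] = c1, _["c2"] = c2,
                      _["parallel"] = cl.parallel);
}

// Overlap cost of one capsule pair and (optionally) its gradient with respect
// to the 12 endpoint coordinates and 4 radii.  The closest parameters (s, t)
// are differentiated through their defining equations: implicit 2x2 system
// when both are interior, one-dimensional projection when one is clamped,
// constants when both are clamped.
struct PairGrad {
  double cost, D;
  double gP[12];   // p0(xyz), p1, q0, q1
  double gR[4];    // rp0, rp1, rq0, rq1
};

static void pair_cost_grad(const double* p0, const double* p1,
                           const double* q0, const double* q1,
                           double rp0, double rp1, double rq0, double rq1,
                           bool want_grad, PairGrad& out) {
  Closest cl = seg_closest(p0, p1, q0, q1);
  const double s = cl.s, t = cl.t;
  double d1[3] = {p1[0]-p0[0], p1[1]-p0[1], p1[2]-p0[2]};
  double d2[3] = {q1[0]-q0[0], q1[1]-q0[1], q1[2]-q0[2]};
  double w[3]  = {p0[0]-q0[0], p0[1]-q0[1], p0[2]-q0[2]};
  double a = dot3(d1,d1), b = dot3(d1,d2), e = dot3(d2,d2);
  double u[3];
  for (int k = 0; k < 3; ++k) u[k] = w[k] + s*d1[k] - t*d2[k];  // c1 - c2
  double n2 = dot3(u,u);
  double n = std::sqrt(n2);
  double rp = (1.0-s)*rp0 + s*rp1;
  double rq = (1.0-t)*rq0 + t*rq1;
  double S = rp + rq;
  double D = 1.0 - n / S;
  out.D = D;
  for (int k = 0; k < 12; ++k) out.gP[k] = 0.0;
  for (int k = 0; k < 4;  ++k) out.gR[k] = 0.0;
  if (D < 0.0) { out.cost = 0.0; return; }
  double L1 = std::sqrt(a), L2 = std::sqrt(e);
  double f1 = D*D * L1 * L2 * rp * rq;
  out.cost = f1;
  if (!want_grad) return;

  double nsafe = (n > 1e-12) ? n : 1e-12;
  double denom = a*e - b*b;
  double c = dot3(d1, w), f = dot3(d2, w);
  double drp_ds = rp1 - rp0, drq_dt = rq1 - rq0;

  // Pre-computed common factors of df1.
  double F_D  = 2.0 * D * L1 * L2 * rp * rq;          // times dD
  double F_L1 = D*D * L2 * rp * rq;                   // times dL1
  double F_L2 = D*D * L1 * rp * rq;                   // times dL2
  double F_rp = D*D * L1 * L2 * rq;                   // times drp
  double F_rq = D*D * L1 * L2 * rp;                   // times drq

  for (int pt = 0; pt < 4; ++pt) {
    for (int k = 0; k < 3; ++k) {
      // derivatives of the dot products wrt this coordinate
      double da = 0, db = 0, de = 0, dc = 0, df = 0;
      if (pt == 0)      { da = -2*d1[k]; db = -d2[k]; dc = -w[k] + d1[k]; df =  d2[k]; }
      else if (pt == 1) { da =  2*d1[k]; db =  d2[k]; dc =  w[k];                       }
      else if (pt == 2) { de = -2*d2[k]; db = -d1[k]; dc = -d1[k]; df = -w[k] - d2[k]; }
      else              { de =  2*d2[k]; db =  d1[k]; df =  w[k];                       }

      // derivatives of the closest parameters
      double ds = 0.0, dt = 0.0;
      if (!cl.parallel && cl.s_interior && cl.t_interior) {
        double dDen = da*e + a*de - 2.0*b*db;
        ds = (db*f + b*df - dc*e - c*de - s*dDen) / denom;
        dt = (da*f + a*df - db*c - b*dc - t*dDen) / denom;
      } else if (cl.s_interior && !cl.p_degenerate) {
        // t fixed (clamped); s = (t*b - c)/a
        ds = (t*db - dc - s*da) / a;
      } else if (cl.t_interior && !cl.q_degenerate) {
        // s fixed; t = (s*b + f)/e
        dt = (s*db + df - t*de) / e;
      }

      // d(c1 - c2)
      double du[3] = {0, 0, 0};
      if (pt == 0) du[k] += (1.0 - s);
      if (pt == 1) du[k] += s;
      if (pt == 2) du[k] -= (1.0 - t);
      if (pt == 3) du[k] -= t;
      for (int m = 0; m < 3; ++m) du[m] += d1[m]*ds - d2[m]*dt;

      double dn = dot3(u, du) / nsafe;
      double drp = drp_ds * ds, drq = drq_dt * dt;
      double dD = -(dn * S - n * (drp + drq)) / (S*S);
      double dL1 = (L1 > 1e-12) ? da / (2.0*L1) : 0.0;
      double dL2 = (L2 > 1e-12) ? de / (2.0*L2) : 0.0;
      out.gP[pt*3 + k] = F_D*dD + F_L1*dL1 + F_L2*dL2 + F_rp*drp + F_rq*drq;
    }
  }
  // radii: s, t do not depend on the radii
  double dD_drp = n / (S*S);   // dD/drp = dD/drq
  double g_rp = F_D * dD_drp + F_rp;
  double g_rq = F_D * dD_drp + F_rq;
  out.gR[0] = (1.0 - s) * g_rp;
  out.gR[1] = s * g_rp;
  out.gR[2] = (1.0 - t) * g_rq;
  out.gR[3] = t * g_rq;
}

// [[Rcpp::export]]
List cpp_capsule_pair_cost(NumericMatrix P, NumericVector R, bool grad = false) {
  if (P.nrow() != 4 || R.size() != 4) stop("expected 4 endpoints and 4 radii");
  double p0[3], p1[3], q0[3], q1[3];
  for (int k = 0; k < 3; ++k) {
    p0[k] = P(0,k); p1[k] = P(1,k); q0[k] = P(2,k); q1[k] = P(3,k);
  }
  PairGrad pg;
  pair_cost_grad(p0, p1, q0, q1, R[0], R[1], R[2], R[3], grad, pg);
  NumericMatrix gP(4, 3);
  NumericVector gR(4);
  if (grad) {
    for (int pt = 0; pt < 4; ++pt)
      for (int k = 0; k < 3; ++k) gP(pt, k) = pg.gP[pt*3 + k];
    for (int k = 0; k < 4; ++k) gR[k] = pg.gR[k];
  }
  return List::create(_["cost"] = pg.cost, _["D"] = pg.D,
                      _["grad_points"] = gP, _["grad_radii"] = gR);
}

// ---- fixed-radius-cell broad phase ---------------------------------------

struct CellKey {
  static inline std::uint64_t make(int x, int y, int z) {
    return (static_cast<std::uint64_t>(static_cast<std::uint32_t>(x + (1<<20))) << 42) ^
           (static_cast<std::uint64_t>(static_cast<std::uint32_t>(y + (1<<20))) << 21) ^
           static_cast<std::uint64_t>(static_cast<std::uint32_t>(z + (1<<20)));
  }
};

// cell size >= 2 * max(half length + max radius) guarantees that any
// overlapping pair lies within the 27-cell neighbourhood of either midpoint.
static double grid_cell_size(NumericMatrix P, NumericVector R, IntegerVector capA) {
  double m = 0.0;
  for (int i = 0; i < capA.size(); ++i) {
    int aidx = capA[i];
    double dx = P(aidx+1,0)-P(aidx,0), dy = P(aidx+1,1)-P(aidx,1), dz = P(aidx+1,2)-P(aidx,2);
    double hl = 0.5*std::sqrt(dx*dx + dy*dy + dz*dz);
    double r = std::max(R[aidx], R[aidx+1]);
    m = std::max(m, hl + r);
  }
  return std::max(2.0*m, 1e-6);
}

static void build_pairs(NumericMatrix P, NumericVector R,
                        IntegerVector capA, IntegerVector capF,
                        std::vector<std::pair<int,int> >& pairs) {
  int nc = capA.size();
  double cell = grid_cell_size(P, R, capA);
  std::vector<double> mx(nc), my(nc), mz(nc), hl(nc), rr(nc);
  std::unordered_map<std::uint64_t, std::vector<int> > grid;
  grid.reserve(nc * 2);
  for (int i = 0; i < nc; ++i) {
    int a = capA[i];
    mx[i] = 0.5*(P(a,0) + P(a+1,0));
    my[i] = 0.5*(P(a,1) + P(a+1,1));
    mz[i] = 0.5*(P(a,2) + P(a+1,2));
    double dx = P(a+1,0)-P(a,0), dy = P(a+1,1)-P(a,1), dz = P(a+1,2)-P(a,2);
    hl[i] = 0.5*std::sqrt(dx*dx + dy*dy + dz*dz);
    rr[i] = std::max(R[a], R[a+1]);
    int cx = (int)std::floor(mx[i]/cell), cy = (int)std::floor(my[i]/cell),
        cz = (int)std::floor(mz[i]/cell);
    grid[CellKey::make(cx, cy, cz)].push_back(i);
  }
  for (int i = 0; i < nc; ++i) {
    int cx = (int)std::floor(mx[i]/cell), cy = (int)std::floor(my[i]/cell),
        cz = (int)std::floor(mz[i]/cell);
    for (int ox = -1; ox <= 1; ++ox)
      for (int oy = -1; oy <= 1; ++oy)
        for (int oz = -1; oz <= 1; ++oz) {
          auto it = grid.find(CellKey::make(cx+ox, cy+oy, cz+oz));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            if (j <= i || capF[j] == capF[i]) continue;
            // conservative reach test: midpoints closer than summed extents
            double dx = mx[i]-mx[j], dy = my[i]-my[j], dz = mz[i]-mz[j];
            double reach = hl[i] + hl[j] + rr[i] + rr[j];
            if (dx*dx + dy*dy + dz*dz <= reach*reach)
              pairs.push_back(std::make_pair(i, j));
          }
        }
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_candidate_pairs(NumericMatrix P, NumericVector R,
                                  IntegerVector capA, IntegerVector capF) {
  std::vector<std::pair<int,int> > pairs;
  build_pairs(P, R, capA, capF, pairs);
  IntegerMatrix out(pairs.size(), 2);
  for (size_t k = 0; k < pairs.size(); ++k) {
    out(k,0) = pairs[k].first;   // 0-based capsule indices
    out(k,1) = pairs[k].second;
  }
  return out;
}

// Total overlap cost over candidate pairs, with accumulated analytic gradient
// over all control points and radii.  pairs is 0-based capsule indices.
// [[Rcpp::export]]
List cpp_overlap_total(NumericMatrix P, NumericVector R,
                       IntegerVector capA, IntegerVector capF,
                       Nullable<IntegerMatrix> pairs_ = R_NilValue,
                       bool want_grad = true) {
  std::vector<std::pair<int,int> > pairs;
  if (pairs_.isNotNull()) {
    IntegerMatrix pm(pairs_);
    pairs.reserve(pm.nrow());
    for (int k = 0; k < pm.nrow(); ++k)
      pairs.push_back(std::make_pair(pm(k,0), pm(k,1)));
  } else {
    build_pairs(P, R, capA, capF, pairs);
  }
  int N = P.nrow();
  NumericMatrix gP(want_grad ? N : 1, 3);
  NumericVector gR(want_grad ? N : 1);
  double total = 0.0, maxD = R_NegInf;
  int count = 0;
  double p0[3], p1[3], q0[3], q1[3];
  PairGrad pg;
  for (size_t k = 0; k < pairs.size(); ++k) {
    int i = pairs[k].first, j = pairs[k].second;
    int ai = capA[i], aj = capA[j];
    for (int m = 0; m < 3; ++m) {
      p0[m] = P(ai,m); p1[m] = P(ai+1,m);
      q0[m] = P(aj,m); q1[m] = P(aj+1,m);
    }
    pair_cost_grad(p0, p1, q0, q1, R[ai], R[ai+1], R[aj], R[aj+1], want_grad, pg);
    if (pg.D > maxD) maxD = pg.D;
    if (pg.D > 0.0) ++count;
    if (pg.cost <= 0.0) continue;
    total += pg.cost;
    if (want_grad) {
      int idx[4] = {ai, ai+1, aj, aj+1};
      for (int pt = 0; pt < 4; ++pt) {
        for (int m = 0; m < 3; ++m) gP(idx[pt], m) += pg.gP[pt*3 + m];
        gR[idx[pt]] += pg.gR[pt];
      }
    }
  }
  return List::create(_["cost"] = total,
                      _["overlap_count"] = count,
                      _["max_D"] = (pairs.empty() ? NA_REAL : maxD),
                      _["n_pairs"] = (int)pairs.size(),
                      _["grad_points"] = gP, _["grad_radii"] = gR);
}
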