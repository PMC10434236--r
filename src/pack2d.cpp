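// Two-dimensional disk packing on a square face: random sequential placement
// followed by repulsive relaxation under a radius ramp (pressure-increase
// style).  Deterministic given R's RNG state.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Relax one sweep at radius scale s; returns number of overlapping pairs.
static int relax_sweep(std::vector<double>& x, std::vector<double>& y,
                       const std::vector<double>& r, double L, double s,
                       double over_relax, double slack) {
  int n = (int)x.size();
  if (n == 0) return 0;
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, r[i]);
  double cell = std::max(2.0 * s * rmax * (1.0 + slack), 1e-6);
  int ncell = std::max(1, (int)std::floor(L / cell));
  cell = L / ncell;
  std::vector<std::vector<int> > grid(ncell * ncell);
  for (int i = 0; i < n; ++i) {
    int cx = std::min(ncell - 1, std::max(0, (int)std::floor(x[i] / cell)));
    int cy = std::min(ncell - 1, std::max(0, (int)std::floor(y[i] / cell)));
    grid[cy * ncell + cx].push_back(i);
  }
  int overlaps = 0;
  for (int i = 0; i < n; ++i) {
    int cx = std::min(ncell - 1, std::max(0, (int)std::floor(x[i] / cell)));
    int cy = std::min(ncell - 1, std::max(0, (int)std::floor(y[i] / cell)));
    for (int ox = -1; ox <= 1; ++ox) {
      for (int oy = -1; oy <= 1; ++oy) {
        int gx = cx + ox, gy = cy + oy;
        if (gx < 0 || gy < 0 || gx >= ncell || gy >= ncell) continue;
        for (int j : grid[gy * ncell + gx]) {
          if (j <= i) continue;
          double dx = x[j] - x[i], dy = y[j] - y[i];
          double d2 = dx * dx + dy * dy;
          double target = s * (r[i] + r[j]) * (1.0 + slack);
          if (d2 >= target * target) continue;
          ++overlaps;
          double d = std::sqrt(d2);
          double ux, uy;
          if (d < 1e-9) {            // coincident centres: deterministic kick
            double ang = 2.399963229728653 * (i + 1);  // golden-angle spread
            ux = std::cos(ang); uy = std::sin(ang); d = 0.0;
          } else { ux = dx / d; uy = dy / d; }
          double push = 0.5 * (target - d) * over_relax;
          x[i] -= ux * push; y[i] -= uy * push;
          x[j] += ux * push; y[j] += uy * push;
        }
      }
    }
    // containment
    double m = s * r[i];
    if (x[i] < m) x[i] = m; else if (x[i] > L - m) x[i] = L - m;
    if (y[i] < m) y[i] = m; else if (y[i] > L - m) y[i] = L - m;
  }
  return overlaps;
}

static int count_overlaps(const std::vector<double>& x, const std::vector<double>& y,
                          const std::vector<double>& r, double L) {
  // strict check at scale 1, no slack (used for the final certificate)
  int n = (int)x.size(), bad = 0;
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, r[i]);
  double cell = std::max(2.0 * rmax, 1e-6);
  int ncell = std::max(1, (int)std::floor(L / cell));
  cell = L / ncell;
  std::vector<std::vector<int> > grid(ncell * ncell);
  for (int i = 0; i < n; ++i) {
    int cx = std::min(ncell - 1, std::max(0, (int)std::floor(x[i] / cell)));
    int cy = std::min(ncell - 1, std::max(0, (int)std::floor(y[i] / cell)));
    grid[cy * ncell + cx].push_back(i);
  }
  for (int i = 0; i < n; ++i) {
    int cx = std::min(ncell - 1, std::max(0, (int)std::floor(x[i] / cell)));
    int cy = std::min(ncell - 1, std::max(0, (int)std::floor(y[i] / cell)));
    for (int ox = -1; ox <= 1; ++ox)
      for (int oy = -1; oy <= 1; ++oy) {
        int gx = cx + ox, gy = cy + oy;
        if (gx < 0 || gy < 0 || gx >= ncell || gy >= ncell) continue;
        for (int j : grid[gy * ncell + gx]) {
          if (j <= i) continue;
          double dx = x[j] - x[i], dy = y[j] - y[i];
          double t = r[i] + r[j];
          if (dx * dx + dy * dy < t * t * (1.0 - 1e-12)) ++bad;
        }
      }
  }
  return bad;
}

// Pack disks of radii r in [0, L]^2.  If init is supplied, relax from those
// positions at full radius (used to re-pack a face whose target positions
// come from the dispersion draw); otherwise place at random and ramp the
// radius scale up from small values.
// [[Rcpp::export]]
List cpp_pack_disks(NumericVector r, double L,
                    Nullable<NumericMatrix> init = R_NilValue,
                    int ramp_steps = 60, int sweeps_per_step = 60,
                    int final_sweeps = 4000, double slack = 1e-4) {
  int n = r.size();
  std::vector<double> x(n), y(n), rr(n);
  for (int i = 0; i < n; ++i) rr[i] = r[i];
  RNGScope scope;
  bool from_init = init.isNotNull();
  if (from_init) {
    NumericMatrix im(init);
    for (int i = 0; i < n; ++i) {
      x[i] = std::min(std::max(im(i,0), rr[i]), L - rr[i]);
      y[i] = std::min(std::max(im(i,1), rr[i]), L - rr[i]);
    }
  } else {
    for (int i = 0; i < n; ++i) {
      x[i] = rr[i] + R::unif_rand() * std::max(L - 2.0*rr[i], 0.0);
      y[i] = rr[i] + R::unif_rand() * std::max(L - 2.0*rr[i], 0.0);
    }
  }
  double over_relax = 1.2;
  if (!from_init) {
    for (int step = 0; step < ramp_steps; ++step) {
      double s = 0.3 + 0.7 * (double)(step + 1) / ramp_steps;
      for (int sw = 0; sw < sweeps_per_step; ++sw)
        if (relax_sweep(x, y, rr, L, s, over_relax, slack) == 0) break;
    }
  }
  int sw = 0;
  for (; sw < final_sweeps; ++sw) {
    if (count_overlaps(x, y, rr, L) == 0) break;
    relax_sweep(x, y, rr, L, 1.0, over_relax, slack);
  }
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) { out(i,0) = x[i]; out(i,1) = y[i]; }
  return List::create(_["centres"] = out,
                      _["converged"] = (count_overlaps(x, y, rr, L) == 0),
                      _["sweeps"] = sw);
}
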