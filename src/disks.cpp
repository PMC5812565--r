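#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Continuous-space Brownian dynamics of hard disks in a periodic square box.
// Proposals are Gaussian steps of per-axis standard deviation sqrt(2 D dt);
// a proposal bringing any pair of centres (minimum image) closer than twice
// the disk radius is rejected and the disk stays put.  Pair checks go through
// a uniform cell grid; the grid is an accelerator only and cannot change
// outcomes relative to the brute-force check.

struct CellGrid {
  int ncell;           // cells per side (>= 1), cell size >= 2 * radius
  double box, cell;
  std::vector<std::vector<int> > members;
  std::vector<int> cell_of;

  void init(double box_, double min_cell, int n) {
    box = box_;
    ncell = (int)std::floor(box / min_cell);
    if (ncell < 1) ncell = 1;
    cell = box / ncell;
    members.assign((size_t)ncell * ncell, std::vector<int>());
    cell_of.assign(n, -1);
  }
  int index(double x, double y) const {
    int cx = (int)std::floor(x / cell); if (cx >= ncell) cx = ncell - 1; if (cx < 0) cx = 0;
    int cy = (int)std::floor(y / cell); if (cy >= ncell) cy = ncell - 1; if (cy < 0) cy = 0;
    return cx + ncell * cy;
  }
  void insert(int i, double x, double y) {
    int c = index(x, y);
    members[c].push_back(i);
    cell_of[i] = c;
  }
  void relocate(int i, double x, double y) {
    int c = index(x, y);
    if (c == cell_of[i]) return;
    std::vector<int> &old = members[cell_of[i]];
    for (size_t k = 0; k < old.size(); ++k)
      if (old[k] == i) { old[k] = old.back(); old.pop_back(); break; }
    members[c].push_back(i);
    cell_of[i] = c;
  }
};

static inline double min_image(double d, double box) {
  if (d > 0.5 * box) return d - box;
  if (d < -0.5 * box) return d + box;
  return d;
}

static inline double fwrap(double x, double box) {
  x -= box * std::floor(x / box);
  if (x >= box) x -= box;   // guard the x/box == 1 rounding edge
  return x;
}

// True if a disk centred at (x, y) would overlap any disk other than `self`.
static bool overlaps(const CellGrid &G, const std::vector<double> &px,
                     const std::vector<double> &py, double x, double y,
                     double dmin2, int self) {
  int cx = (int)std::floor(x / G.cell); if (cx >= G.ncell) cx = G.ncell - 1; if (cx < 0) cx = 0;
  int cy = (int)std::floor(y / G.cell); if (cy >= G.ncell) cy = G.ncell - 1; if (cy < 0) cy = 0;
  int reach = (G.ncell >= 3) ? 1 : G.ncell; // tiny grids: scan everything
  for (int dx = -reach; dx <= reach; ++dx) {
    for (int dy = -reach; dy <= reach; ++dy) {
      int cxx = (cx + dx + G.ncell) % G.ncell;
      int cyy = (cy + dy + G.ncell) % G.ncell;
      const std::vector<int> &cell = G.members[cxx + G.ncell * cyy];
      for (size_t k = 0; k < cell.size(); ++k) {
        int j = cell[k];
        if (j == self) continue;
        double ddx = min_image(x - px[j], G.box);
        double ddy = min_image(y - py[j], G.box);
        if (ddx * ddx + ddy * ddy < dmin2) return true;
      }
    }
  }
  return false;
}

// Rejection-sample `n` non-overlapping uniform centres; errors out after
// `max_attempts` failed draws (dense packings need a lattice seed instead).
// [[Rcpp::export]]
List place_disks_cpp(int n, double box, double radius, int max_attempts) {
  std::vector<double> px, py;
  px.reserve(n); py.reserve(n);
  CellGrid G;
  G.init(box, 2.0 * radius, n);
  double dmin2 = 4.0 * radius * radius;
  int attempts = 0;
  while ((int)px.size() < n) {
    if (++attempts > max_attempts)
      stop("could not place %d non-overlapping disks after %d attempts", n, max_attempts);
    double x = unif_rand() * box, y = unif_rand() * box;
    if (overlaps(G, px, py, x, y, dmin2, -1)) continue;
    int i = (int)px.size();
    px.push_back(x); py.push_back(y);
    G.insert(i, x, y);
  }
  return List::create(_["x"] = px, _["y"] = py);
}

// [[Rcpp::export]]
List disk_sim_cpp(NumericVector x0, NumericVector y0,
                  double box, double radius, double D, double dt,
                  int n_equil, int n_measure, IntegerVector record_steps,
                  bool exclusion, bool check_invariants) {
  int n = x0.size();
  std::vector<double> px(x0.begin(), x0.end());
  std::vector<double> py(y0.begin(), y0.end());
  std::vector<double> ux(n, 0.0), uy(n, 0.0);
  double sd = std::sqrt(2.0 * D * dt);
  double dmin2 = 4.0 * radius * radius;

  CellGrid G;
  G.init(box, 2.0 * radius, n);
  for (int i = 0; i < n; ++i) G.insert(i, px[i], py[i]);

  if (exclusion) {
    for (int i = 0; i < n; ++i)
      if (overlaps(G, px, py, px[i], py[i], dmin2 * (1.0 - 1e-12), i))
        stop("initial disk configuration overlaps");
  }

  int nRec = record_steps.size();
  NumericMatrix X(nRec, n), Y(nRec, n);
  int next = 0;
  long total = (long)n_equil + n_measure;
  for (long s = 1; s <= total; ++s) {
    for (int i = 0; i < n; ++i) {
      double nx = px[i] + sd * norm_rand();
      double ny = py[i] + sd * norm_rand();
      double wx = fwrap(nx, box), wy = fwrap(ny, box);
      if (exclusion && overlaps(G, px, py, wx, wy, dmin2, i)) continue;
      ux[i] += nx - px[i];
      uy[i] += ny - py[i];
      px[i] = wx; py[i] = wy;
      if (exclusion) G.relocate(i, wx, wy);
    }
    if (s == n_equil) {
      std::fill(ux.begin(), ux.end(), 0.0);
      std::fill(uy.begin(), uy.end(), 0.0);
    }
    if (s > n_equil) {
      int ms = (int)(s - n_equil);
      if (check_invariants && exclusion) {
        for (int i = 0; i < n; ++i)
          for (int j = i + 1; j < n; ++j) {
            double ddx = min_image(px[i] - px[j], box);
            double ddy = min_image(py[i] - py[j], box);
            if (ddx * ddx + ddy * ddy < dmin2 * (1.0 - 1e-12))
              stop("hard-disk overlap after step");
          }
      }
      while (next < nRec && record_steps[next] == ms) {
        for (int i = 0; i < n; ++i) {
          X(next, i) = ux[i];
          Y(next, i) = uy[i];
        }
        ++next;
      }
      if (next >= nRec) break;
    }
    if (s % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["x"] = X, _["y"] = Y,
                      _["xf"] = Rcpp::wrap(px), _["yf"] = Rcpp::wrap(py));
}
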