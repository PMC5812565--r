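#include <Rcpp.h>
using namespace Rcpp;

// Site codes shared with the R side: 0 = empty, 1 = completely-reflecting
// obstacle (CRO), 2 = partially-reflecting binding obstacle (PRO).
enum { SITE_EMPTY = 0, SITE_CRO = 1, SITE_PRO = 2 };

// Direction sampling follows the quartile rule: u < .25 left, < .5 right,
// < .75 up, otherwise down.  (row, col) with 0-based indices; "up" = row - 1.
static inline int draw_direction() {
  double u = unif_rand();
  if (u < 0.25) return 0;       // left
  if (u < 0.50) return 1;       // right
  if (u < 0.75) return 2;       // up
  return 3;                     // down
}

static inline int pwrap(int k, int n) {
  if (k < 0) return k + n;
  if (k >= n) return k - n;
  return k;
}

struct LatticeState {
  int n;                          // sites per side
  const int *kind;                // site kinds, column-major n x n
  std::vector<int> row, col;      // tracer lattice coordinates
  std::vector<double> ux, uy;     // unwrapped displacement, lattice units
  std::vector<int> occ;           // occupant tracer index per site, -1 = none
  bool exclusion;

  int site(int r, int c) const { return r + n * c; }
  bool on_pro(int i) const { return kind[site(row[i], col[i])] == SITE_PRO; }

  void dest_of(int i, int dir, int &r, int &c) const {
    r = row[i]; c = col[i];
    switch (dir) {
      case 0: c = pwrap(c - 1, n); break;
      case 1: c = pwrap(c + 1, n); break;
      case 2: r = pwrap(r - 1, n); break;
      default: r = pwrap(r + 1, n); break;
    }
  }

  void move(int i, int r, int c, int dir) {
    if (exclusion) {
      occ[site(row[i], col[i])] = -1;
      occ[site(r, c)] = i;
    }
    row[i] = r; col[i] = c;
    switch (dir) {
      case 0: ux[i] -= 1.0; break;
      case 1: ux[i] += 1.0; break;
      case 2: uy[i] -= 1.0; break;
      default: uy[i] += 1.0; break;
    }
  }
};

// Decide whether a bound tracer escapes its scaffold site this step.
// Standard rule: escape with probability p_escape (u < p).  The literal
// text-reading (u >= p) is kept behind a switch for comparison.
static inline bool escapes(double p_escape, bool literal) {
  double u = unif_rand();
  return literal ? (u >= p_escape) : (u < p_escape);
}

// One time step without tracer-tracer exclusion: every tracer is independent.
static void step_independent(LatticeState &S, double p_reflect, double p_escape,
                             bool literal_escape) {
  int nT = (int)S.row.size();
  for (int i = 0; i < nT; ++i) {
    if (S.on_pro(i) && !escapes(p_escape, literal_escape)) continue;
    int dir = draw_direction();
    int r, c;
    S.dest_of(i, dir, r, c);
    int k = S.kind[S.site(r, c)];
    if (k == SITE_CRO) continue;
    if (k == SITE_PRO && unif_rand() < p_reflect) continue;
    S.move(i, r, c, dir);
  }
}

// One time step with steric exclusion among tracers, as a sequential sweep
// with an optional second (recursive) pass over tracers whose first attempt
// was blocked by another tracer.  Directions are pre-drawn (pass two reuses
// them); a blocked tracer whose destination PRO was vacated in pass one
// re-applies the partial-reflection draw with a fresh variate.
static void step_exclusion(LatticeState &S, double p_reflect, double p_escape,
                           bool literal_escape, bool recursive,
                           std::vector<int> &dir_buf, std::vector<int> &blocked_buf) {
  int nT = (int)S.row.size();
  dir_buf.resize(nT);
  blocked_buf.clear();

  // Pass 0: pre-draw participation and directions for every tracer.
  for (int i = 0; i < nT; ++i) {
    if (S.on_pro(i) && !escapes(p_escape, literal_escape)) {
      dir_buf[i] = -1;
      continue;
    }
    dir_buf[i] = draw_direction();
  }

  // Pass 1: sequential hopping; tracers blocked by another tracer (on an
  // empty site or holding a PRO) are labelled for re-examination.
  for (int i = 0; i < nT; ++i) {
    int dir = dir_buf[i];
    if (dir < 0) continue;
    int r, c;
    S.dest_of(i, dir, r, c);
    int s = S.site(r, c);
    int k = S.kind[s];
    if (k == SITE_CRO) continue;
    if (S.occ[s] >= 0) { blocked_buf.push_back(i); continue; }
    if (k == SITE_PRO && unif_rand() < p_reflect) continue;
    S.move(i, r, c, dir);
  }

  if (!recursive) return;

  // Pass 2: re-examine the labelled set against their original destinations;
  // sites vacated during pass one now admit the hop.
  for (size_t b = 0; b < blocked_buf.size(); ++b) {
    int i = blocked_buf[b];
    int dir = dir_buf[i];
    int r, c;
    S.dest_of(i, dir, r, c);
    int s = S.site(r, c);
    if (S.occ[s] >= 0) continue;
    if (S.kind[s] == SITE_PRO && unif_rand() < p_reflect) continue;
    S.move(i, r, c, dir);
  }
}

// Core simulation driver.  Runs `n_anneal` unrecorded steps, zeroes the
// displacement accumulators, then runs `n_measure` steps recording unwrapped
// displacements (lattice units) at the 1-based step indices `record_steps`.
// Returns matrices [n_records x n_tracers] of x/y displacement plus final
// state and, optionally, the bound fraction sampled during annealing.
// [[Rcpp::export]]
List lattice_sim_cpp(int n_side, IntegerVector site_kind,
                     IntegerVector row0, IntegerVector col0,
                     bool exclusion, bool recursive,
                     double p_reflect, double p_escape,
                     int n_anneal, int n_measure,
                     IntegerVector record_steps,
                     int anneal_monitor_every,
                     bool literal_escape,
                     bool check_invariants) {
  int nT = row0.size();
  LatticeState S;
  S.n = n_side;
  S.kind = INTEGER(site_kind);
  S.exclusion = exclusion;
  S.row.assign(row0.begin(), row0.end());
  S.col.assign(col0.begin(), col0.end());
  S.ux.assign(nT, 0.0);
  S.uy.assign(nT, 0.0);
  if (exclusion) {
    S.occ.assign((size_t)n_side * n_side, -1);
    for (int i = 0; i < nT; ++i) {
      int s = S.site(S.row[i], S.col[i]);
      if (S.occ[s] >= 0) stop("tracers share a site under exclusion");
      S.occ[s] = i;
    }
  }
  for (int i = 0; i < nT; ++i) {
    int k = S.kind[S.site(S.row[i], S.col[i])];
    if (k == SITE_CRO) stop("tracer placed on a reflecting obstacle");
  }

  std::vector<int> dir_buf, blocked_buf;
  std::vector<double> anneal_bound;

  for (int s = 1; s <= n_anneal; ++s) {
    if (exclusion)
      step_exclusion(S, p_reflect, p_escape, literal_escape, recursive,
                     dir_buf, blocked_buf);
    else
      step_independent(S, p_reflect, p_escape, literal_escape);
    if (anneal_monitor_every > 0 && s % anneal_monitor_every == 0) {
      int nb = 0;
      for (int i = 0; i < nT; ++i) if (S.on_pro(i)) ++nb;
      anneal_bound.push_back(nT > 0 ? (double)nb / nT : 0.0);
    }
    if (s % 65536 == 0) Rcpp::checkUserInterrupt();
  }

  // Measurement clock starts here: displacement measured from this origin.
  std::fill(S.ux.begin(), S.ux.end(), 0.0);
  std::fill(S.uy.begin(), S.uy.end(), 0.0);

  int nRec = record_steps.size();
  NumericMatrix X(nRec, nT), Y(nRec, nT);
  int next = 0;
  for (int s = 1; s <= n_measure && next < nRec; ++s) {
    if (exclusion)
      step_exclusion(S, p_reflect, p_escape, literal_escape, recursive,
                     dir_buf, blocked_buf);
    else
      step_independent(S, p_reflect, p_escape, literal_escape);
    if (check_invariants && exclusion) {
      std::vector<bool> seen((size_t)n_side * n_side, false);
      for (int i = 0; i < nT; ++i) {
        int st = S.site(S.row[i], S.col[i]);
        if (seen[st]) stop("exclusion violated: two tracers share a site");
        seen[st] = true;
        if (S.kind[st] == SITE_CRO) stop("tracer rests on a reflecting obstacle");
      }
    }
    while (next < nRec && record_steps[next] == s) {
      for (int i = 0; i < nT; ++i) {
        X(next, i) = S.ux[i];
        Y(next, i) = S.uy[i];
      }
      ++next;
    }
    if (s % 65536 == 0) Rcpp::checkUserInterrupt();
  }

  LogicalVector bound(nT);
  IntegerVector rowf(nT), colf(nT);
  for (int i = 0; i < nT; ++i) {
    bound[i] = S.on_pro(i);
    rowf[i] = S.row[i];
    colf[i] = S.col[i];
  }

  return List::create(_["x"] = X, _["y"] = Y,
                      _["row"] = rowf, _["col"] = colf,
                      _["bound"] = bound,
                      _["anneal_bound_fraction"] = wrap(anneal_bound));
}

// Single-hop semantics exposed for unit testing: returns the outcome of one
// attempted hop of tracer `i` given a pre-chosen direction.  Mirrors the
// checks of the sequential pass exactly.
// [[Rcpp::export]]
List attempt_hop_cpp(int n_side, IntegerVector site_kind,
                     IntegerVector row, IntegerVector col,
                     int i, int dir, bool exclusion,
                     double p_reflect, double u_reflect) {
  int nT = row.size();
  LatticeState S;
  S.n = n_side;
  S.kind = INTEGER(site_kind);
  S.exclusion = exclusion;
  S.row.assign(row.begin(), row.end());
  S.col.assign(col.begin(), col.end());
  S.ux.assign(nT, 0.0);
  S.uy.assign(nT, 0.0);
  if (exclusion) {
    S.occ.assign((size_t)n_side * n_side, -1);
    for (int t = 0; t < nT; ++t) S.occ[S.site(S.row[t], S.col[t])] = t;
  }
  int r, c;
  S.dest_of(i - 1, dir, r, c);
  int s = S.site(r, c);
  int k = S.kind[s];
  bool moved = false, blocked_by_dt = false, newly_bound = false;
  if (k == SITE_CRO) {
    // complete reflection
  } else if (exclusion && S.occ[s] >= 0) {
    blocked_by_dt = true;
  } else if (k == SITE_PRO && u_reflect < p_reflect) {
    // partial reflection
  } else {
    S.move(i - 1, r, c, dir);
    moved = true;
    newly_bound = (k == SITE_PRO);
  }
  return List::create(_["moved"] = moved,
                      _["blocked_by_dt"] = blocked_by_dt,
                      _["newly_bound"] = newly_bound,
                      _["row"] = S.row[i - 1] ,
                      _["col"] = S.col[i - 1]);
}

// One exclusion-mode time step with externally supplied hop directions
// (0 left, 1 right, 2 up, 3 down, -1 sit out), exposing the sequential pass
// and the optional recursion for direct testing of blocking resolution.
// Reflection draws, if a PRO destination is involved, use the RNG.
// [[Rcpp::export]]
List lattice_step_cpp(int n_side, IntegerVector site_kind,
                      IntegerVector row0, IntegerVector col0,
                      IntegerVector directions, bool recursive,
                      double p_reflect) {
  int nT = row0.size();
  LatticeState S;
  S.n = n_side;
  S.kind = INTEGER(site_kind);
  S.exclusion = true;
  S.row.assign(row0.begin(), row0.end());
  S.col.assign(col0.begin(), col0.end());
  S.ux.assign(nT, 0.0);
  S.uy.assign(nT, 0.0);
  S.occ.assign((size_t)n_side * n_side, -1);
  for (int i = 0; i < nT; ++i) {
    int s = S.site(S.row[i], S.col[i]);
    if (S.occ[s] >= 0) stop("tracers share a site under exclusion");
    S.occ[s] = i;
  }

  std::vector<int> dir(directions.begin(), directions.end());
  std::vector<int> blocked;
  LogicalVector moved(nT), was_blocked(nT);

  for (int i = 0; i < nT; ++i) {
    if (dir[i] < 0) continue;
    int r, c;
    S.dest_of(i, dir[i], r, c);
    int s = S.site(r, c);
    int k = S.kind[s];
    if (k == SITE_CRO) continue;
    if (S.occ[s] >= 0) { blocked.push_back(i); was_blocked[i] = true; continue; }
    if (k == SITE_PRO && unif_rand() < p_reflect) continue;
    S.move(i, r, c, dir[i]);
    moved[i] = true;
  }
  if (recursive) {
    for (size_t b = 0; b < blocked.size(); ++b) {
      int i = blocked[b];
      int r, c;
      S.dest_of(i, dir[i], r, c);
      int s = S.site(r, c);
      if (S.occ[s] >= 0) continue;
      if (S.kind[s] == SITE_PRO && unif_rand() < p_reflect) continue;
      S.move(i, r, c, dir[i]);
      moved[i] = true;
    }
  }

  IntegerVector rowf(nT), colf(nT);
  for (int i = 0; i < nT; ++i) { rowf[i] = S.row[i]; colf[i] = S.col[i]; }
  return List::create(_["row"] = rowf, _["col"] = colf,
                      _["moved"] = moved, _["blocked_by_dt"] = was_blocked);
}
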