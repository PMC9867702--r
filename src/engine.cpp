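#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdlib>
using namespace Rcpp;

// Hourly cellular-automaton engine for cell growth in a porous bioprinted
// scaffold. All randomness is drawn from R's RNG (unif_rand / norm_rand)
// under a strict draw protocol so that a pure-R reference implementation
// (R/reference.R) can reproduce trajectories draw-for-draw:
//
// per hour t = 1..horizon (clocks incremented first):
//   1. death:    Fisher-Yates permutation of quiescent ids (ascending id
//                order input); per cell past its threshold, one unif draw.
//   2. division: permutation of eligible proliferative ids; per attempt:
//                capacity lottery draw (only when live >= capacity), then
//                vacancy pick draw on the lowest non-empty Moore shell,
//                then daughter draws: doubling time (rejection normals),
//                death threshold (1 unif), movement jitter (1 unif).
//   3. movement: permutation of due live ids; per cell: one direction draw
//                if any feasible target, then one jitter draw (always).
//   4. re-entry: permutation of pre-threshold quiescent ids; one lottery
//                draw only when live >= capacity and a vacancy exists.
//
// Seeding (cell = 0..c_initial-1): site rejection draws, doubling time,
// desync clock draw (desync mode only), death threshold, movement jitter.
//
// Direction convention (index 0..5): +x right, -x left, +y up, -y down,
// +z forward, -z backward. Shell enumeration order: dz outer, dy, dx inner.

static const int DX[6] = {1, -1, 0, 0, 0, 0};
static const int DY[6] = {0, 0, 1, -1, 0, 0};
static const int DZ[6] = {0, 0, 0, 0, 1, -1};

static inline int runif_int(int n) {
  int j = (int)std::floor(unif_rand() * n);
  if (j >= n) j = n - 1;
  if (j < 0) j = 0;
  return j;
}

static void fy_permute(std::vector<int> &v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = runif_int(i + 1);
    std::swap(v[i], v[j]);
  }
}

// dominant displacement axis, priority x > y > z on ties; -1 if zero vector
static inline int dominant_dir(int dx, int dy, int dz) {
  int ax = std::abs(dx), ay = std::abs(dy), az = std::abs(dz);
  if (ax == 0 && ay == 0 && az == 0) return -1;
  if (ax >= ay && ax >= az) return dx > 0 ? 0 : 1;
  if (ay >= az) return dy > 0 ? 2 : 3;
  return dz > 0 ? 4 : 5;
}

// Euclidean distance from (x,y,z) to nearest site of any pore box
// (boxes are half-open [x0, x0+wx) in lattice units); closest lattice site
// of a box is the coordinate-wise clamp. dir: dominant axis of the
// displacement to that site; ties between boxes broken by first box in
// row order (strict < comparison).
static void pore_distance(const IntegerMatrix &pores, int x, int y, int z,
                          double &d, int &dir) {
  double best = R_PosInf;
  int bx = 0, by = 0, bz = 0;
  bool found = false;
  for (int b = 0; b < pores.nrow(); ++b) {
    int cx = std::min(std::max(x, pores(b, 0)), pores(b, 0) + pores(b, 3) - 1);
    int cy = std::min(std::max(y, pores(b, 1)), pores(b, 1) + pores(b, 4) - 1);
    int cz = std::min(std::max(z, pores(b, 2)), pores(b, 2) + pores(b, 5) - 1);
    double dd = (double)(cx - x) * (cx - x) + (double)(cy - y) * (cy - y) +
                (double)(cz - z) * (cz - z);
    if (dd < best) {
      best = dd;
      bx = cx; by = cy; bz = cz;
      found = true;
    }
  }
  if (!found) {
    d = R_PosInf;
    dir = -1;
    return;
  }
  d = std::sqrt(best);
  dir = dominant_dir(bx - x, by - y, bz - z);
}

struct Engine {
  int nx, ny, nz;
  IntegerMatrix pores;
  std::vector<int> occ;  // -1 pore, 0 empty, cell id (1-based) otherwise
  std::vector<int> hyd;  // ascending linear indices of hydrogel sites

  int c_initial, capacity;
  double p_abort, mu, sigma, cd_min, cd_max, p_death, m_c;
  int jitter_max, Lc;
  double Lp, alpha, beta;
  bool biased, desync, reentry;
  int horizon;

  // cell state (index = id - 1); phase 0 proliferative, 1 quiescent, 2 dead
  std::vector<int> cx, cy, cz, phase;
  std::vector<double> dtime, cyc, qcl, thr, nmv;
  long live, births, deaths, aborts;

  inline int sidx(int x, int y, int z) const { return x + nx * (y + ny * z); }
  inline bool inb(int x, int y, int z) const {
    return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
  }

  double samp_dtime() {
    double v;
    do { v = mu + sigma * norm_rand(); } while (v <= 0);
    return v;
  }
  double samp_thr() { return cd_min + unif_rand() * (cd_max - cd_min); }
  double samp_jitter() { return (double)runif_int(jitter_max + 1); }

  void add_cell(int x, int y, int z, double t) {
    cx.push_back(x); cy.push_back(y); cz.push_back(z);
    phase.push_back(0);
    dtime.push_back(samp_dtime());
    cyc.push_back(0.0);
    qcl.push_back(0.0);
    thr.push_back(samp_thr());
    nmv.push_back(t + m_c + samp_jitter());
    occ[sidx(x, y, z)] = (int)cx.size();
    ++live;
  }

  void seed_population() {
    int nh = (int)hyd.size();
    for (int c = 0; c < c_initial; ++c) {
      int s;
      do { s = hyd[runif_int(nh)]; } while (occ[s] != 0);
      int x = s % nx, y = (s / nx) % ny, z = s / (nx * ny);
      cx.push_back(x); cy.push_back(y); cz.push_back(z);
      phase.push_back(0);
      dtime.push_back(samp_dtime());
      cyc.push_back(desync ? unif_rand() * dtime.back() : 0.0);
      qcl.push_back(0.0);
      thr.push_back(samp_thr());
      nmv.push_back(m_c + samp_jitter());
      occ[s] = (int)cx.size();
      ++live;
    }
  }

  // vacant hydrogel sites at Chebyshev distance exactly k
  void shell_vacancies(int x, int y, int z, int k, std::vector<int> &out) {
    out.clear();
    for (int dz = -k; dz <= k; ++dz)
      for (int dy = -k; dy <= k; ++dy)
        for (int dx = -k; dx <= k; ++dx) {
          int m = std::max(std::max(std::abs(dx), std::abs(dy)), std::abs(dz));
          if (m != k) continue;
          int tx = x + dx, ty = y + dy, tz = z + dz;
          if (!inb(tx, ty, tz)) continue;
          if (occ[sidx(tx, ty, tz)] == 0) out.push_back(sidx(tx, ty, tz));
        }
  }

  bool any_vacancy_order123(int x, int y, int z) {
    std::vector<int> v;
    for (int k = 1; k <= 3; ++k) {
      shell_vacancies(x, y, z, k, v);
      if (!v.empty()) return true;
    }
    return false;
  }

  // movement weights over the six axis directions; feasible = in-bounds
  // vacant hydrogel target. Biased form: w = 1 + alpha*N_i + beta*Phi_i.
  void move_weights(int i, double *w) {
    int x = cx[i], y = cy[i], z = cz[i];
    bool feas[6];
    for (int d = 0; d < 6; ++d) {
      int tx = x + DX[d], ty = y + DY[d], tz = z + DZ[d];
      feas[d] = inb(tx, ty, tz) && occ[sidx(tx, ty, tz)] == 0;
    }
    if (!biased) {
      for (int d = 0; d < 6; ++d) w[d] = feas[d] ? 1.0 : 0.0;
      return;
    }
    double N[6] = {0, 0, 0, 0, 0, 0};
    for (int dz = -Lc; dz <= Lc; ++dz)
      for (int dy = -Lc; dy <= Lc; ++dy)
        for (int dx = -Lc; dx <= Lc; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          int tx = x + dx, ty = y + dy, tz = z + dz;
          if (!inb(tx, ty, tz)) continue;
          int o = occ[sidx(tx, ty, tz)];
          if (o > 0 && phase[o - 1] != 2) {
            int d = dominant_dir(dx, dy, dz);
            if (d >= 0) N[d] += 1.0;
          }
        }
    double pd; int pdir;
    pore_distance(pores, x, y, z, pd, pdir);
    double phi[6] = {0, 0, 0, 0, 0, 0};
    if (pdir >= 0 && pd <= Lp) phi[pdir] = 1.0 - pd / Lp;
    for (int d = 0; d < 6; ++d)
      w[d] = feas[d] ? 1.0 + alpha * N[d] + beta * phi[d] : 0.0;
  }

  void step(int t) {
    int n0 = (int)cx.size();
    // 1. clocks
    for (int i = 0; i < n0; ++i) {
      if (phase[i] == 0) cyc[i] += 1.0;
      else if (phase[i] == 1) qcl[i] += 1.0;
    }
    // 2. death
    {
      std::vector<int> q;
      for (int i = 0; i < n0; ++i) if (phase[i] == 1) q.push_back(i);
      fy_permute(q);
      for (size_t k = 0; k < q.size(); ++k) {
        int i = q[k];
        if (qcl[i] > thr[i]) {
          if (unif_rand() < p_death) {
            phase[i] = 2;
            --live;
            ++deaths;
          }
        }
      }
    }
    // 3. division
    {
      std::vector<int> e;
      for (int i = 0; i < n0; ++i)
        if (phase[i] == 0 && cyc[i] >= dtime[i]) e.push_back(i);
      fy_permute(e);
      std::vector<int> vac;
      for (size_t k = 0; k < e.size(); ++k) {
        int i = e[k];
        if (live >= capacity) {
          if (unif_rand() < p_abort) {
            phase[i] = 1;
            qcl[i] = 0.0;
            ++aborts;
            continue;
          }
        }
        int site = -1;
        for (int ord = 1; ord <= 3; ++ord) {
          shell_vacancies(cx[i], cy[i], cz[i], ord, vac);
          if (!vac.empty()) {
            site = vac[runif_int((int)vac.size())];
            break;
          }
        }
        if (site >= 0) {
          int x = site % nx, y = (site / nx) % ny, z = site / (nx * ny);
          add_cell(x, y, z, (double)t);
          ++births;
          cyc[i] = 0.0;
        } else {
          phase[i] = 1;
          qcl[i] = 0.0;
        }
      }
    }
    // 4. movement
    {
      int n1 = (int)cx.size();
      std::vector<int> mv;
      for (int i = 0; i < n1; ++i)
        if (phase[i] != 2 && (double)t >= nmv[i]) mv.push_back(i);
      fy_permute(mv);
      double w[6];
      for (size_t k = 0; k < mv.size(); ++k) {
        int i = mv[k];
        move_weights(i, w);
        double tot = w[0] + w[1] + w[2] + w[3] + w[4] + w[5];
        if (tot > 0) {
          double u = unif_rand() * tot, cum = 0.0;
          int dir = 5;
          for (int d = 0; d < 6; ++d) {
            cum += w[d];
            if (u < cum) { dir = d; break; }
          }
          int tx = cx[i] + DX[dir], ty = cy[i] + DY[dir], tz = cz[i] + DZ[dir];
          occ[sidx(cx[i], cy[i], cz[i])] = 0;
          occ[sidx(tx, ty, tz)] = i + 1;
          cx[i] = tx; cy[i] = ty; cz[i] = tz;
        }
        nmv[i] = (double)t + m_c + samp_jitter();
      }
    }
    // 5. quiescence re-entry (only before the per-cell death threshold)
    if (reentry) {
      int n1 = (int)cx.size();
      std::vector<int> q;
      for (int i = 0; i < n1; ++i)
        if (phase[i] == 1 && qcl[i] <= thr[i]) q.push_back(i);
      fy_permute(q);
      for (size_t k = 0; k < q.size(); ++k) {
        int i = q[k];
        if (!any_vacancy_order123(cx[i], cy[i], cz[i])) continue;
        // re-entering the cycle passes the same lottery as a division
        // attempt at capacity: probability 1 - p_abort per hour
        if (unif_rand() >= p_abort) {
          phase[i] = 0;
          cyc[i] = 0.0;
          qcl[i] = 0.0;
        }
      }
    }
  }

  NumericVector ts_row(int t) {
    int np = 0, nq = 0;
    for (size_t i = 0; i < phase.size(); ++i) {
      if (phase[i] == 0) ++np;
      else if (phase[i] == 1) ++nq;
    }
    return NumericVector::create((double)t, (double)live, (double)deaths_total(),
                                 (double)np, (double)nq, (double)births,
                                 (double)deaths, (double)aborts);
  }
  long deaths_total() { return deaths; }

  IntegerMatrix snapshot() {
    int n = (int)cx.size();
    IntegerMatrix m(n, 5);
    for (int i = 0; i < n; ++i) {
      m(i, 0) = i + 1;
      m(i, 1) = cx[i];
      m(i, 2) = cy[i];
      m(i, 3) = cz[i];
      m(i, 4) = phase[i];
    }
    colnames(m) = CharacterVector::create("id", "x", "y", "z", "phase");
    return m;
  }

  DataFrame cell_table() {
    int n = (int)cx.size();
    IntegerVector id(n), X(n), Y(n), Z(n), ph(n);
    NumericVector dt(n), cc(n), qc(n), th(n), nm(n);
    for (int i = 0; i < n; ++i) {
      id[i] = i + 1; X[i] = cx[i]; Y[i] = cy[i]; Z[i] = cz[i];
      ph[i] = phase[i]; dt[i] = dtime[i]; cc[i] = cyc[i]; qc[i] = qcl[i];
      th[i] = thr[i]; nm[i] = nmv[i];
    }
    return DataFrame::create(
        Named("id") = id, Named("x") = X, Named("y") = Y, Named("z") = Z,
        Named("phase") = ph, Named("doubling_time") = dt,
        Named("cycle_clock") = cc, Named("quiescence_clock") = qc,
        Named("death_threshold") = th, Named("next_move_at") = nm);
  }
};

// [[Rcpp::export]]
List cpp_run(int nx, int ny, int nz, IntegerMatrix pores, int c_initial,
             int capacity, double p_abort, double mu, double sigma,
             double cd_min, double cd_max, double p_death, double m_c,
             int jitter_max, int Lc, double Lp, double alpha, double beta,
             bool biased, bool desync, bool reentry, int horizon,
             IntegerVector snapshot_hours, bool record_states) {
  Engine E;
  E.nx = nx; E.ny = ny; E.nz = nz; E.pores = pores;
  E.c_initial = c_initial; E.capacity = capacity; E.p_abort = p_abort;
  E.mu = mu; E.sigma = sigma; E.cd_min = cd_min; E.cd_max = cd_max;
  E.p_death = p_death; E.m_c = m_c; E.jitter_max = jitter_max;
  E.Lc = Lc; E.Lp = Lp; E.alpha = alpha; E.beta = beta;
  E.biased = biased; E.desync = desync; E.reentry = reentry;
  E.horizon = horizon;
  E.live = 0; E.births = 0; E.deaths = 0; E.aborts = 0;

  long N = (long)nx * ny * nz;
  E.occ.assign(N, 0);
  for (int b = 0; b < pores.nrow(); ++b) {
    for (int z = pores(b, 2); z < pores(b, 2) + pores(b, 5); ++z)
      for (int y = pores(b, 1); y < pores(b, 1) + pores(b, 4); ++y)
        for (int x = pores(b, 0); x < pores(b, 0) + pores(b, 3); ++x)
          E.occ[E.sidx(x, y, z)] = -1;
  }
  for (long s = 0; s < N; ++s)
    if (E.occ[s] == 0) E.hyd.push_back((int)s);
  if (c_initial > (int)E.hyd.size())
    stop("c_initial exceeds the number of hydrogel sites");

  E.seed_population();

  NumericMatrix ts(horizon + 1, 8);
  colnames(ts) = CharacterVector::create("hour", "live", "dead",
                                         "proliferative", "quiescent",
                                         "births", "deaths", "aborts");
  ts(0, _) = E.ts_row(0);

  std::vector<bool> snap_at(horizon + 1, false);
  for (int k = 0; k < snapshot_hours.size(); ++k) {
    int h = snapshot_hours[k];
    if (h >= 0 && h <= horizon) snap_at[h] = true;
  }
  List snaps;
  if (snap_at[0]) snaps.push_back(E.snapshot(), "h0");
  List states;
  if (record_states) states.push_back(E.cell_table(), "t0");

  for (int t = 1; t <= horizon; ++t) {
    E.step(t);
    ts(t, _) = E.ts_row(t);
    if (snap_at[t]) {
      char buf[16];
      std::snprintf(buf, sizeof(buf), "h%d", t);
      snaps.push_back(E.snapshot(), buf);
    }
    if (record_states) {
      char buf[16];
      std::snprintf(buf, sizeof(buf), "t%d", t);
      states.push_back(E.cell_table(), buf);
    }
  }

  return List::create(Named("timeseries") = ts, Named("snapshots") = snaps,
                      Named("states") = states,
                      Named("cells") = E.cell_table());
}

// Standalone movement-probability evaluation used by the exported R API.
// occ codes: -1 pore, 0 empty, >0 id of a cell; `phases` maps id -> phase.
// [[Rcpp::export]]
NumericVector cpp_move_probs(IntegerVector occ, int nx, int ny, int nz,
                             IntegerMatrix pores, IntegerVector phases,
                             int x, int y, int z, bool biased, double alpha,
                             double beta, int Lc, double Lp) {
  Engine E;
  E.nx = nx; E.ny = ny; E.nz = nz; E.pores = pores;
  E.biased = biased; E.alpha = alpha; E.beta = beta; E.Lc = Lc; E.Lp = Lp;
  E.occ.assign(occ.begin(), occ.end());
  E.phase.assign(phases.begin(), phases.end());
  int id = E.occ[E.sidx(x, y, z)];
  if (id <= 0) stop("no cell at the queried position");
  E.cx.assign(E.phase.size(), 0);
  E.cy.assign(E.phase.size(), 0);
  E.cz.assign(E.phase.size(), 0);
  E.cx[id - 1] = x; E.cy[id - 1] = y; E.cz[id - 1] = z;
  double w[6];
  E.move_weights(id - 1, w);
  double tot = 0;
  for (int d = 0; d < 6; ++d) tot += w[d];
  NumericVector p(6);
  if (tot > 0)
    for (int d = 0; d < 6; ++d) p[d] = w[d] / tot;
  p.names() = CharacterVector::create("right", "left", "up", "down",
                                      "forward", "backward");
  return p;
}

// Euclidean distance (and dominant direction) to the nearest pore site for
// each queried position; dir codes 0..5 as in the engine, -1 when no pore.
// [[Rcpp::export]]
List cpp_pore_distance(IntegerMatrix pores, IntegerMatrix pos) {
  int n = pos.nrow();
  NumericVector d(n);
  IntegerVector dir(n);
  for (int i = 0; i < n; ++i) {
    double dd; int dr;
    pore_distance(pores, pos(i, 0), pos(i, 1), pos(i, 2), dd, dr);
    d[i] = dd;
    dir[i] = dr;
  }
  return List::create(Named("distance") = d, Named("direction") = dir);
}
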