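#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <cstring>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// PCG32 generator: the simulator's own RNG so that trajectories are
// bit-reproducible for a given (arena, cfg, seed) independently of R's RNG.
// State crosses the R boundary as a 16-byte raw vector.
// ---------------------------------------------------------------------------
struct PCG {
  uint64_t state, inc;
  PCG() : state(0), inc(1) {}
  explicit PCG(uint64_t seed, uint64_t seq = 54u) {
    state = 0u;
    inc = (seq << 1u) | 1u;
    next();
    state += seed;
    next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31u));
  }
  double u01() { return next() * (1.0 / 4294967296.0); }
  // unbiased integer in [0, n)
  int bounded(int n) {
    if (n <= 1) return 0;
    uint32_t un = (uint32_t)n;
    uint32_t threshold = (uint32_t)(-un) % un;
    for (;;) {
      uint32_t r = next();
      if (r >= threshold) return (int)(r % un);
    }
  }
};

static RawVector rng_save(const PCG& g) {
  RawVector out(16);
  std::memcpy(&out[0], &g.state, 8);
  std::memcpy(&out[8], &g.inc, 8);
  return out;
}
static PCG rng_load(const RawVector& raw) {
  if (raw.size() != 16) stop("corrupt RNG state");
  PCG g;
  std::memcpy(&g.state, &raw[0], 8);
  std::memcpy(&g.inc, &raw[8], 8);
  return g;
}

// [[Rcpp::export]]
RawVector cpp_rng_new(double seed) {
  PCG g((uint64_t)seed);
  return rng_save(g);
}

// ---------------------------------------------------------------------------
// Simulation state. Lattices are stored row-major (idx = r*W + c) with
// 0-based (row, col); conversion to/from R's column-major matrices happens
// only at the boundary.
// ---------------------------------------------------------------------------
struct Sim {
  int H = 0, W = 0;
  std::vector<uint8_t> mask;
  std::vector<double> height;
  bool has_height = false;
  std::vector<double> trail;
  std::vector<int> occ;           // particle index + 1, or 0
  std::vector<double> pr, pc, ph; // continuous row, col, heading (deg)
  std::vector<int> site_r, site_c;
  // config
  double SA = 45, RA = 45, SO = 9, SS = 1, D = 5, rho = 0.1;
  double wh = 0, wf = 2.55, hmax = std::numeric_limits<double>::infinity();
  int kdiff = 3;
  int g_window = 9, g_min = 1, g_max = 10, g_interval = 5;
  int s_window = 5, s_min = 1, s_interval = 5;
  PCG rng;

  inline int idx(int r, int c) const { return r * W + c; }
  inline bool in_grid(int r, int c) const {
    return r >= 0 && r < H && c >= 0 && c < W;
  }
  inline bool passable(int r, int c) const {
    if (!mask[idx(r, c)]) return false;
    if (has_height && height[idx(r, c)] >= hmax) return false;
    return true;
  }
  int n() const { return (int)pr.size(); }

  // effective sensed value: trail minus the height penalty; -Inf outside.
  inline double sense_at(int r, int c) const {
    if (!in_grid(r, c) || !mask[idx(r, c)])
      return -std::numeric_limits<double>::infinity();
    double v = trail[idx(r, c)];
    if (has_height) v -= wh * height[idx(r, c)];
    return v;
  }

  double steer(double heading, double prow, double pcol) {
    const double d2r = M_PI / 180.0;
    double vals[3];
    double offs[3] = {-SA, 0.0, SA};
    for (int s = 0; s < 3; ++s) {
      double a = (heading + offs[s]) * d2r;
      int sr = (int)std::llround(prow + SO * std::sin(a));
      int sc = (int)std::llround(pcol + SO * std::cos(a));
      vals[s] = sense_at(sr, sc);
    }
    double L = vals[0], F = vals[1], R = vals[2];
    double h = heading;
    if (L > F && L > R) {
      h -= RA;
    } else if (R > F && R > L) {
      h += RA;
    } else if (F < L && F < R && L == R) {
      h += (rng.u01() < 0.5) ? -RA : RA;
    } // else: front maximal / all equal / other ties -> unchanged
    h -= 360.0 * std::floor(h / 360.0); // wrap to [0, 360)
    return h;
  }

  void project_stimuli() {
    for (size_t s = 0; s < site_r.size(); ++s)
      trail[idx(site_r[s], site_c[s])] += wf;
  }

  // one shuffled pass of sense-steer-move over all particles
  void move_pass() {
    int np = n();
    if (np == 0) return;
    std::vector<int> perm(np);
    for (int i = 0; i < np; ++i) perm[i] = i;
    for (int i = np - 1; i > 0; --i)
      std::swap(perm[i], perm[rng.bounded(i + 1)]);
    const double d2r = M_PI / 180.0;
    for (int k = 0; k < np; ++k) {
      int i = perm[k];
      ph[i] = steer(ph[i], pr[i], pc[i]);
      double a = ph[i] * d2r;
      double nr = pr[i] + SS * std::sin(a);
      double nc = pc[i] + SS * std::cos(a);
      int tr = (int)std::llround(nr);
      int tc = (int)std::llround(nc);
      int cr = (int)std::llround(pr[i]);
      int cc = (int)std::llround(pc[i]);
      bool ok = in_grid(tr, tc) && passable(tr, tc) &&
                (occ[idx(tr, tc)] == 0 || (tr == cr && tc == cc));
      if (ok) {
        occ[idx(cr, cc)] = 0;
        occ[idx(tr, tc)] = i + 1;
        pr[i] = nr;
        pc[i] = nc;
        trail[idx(tr, tc)] += D;
      } else {
        ph[i] = rng.u01() * 360.0;
      }
    }
  }

  int window_count(int cr, int cc, int win) const {
    int half = win / 2, cnt = 0;
    for (int r = cr - half; r <= cr + half; ++r) {
      if (r < 0 || r >= H) continue;
      for (int c = cc - half; c <= cc + half; ++c) {
        if (c < 0 || c >= W) continue;
        if (occ[idx(r, c)]) ++cnt;
      }
    }
    return cnt;
  }

  void growth_pass() {
    int np = n();
    std::vector<int> order(np);
    for (int i = 0; i < np; ++i) order[i] = i;
    for (int i = np - 1; i > 0; --i)
      std::swap(order[i], order[rng.bounded(i + 1)]);
    const int dr[4] = {-1, 1, 0, 0};
    const int dc[4] = {0, 0, -1, 1};
    for (int k = 0; k < np; ++k) {
      int i = order[k];
      if (occ[idx((int)std::llround(pr[i]), (int)std::llround(pc[i]))] != i + 1)
        continue; // defensive; should not happen
      int cr = (int)std::llround(pr[i]);
      int cc = (int)std::llround(pc[i]);
      int cnt = window_count(cr, cc, g_window); // includes self
      if (cnt < g_min || cnt > g_max) continue;
      int free_r[4], free_c[4], nfree = 0;
      for (int d = 0; d < 4; ++d) {
        int r = cr + dr[d], c = cc + dc[d];
        if (in_grid(r, c) && passable(r, c) && occ[idx(r, c)] == 0) {
          free_r[nfree] = r;
          free_c[nfree] = c;
          ++nfree;
        }
      }
      if (nfree == 0) continue;
      int pick = rng.bounded(nfree);
      pr.push_back((double)free_r[pick]);
      pc.push_back((double)free_c[pick]);
      ph.push_back(rng.u01() * 360.0);
      occ[idx(free_r[pick], free_c[pick])] = (int)pr.size();
    }
  }

  void shrink_pass() {
    int np = n();
    std::vector<int> order(np);
    for (int i = 0; i < np; ++i) order[i] = i;
    for (int i = np - 1; i > 0; --i)
      std::swap(order[i], order[rng.bounded(i + 1)]);
    std::vector<uint8_t> dead(np, 0);
    for (int k = 0; k < np; ++k) {
      int i = order[k];
      if (dead[i]) continue;
      int cr = (int)std::llround(pr[i]);
      int cc = (int)std::llround(pc[i]);
      int others = window_count(cr, cc, s_window) - 1; // exclude self
      if (others < s_min) {
        dead[i] = 1;
        occ[idx(cr, cc)] = 0;
      }
    }
    // compact
    std::vector<double> npr, npc, nph;
    npr.reserve(np);
    npc.reserve(np);
    nph.reserve(np);
    for (int i = 0; i < np; ++i) {
      if (dead[i]) continue;
      npr.push_back(pr[i]);
      npc.push_back(pc[i]);
      nph.push_back(ph[i]);
      occ[idx((int)std::llround(pr[i]), (int)std::llround(pc[i]))] =
          (int)npr.size();
    }
    pr.swap(npr);
    pc.swap(npc);
    ph.swap(nph);
  }

  void diffuse_decay() {
    std::vector<double> out(trail.size(), 0.0);
    int half = kdiff / 2;
    for (int r = 0; r < H; ++r) {
      for (int c = 0; c < W; ++c) {
        double s = 0.0;
        int cnt = 0;
        for (int rr = r - half; rr <= r + half; ++rr) {
          if (rr < 0 || rr >= H) continue;
          for (int cc = c - half; cc <= c + half; ++cc) {
            if (cc < 0 || cc >= W) continue;
            s += trail[idx(rr, cc)];
            ++cnt;
          }
        }
        out[idx(r, c)] = (s / cnt) * (1.0 - rho);
      }
    }
    trail.swap(out);
  }

  void assert_exclusion() const {
    std::vector<uint8_t> seen(trail.size(), 0);
    for (int i = 0; i < n(); ++i) {
      int cr = (int)std::llround(pr[i]);
      int cc = (int)std::llround(pc[i]);
      if (!in_grid(cr, cc)) stop("exclusion check: particle off grid");
      if (!mask[idx(cr, cc)]) stop("exclusion check: particle off mask");
      if (seen[idx(cr, cc)]) stop("exclusion check: two particles share a cell");
      seen[idx(cr, cc)] = 1;
      if (occ[idx(cr, cc)] != i + 1) stop("exclusion check: occupancy desync");
    }
  }
};

// ---- boundary conversion helpers ------------------------------------------
static void fill_mask(Sim& S, const LogicalMatrix& mask) {
  S.H = mask.nrow();
  S.W = mask.ncol();
  S.mask.assign((size_t)S.H * S.W, 0);
  for (int r = 0; r < S.H; ++r)
    for (int c = 0; c < S.W; ++c) S.mask[S.idx(r, c)] = mask(r, c) ? 1 : 0;
}
static void fill_height(Sim& S, SEXP height) {
  if (Rf_isNull(height)) {
    S.has_height = false;
    return;
  }
  NumericMatrix h(height);
  if (h.nrow() != S.H || h.ncol() != S.W) stop("heightfield/mask dimension mismatch");
  S.has_height = true;
  S.height.assign((size_t)S.H * S.W, 0.0);
  for (int r = 0; r < S.H; ++r)
    for (int c = 0; c < S.W; ++c) S.height[S.idx(r, c)] = h(r, c);
}
static void fill_trail(Sim& S, const NumericMatrix& trail) {
  if (trail.nrow() != S.H || trail.ncol() != S.W) stop("trail dimension mismatch");
  S.trail.assign((size_t)S.H * S.W, 0.0);
  for (int r = 0; r < S.H; ++r)
    for (int c = 0; c < S.W; ++c) S.trail[S.idx(r, c)] = trail(r, c);
}
static void fill_particles(Sim& S, const NumericVector& pr,
                           const NumericVector& pc, const NumericVector& ph) {
  int np = pr.size();
  S.pr.assign(pr.begin(), pr.end());
  S.pc.assign(pc.begin(), pc.end());
  S.ph.assign(ph.begin(), ph.end());
  S.occ.assign((size_t)S.H * S.W, 0);
  for (int i = 0; i < np; ++i) {
    int r = (int)std::llround(pr[i]);
    int c = (int)std::llround(pc[i]);
    if (!S.in_grid(r, c)) stop("particle outside grid");
    if (!S.mask[S.idx(r, c)]) stop("particle on non-habitable cell");
    if (S.occ[S.idx(r, c)]) stop("two particles share a cell");
    S.occ[S.idx(r, c)] = i + 1;
  }
}
static void fill_cfg(Sim& S, const List& cfg) {
  S.SA = as<double>(cfg["sensor_angle"]);
  S.RA = as<double>(cfg["rotation_angle"]);
  S.SO = as<double>(cfg["sensor_offset"]);
  S.SS = as<double>(cfg["step_size"]);
  S.D = as<double>(cfg["deposit"]);
  S.rho = as<double>(cfg["decay"]);
  S.kdiff = as<int>(cfg["diffusion_kernel"]);
  S.wh = as<double>(cfg["height_weight"]);
  S.wf = as<double>(cfg["site_stimulus"]);
  if (cfg.containsElementNamed("height_cutoff") &&
      !Rf_isNull(cfg["height_cutoff"]))
    S.hmax = as<double>(cfg["height_cutoff"]);
  S.g_window = as<int>(cfg["growth_window"]);
  S.g_min = as<int>(cfg["growth_min"]);
  S.g_max = as<int>(cfg["growth_max"]);
  S.g_interval = as<int>(cfg["growth_interval"]);
  S.s_window = as<int>(cfg["shrink_window"]);
  S.s_min = as<int>(cfg["shrink_min"]);
  S.s_interval = as<int>(cfg["shrink_interval"]);
}
static void fill_sites(Sim& S, const IntegerMatrix& sites) {
  // sites: n x 2 matrix of 0-based (row, col)
  for (int i = 0; i < sites.nrow(); ++i) {
    if (!S.in_grid(sites(i, 0), sites(i, 1))) stop("site outside grid");
    S.site_r.push_back(sites(i, 0));
    S.site_c.push_back(sites(i, 1));
  }
}
static NumericMatrix mat_out(const Sim& S, const std::vector<double>& v) {
  NumericMatrix out(S.H, S.W);
  for (int r = 0; r < S.H; ++r)
    for (int c = 0; c < S.W; ++c) out(r, c) = v[S.idx(r, c)];
  return out;
}
static IntegerMatrix occ_out(const Sim& S) {
  IntegerMatrix out(S.H, S.W);
  for (int r = 0; r < S.H; ++r)
    for (int c = 0; c < S.W; ++c) out(r, c) = S.occ[S.idx(r, c)];
  return out;
}
static List state_out(Sim& S) {
  return List::create(_["row"] = NumericVector(S.pr.begin(), S.pr.end()),
                      _["col"] = NumericVector(S.pc.begin(), S.pc.end()),
                      _["heading"] = NumericVector(S.ph.begin(), S.ph.end()),
                      _["trail"] = mat_out(S, S.trail),
                      _["occupancy"] = occ_out(S),
                      _["rng"] = rng_save(S.rng));
}

// ---------------------------------------------------------------------------
// Exported stage functions (used by R wrappers and unit tests) and the full
// run loop. All share the Sim internals above so semantics cannot diverge.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_inoculate(LogicalMatrix mask, double d0, SEXP target, double seed) {
  Sim S;
  fill_mask(S, mask);
  S.occ.assign((size_t)S.H * S.W, 0);
  PCG g((uint64_t)seed);
  if (!Rf_isNull(target)) {
    // exactly `target` particles on distinct habitable cells
    int tgt = as<int>(target);
    std::vector<int> cells;
    for (int r = 0; r < S.H; ++r)
      for (int c = 0; c < S.W; ++c)
        if (S.mask[S.idx(r, c)]) cells.push_back(S.idx(r, c));
    if (tgt > (int)cells.size()) stop("target_population exceeds habitable cells");
    for (int i = (int)cells.size() - 1; i > 0; --i)
      std::swap(cells[i], cells[g.bounded(i + 1)]);
    for (int i = 0; i < tgt; ++i) {
      int r = cells[i] / S.W, c = cells[i] % S.W;
      S.pr.push_back((double)r);
      S.pc.push_back((double)c);
      S.ph.push_back(g.u01() * 360.0);
      S.occ[cells[i]] = (int)S.pr.size();
    }
  } else {
    for (int r = 0; r < S.H; ++r) {
      for (int c = 0; c < S.W; ++c) {
        if (!S.mask[S.idx(r, c)]) continue;
        if (g.u01() < d0) {
          S.pr.push_back((double)r);
          S.pc.push_back((double)c);
          S.ph.push_back(g.u01() * 360.0);
          S.occ[S.idx(r, c)] = (int)S.pr.size();
        }
      }
    }
  }
  S.rng = g;
  S.trail.assign((size_t)S.H * S.W, 0.0);
  return state_out(S);
}

// [[Rcpp::export]]
NumericMatrix cpp_diffuse_decay(NumericMatrix trail, int kernel, double rho,
                                bool toroidal) {
  int H = trail.nrow(), W = trail.ncol();
  NumericMatrix out(H, W);
  int half = kernel / 2;
  double k2 = (double)kernel * kernel;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      double s = 0.0;
      int cnt = 0;
      for (int dr = -half; dr <= half; ++dr) {
        for (int dc = -half; dc <= half; ++dc) {
          int rr = r + dr, cc = c + dc;
          if (toroidal) {
            rr = ((rr % H) + H) % H;
            cc = ((cc % W) + W) % W;
          } else if (rr < 0 || rr >= H || cc < 0 || cc >= W) {
            continue;
          }
          s += trail(rr, cc);
          ++cnt;
        }
      }
      out(r, c) = (toroidal ? s / k2 : s / cnt) * (1.0 - rho);
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_steer(NumericVector heading, NumericVector prow, NumericVector pcol,
               NumericMatrix trail, LogicalMatrix mask, SEXP height, List cfg,
               RawVector rng) {
  Sim S;
  fill_mask(S, mask);
  fill_height(S, height);
  fill_trail(S, trail);
  fill_cfg(S, cfg);
  S.rng = rng_load(rng);
  int n = heading.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = S.steer(heading[i], prow[i], pcol[i]);
  return List::create(_["heading"] = out, _["rng"] = rng_save(S.rng));
}

// [[Rcpp::export]]
List cpp_move_pass(NumericVector prow, NumericVector pcol, NumericVector phead,
                   NumericMatrix trail, LogicalMatrix mask, SEXP height,
                   List cfg, RawVector rng) {
  Sim S;
  fill_mask(S, mask);
  fill_height(S, height);
  fill_trail(S, trail);
  fill_cfg(S, cfg);
  fill_particles(S, prow, pcol, phead);
  S.rng = rng_load(rng);
  S.move_pass();
  return state_out(S);
}

// [[Rcpp::export]]
List cpp_adapt(NumericVector prow, NumericVector pcol, NumericVector phead,
               NumericMatrix trail, LogicalMatrix mask, SEXP height, List cfg,
               bool do_growth, bool do_shrink, RawVector rng) {
  Sim S;
  fill_mask(S, mask);
  fill_height(S, height);
  fill_trail(S, trail);
  fill_cfg(S, cfg);
  fill_particles(S, prow, pcol, phead);
  S.rng = rng_load(rng);
  if (do_growth) S.growth_pass();
  if (do_shrink) S.shrink_pass();
  return state_out(S);
}

// [[Rcpp::export]]
List cpp_run(NumericVector prow, NumericVector pcol, NumericVector phead,
             NumericMatrix trail, LogicalMatrix mask, SEXP height,
             IntegerMatrix sites, List cfg, int steps, RawVector rng,
             int snapshot_every, bool check_exclusion) {
  Sim S;
  fill_mask(S, mask);
  fill_height(S, height);
  fill_trail(S, trail);
  fill_cfg(S, cfg);
  fill_particles(S, prow, pcol, phead);
  fill_sites(S, sites);
  S.rng = rng_load(rng);
  IntegerVector popcurve(steps);
  List snap_trail, snap_occ;
  IntegerVector snap_step;
  for (int step = 1; step <= steps; ++step) {
    S.project_stimuli();
    S.move_pass();
    if (S.g_interval > 0 && step % S.g_interval == 0) S.growth_pass();
    if (S.s_interval > 0 && step % S.s_interval == 0) S.shrink_pass();
    S.diffuse_decay();
    popcurve[step - 1] = S.n();
    if (check_exclusion) S.assert_exclusion();
    if (snapshot_every > 0 && step % snapshot_every == 0) {
      snap_trail.push_back(mat_out(S, S.trail));
      snap_occ.push_back(occ_out(S));
      snap_step.push_back(step);
    }
  }
  List out = state_out(S);
  out["population"] = popcurve;
  out["snapshot_steps"] = snap_step;
  out["snapshot_trail"] = snap_trail;
  out["snapshot_occupancy"] = snap_occ;
  return out;
}

// ---------------------------------------------------------------------------
// Zhang-Suen morphological thinning (8-connectivity preserving).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  std::vector<uint8_t> img((size_t)H * W, 0);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) img[(size_t)r * W + c] = mask(r, c) ? 1 : 0;
  auto at = [&](int r, int c) -> uint8_t {
    if (r < 0 || r >= H || c < 0 || c >= W) return 0;
    return img[(size_t)r * W + c];
  };
  bool changed = true;
  std::vector<size_t> kill;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      kill.clear();
      for (int r = 0; r < H; ++r) {
        for (int c = 0; c < W; ++c) {
          if (!img[(size_t)r * W + c]) continue;
          // neighbours p2..p9 clockwise from north
          uint8_t p2 = at(r - 1, c), p3 = at(r - 1, c + 1), p4 = at(r, c + 1),
                  p5 = at(r + 1, c + 1), p6 = at(r + 1, c),
                  p7 = at(r + 1, c - 1), p8 = at(r, c - 1),
                  p9 = at(r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (sub == 0) {
            if (p2 * p4 * p6 != 0) continue;
            if (p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0) continue;
            if (p2 * p6 * p8 != 0) continue;
          }
          kill.push_back((size_t)r * W + c);
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t k : kill) img[k] = 0;
    }
  }
  LogicalMatrix out(H, W);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) out(r, c) = img[(size_t)r * W + c] != 0;
  return out;
}
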