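// Probabilistic streamline propagation over a fixed multi-fibre orientation
// field. Semantics: at each step the candidate orientations of the current
// voxel (nearest-voxel lookup) with volume fraction > min_vf are sampled with
// probability proportional to fraction; the sign is aligned with the previous
// direction; a turn sharper than the curvature limit terminates the
// streamline. Both directions from the seed are tracked and concatenated.
// A self-contained mt19937_64 with a bit-derived uniform keeps runs
// reproducible across compilers and platforms.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

constexpr int REASON_LEFT_MASK = 0;
constexpr int REASON_STOP = 1;
constexpr int REASON_MAX_STEPS = 2;
constexpr int REASON_CURVATURE = 3;
constexpr int REASON_NO_FIBRE = 4;
constexpr int REASON_EXCLUSION = 5;

struct Rng {
  std::mt19937_64 gen;
  explicit Rng(uint64_t seed) : gen(seed) {}
  double unif() {
    // 53 random bits -> [0, 1); implementation-defined distributions avoided
    return (gen() >> 11) * (1.0 / 9007199254740992.0);
  }
};

struct Tracker {
  const double* orient;   // [nvox, 3, nfib]
  const double* vf;       // [nvox, nfib]
  int nfib;
  const int* brain;
  const int* stop_mask;   // may be null
  const int* excl_mask;   // may be null
  int dx, dy, dz;
  R_xlen_t nvox;
  double inv[16];         // world -> voxel, row-major 4x4
  double step_mm, cos_limit, min_vf;
  int max_steps;

  inline long voxel_of(const double* p) const {
    double vx = inv[0] * p[0] + inv[1] * p[1] + inv[2] * p[2] + inv[3];
    double vy = inv[4] * p[0] + inv[5] * p[1] + inv[6] * p[2] + inv[7];
    double vz = inv[8] * p[0] + inv[9] * p[1] + inv[10] * p[2] + inv[11];
    long i = (long)std::llround(vx), j = (long)std::llround(vy), k = (long)std::llround(vz);
    if (i < 0 || i >= dx || j < 0 || j >= dy || k < 0 || k >= dz) return -1;
    return i + (long)dx * (j + (long)dy * k);
  }

  // sample a candidate orientation at voxel `lin`; returns fibre index or -1
  inline int sample_fibre(long lin, Rng& rng) const {
    double tot = 0.0;
    double fr[3];
    for (int f = 0; f < nfib; ++f) {
      double v = vf[lin + nvox * f];
      fr[f] = (v > min_vf) ? v : 0.0;
      tot += fr[f];
    }
    if (tot <= 0.0) return -1;
    double u = rng.unif() * tot, acc = 0.0;
    for (int f = 0; f < nfib; ++f) {
      acc += fr[f];
      if (u <= acc && fr[f] > 0.0) return f;
    }
    for (int f = nfib - 1; f >= 0; --f) if (fr[f] > 0.0) return f;
    return -1;
  }

  inline void fibre_dir(long lin, int f, double* o) const {
    o[0] = orient[lin + nvox * (0 + 3 * f)];
    o[1] = orient[lin + nvox * (1 + 3 * f)];
    o[2] = orient[lin + nvox * (2 + 3 * f)];
  }

  // track one direction; appends visited voxels and (optionally) points
  int track_dir(const double* seed_pt, const double* init_dir, int sgn,
                Rng& rng, std::vector<long>& visited,
                std::vector<double>* pts, bool& hit_excl) const {
    double pos[3] = {seed_pt[0], seed_pt[1], seed_pt[2]};
    double prev[3] = {sgn * init_dir[0], sgn * init_dir[1], sgn * init_dir[2]};
    // first move along the seed-voxel orientation
    for (int c = 0; c < 3; ++c) pos[c] += step_mm * prev[c];
    for (int step = 1; step <= max_steps; ++step) {
      long lin = voxel_of(pos);
      if (lin < 0 || !brain[lin]) return REASON_LEFT_MASK;
      visited.push_back(lin);
      if (pts) { pts->push_back(pos[0]); pts->push_back(pos[1]); pts->push_back(pos[2]); }
      if (excl_mask && excl_mask[lin]) { hit_excl = true; return REASON_EXCLUSION; }
      if (stop_mask && stop_mask[lin]) return REASON_STOP;
      if (step == max_steps) return REASON_MAX_STEPS;
      int f = sample_fibre(lin, rng);
      if (f < 0) return REASON_NO_FIBRE;
      double o[3];
      fibre_dir(lin, f, o);
      double dot = o[0] * prev[0] + o[1] * prev[1] + o[2] * prev[2];
      if (dot < 0) { o[0] = -o[0]; o[1] = -o[1]; o[2] = -o[2]; dot = -dot; }
      if (dot < cos_limit) return REASON_CURVATURE;
      for (int c = 0; c < 3; ++c) { pos[c] += step_mm * o[c]; prev[c] = o[c]; }
    }
    return REASON_MAX_STEPS;
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_track(IntegerVector dims, NumericVector orient, NumericVector vf,
               NumericMatrix inv_affine, IntegerVector brain,
               Nullable<IntegerVector> stop_mask, Nullable<IntegerVector> excl_mask,
               List waypoint_masks, NumericMatrix seeds,
               double step_mm, double curvature_limit_deg, int max_steps,
               double min_vf, double rng_seed,
               bool store_paths, Nullable<IntegerVector> coarse_map,
               bool count_visits) {
  Tracker tk;
  tk.dx = dims[0]; tk.dy = dims[1]; tk.dz = dims[2];
  tk.nvox = (R_xlen_t)tk.dx * tk.dy * tk.dz;
  tk.nfib = (int)(vf.size() / tk.nvox);
  tk.orient = REAL(orient);
  tk.vf = REAL(vf);
  tk.brain = INTEGER(brain);
  IntegerVector stop_v, excl_v, cmap_v;
  tk.stop_mask = nullptr; tk.excl_mask = nullptr;
  if (stop_mask.isNotNull()) { stop_v = stop_mask.get(); tk.stop_mask = INTEGER(stop_v); }
  if (excl_mask.isNotNull()) { excl_v = excl_mask.get(); tk.excl_mask = INTEGER(excl_v); }
  const int* cmap = nullptr;
  if (coarse_map.isNotNull()) { cmap_v = coarse_map.get(); cmap = INTEGER(cmap_v); }
  for (int r = 0; r < 4; ++r)
    for (int c = 0; c < 4; ++c) tk.inv[4 * r + c] = inv_affine(r, c);
  tk.step_mm = step_mm;
  tk.cos_limit = std::cos(curvature_limit_deg * M_PI / 180.0);
  tk.min_vf = min_vf;
  tk.max_steps = max_steps;

  int n_way = waypoint_masks.size();
  std::vector<const int*> ways(n_way);
  std::vector<IntegerVector> way_keep(n_way);
  for (int w = 0; w < n_way; ++w) {
    way_keep[w] = as<IntegerVector>(waypoint_masks[w]);
    ways[w] = INTEGER(way_keep[w]);
  }

  int n = seeds.nrow();
  Rng rng((uint64_t)rng_seed);

  IntegerVector counts(count_visits ? tk.nvox : 0);
  LogicalVector valid(n);
  IntegerVector reason_fwd(n), reason_bwd(n);
  List paths(store_paths ? n : 0);
  List coarse_visits(cmap ? n : 0);
  int n_valid = 0;

  std::vector<long> visited;
  std::vector<double> pts_fwd, pts_bwd;

  for (int s = 0; s < n; ++s) {
    visited.clear(); pts_fwd.clear(); pts_bwd.clear();
    double seed_pt[3] = {seeds(s, 0), seeds(s, 1), seeds(s, 2)};
    bool hit_excl = false;
    long lin0 = tk.voxel_of(seed_pt);
    int rf, rb;
    if (lin0 < 0 || !tk.brain[lin0]) {
      rf = rb = REASON_LEFT_MASK;
    } else {
      visited.push_back(lin0);
      if (tk.excl_mask && tk.excl_mask[lin0]) hit_excl = true;
      int f0 = tk.sample_fibre(lin0, rng);
      if (f0 < 0 || hit_excl) {
        rf = rb = hit_excl ? REASON_EXCLUSION : REASON_NO_FIBRE;
      } else {
        double d0[3];
        tk.fibre_dir(lin0, f0, d0);
        rf = tk.track_dir(seed_pt, d0, +1, rng, visited,
                          store_paths ? &pts_fwd : nullptr, hit_excl);
        if (!hit_excl) {
          rb = tk.track_dir(seed_pt, d0, -1, rng, visited,
                            store_paths ? &pts_bwd : nullptr, hit_excl);
        } else {
          rb = REASON_EXCLUSION;
        }
      }
    }
    reason_fwd[s] = rf; reason_bwd[s] = rb;

    std::sort(visited.begin(), visited.end());
    visited.erase(std::unique(visited.begin(), visited.end()), visited.end());

    bool ok = !hit_excl;
    if (ok) {
      for (int w = 0; w < n_way && ok; ++w) {
        bool hit = false;
        for (long v : visited) if (ways[w][v]) { hit = true; break; }
        ok = hit;
      }
    }
    valid[s] = ok;
    if (ok) {
      ++n_valid;
      if (count_visits) for (long v : visited) counts[v] += 1;
    }

    if (cmap) {
      std::vector<int> cv;
      cv.reserve(visited.size());
      for (long v : visited) if (cmap[v] > 0) cv.push_back(cmap[v]);
      std::sort(cv.begin(), cv.end());
      cv.erase(std::unique(cv.begin(), cv.end()), cv.end());
      coarse_visits[s] = IntegerVector(cv.begin(), cv.end());
    }

    if (store_paths) {
      // backward points reversed, then seed, then forward points
      R_xlen_t nb = pts_bwd.size() / 3, nf2 = pts_fwd.size() / 3;
      NumericMatrix pm(nb + 1 + nf2, 3);
      for (R_xlen_t i = 0; i < nb; ++i) {
        R_xlen_t j = nb - 1 - i;
        pm(i, 0) = pts_bwd[3 * j]; pm(i, 1) = pts_bwd[3 * j + 1]; pm(i, 2) = pts_bwd[3 * j + 2];
      }
      pm(nb, 0) = seed_pt[0]; pm(nb, 1) = seed_pt[1]; pm(nb, 2) = seed_pt[2];
      for (R_xlen_t i = 0; i < nf2; ++i) {
        pm(nb + 1 + i, 0) = pts_fwd[3 * i];
        pm(nb + 1 + i, 1) = pts_fwd[3 * i + 1];
        pm(nb + 1 + i, 2) = pts_fwd[3 * i + 2];
      }
      paths[s] = pm;
    }
  }

  List out = List::create(
    _["n_seeded"] = n, _["n_valid"] = n_valid, _["valid"] = valid,
    _["reason_fwd"] = reason_fwd, _["reason_bwd"] = reason_bwd);
  if (count_visits) out["counts"] = counts;
  if (store_paths) out["paths"] = paths;
  if (cmap) out["coarse_visits"] = coarse_visits;
  return out;
}
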