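// Simulation core: spring force field, exposure-gated solvent, Langevin step,
// co-translational synthesis.  Single-threaded; all randomness through R's RNG
// so trajectories are reproducible from set.seed().
#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
using namespace Rcpp;

// particle role codes (keep in sync with R side)
#define ROLE_BB 1
#define ROLE_SC 2
#define ROLE_CROWDER 3
#define ROLE_RIBOSOME 4
#define ROLE_EXIT 5

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

struct SceneC {
  bool has_container = false;
  double container_radius = 0.0;
  double cc[3] = {0, 0, 0};
  bool has_ribosome = false;
  double ribosome_radius = 0.0;
  double rc[3] = {0, 0, 0};
  double k_boundary = 1.0;
  int anchor_id = -1;          // exit particle anchored to a fixed point
  double anchor_point[3] = {0, 0, 0};
  double anchor_k = 0.0;
  double anchor_L0 = 0.0;
};

struct FFC {
  double vdw_contact[6][6];    // indexed by role, roles 1..5 used
  double vdw_maxrep[6][6];
  std::unordered_set<long long> excl; // spring-linked pairs excluded from vdw
  double hb_threshold = 0.0;
  double hb_strength = 0.0;
  int hb_min_sep = 3;
  double hb_offset = 1.9;      // virtual-site offset along chain bisector
};

struct LPC {
  double gamma = 0.0;
  double kick_rate = 0.0;
  double kick_speed = 0.0;
  double hmult = 1.0;
  double dt = 1.0;
  double speed_cap = 1.0;
  double neighbor_cutoff = 12.0;
  int exposure_every = 1;
  NumericMatrix rays;          // K x 3 quasi-uniform directions
};

static SceneC parse_scene(List s) {
  SceneC sc;
  NumericVector cr = s["container_radius"];
  if (cr.size() == 1 && R_finite(cr[0]) && cr[0] > 0) {
    sc.has_container = true;
    sc.container_radius = cr[0];
    NumericVector c = s["container_center"];
    for (int k = 0; k < 3; ++k) sc.cc[k] = c[k];
  }
  NumericVector rr = s["ribosome_radius"];
  if (rr.size() == 1 && R_finite(rr[0]) && rr[0] > 0) {
    sc.has_ribosome = true;
    sc.ribosome_radius = rr[0];
    NumericVector c = s["ribosome_center"];
    for (int k = 0; k < 3; ++k) sc.rc[k] = c[k];
  }
  sc.k_boundary = as<double>(s["k_boundary"]);
  sc.anchor_id = as<int>(s["anchor_id"]);   // 0-based, -1 = none
  if (sc.anchor_id >= 0) {
    NumericVector p = s["anchor_point"];
    for (int k = 0; k < 3; ++k) sc.anchor_point[k] = p[k];
    sc.anchor_k = as<double>(s["anchor_k"]);
    sc.anchor_L0 = as<double>(s["anchor_L0"]);
  }
  return sc;
}

static FFC parse_ff(List f, int n) {
  FFC ff;
  NumericMatrix ct = f["vdw_contact"], mr = f["vdw_maxrep"]; // 5x5, roles 1..5
  for (int i = 1; i <= 5; ++i)
    for (int j = 1; j <= 5; ++j) {
      ff.vdw_contact[i][j] = ct(i - 1, j - 1);
      ff.vdw_maxrep[i][j] = mr(i - 1, j - 1);
    }
  IntegerVector ei = f["excl_i"], ej = f["excl_j"]; // 0-based
  for (int k = 0; k < ei.size(); ++k) {
    int a = ei[k], b = ej[k];
    if (a > b) std::swap(a, b);
    ff.excl.insert((long long)a * n + b);
  }
  ff.hb_threshold = as<double>(f["hb_threshold"]);
  ff.hb_strength = as<double>(f["hb_strength"]);
  ff.hb_min_sep = as<int>(f["hb_min_sep"]);
  ff.hb_offset = as<double>(f["hb_offset"]);
  return ff;
}

static LPC parse_lp(List l) {
  LPC lp;
  lp.gamma = as<double>(l["gamma"]);
  lp.kick_rate = as<double>(l["kick_rate"]);
  lp.kick_speed = as<double>(l["kick_speed"]);
  lp.hmult = as<double>(l["hydrophobic_multiplier"]);
  lp.dt = as<double>(l["dt"]);
  lp.speed_cap = as<double>(l["speed_cap"]);
  lp.neighbor_cutoff = as<double>(l["neighbor_cutoff"]);
  lp.exposure_every = as<int>(l["exposure_every"]);
  lp.rays = as<NumericMatrix>(l["rays"]);
  return lp;
}

// Accumulate spring force between particles i and j into F (and optionally T).
static void spring_pair(const std::vector<double>& X, int i, int j,
                        double L0, double k, std::vector<double>& F,
                        std::vector<double>* T) {
  double d[3] = {X[3 * j] - X[3 * i], X[3 * j + 1] - X[3 * i + 1],
                 X[3 * j + 2] - X[3 * i + 2]};
  double r = norm3(d);
  if (r < 1e-12) return;  // degenerate geometry: direction undefined, no force
  double mag = k * (r - L0); // >0 attractive (toward j)
  for (int c = 0; c < 3; ++c) {
    double f = mag * d[c] / r;
    F[3 * i + c] += f;
    F[3 * j + c] -= f;
    if (T) {
      (*T)[3 * i + c] += f;
      (*T)[3 * j + c] -= f;
    }
  }
}

// Full force evaluation.  Breakdown terms (cov, bb, sc, vdw, hb, boundary) are
// filled only when want_terms is true.
static void compute_forces(
    const std::vector<double>& X, int n, const std::vector<int>& role,
    const std::vector<int>& active, const NumericVector& srad,
    const IntegerVector& sp_i, const IntegerVector& sp_j,
    const NumericVector& sp_L0, const NumericVector& sp_k,
    const IntegerVector& sp_cat, int tether_to, double tether_k,
    double tether_L0, int exit_id, const IntegerVector& res_bb,
    const SceneC& sc, const FFC& ff, std::vector<double>& F, bool want_terms,
    std::vector<std::vector<double> >& terms) {
  std::fill(F.begin(), F.end(), 0.0);
  if (want_terms) {
    terms.assign(6, std::vector<double>(3 * n, 0.0));
  }
  // spring terms: categories 1 cov, 2 bb, 3 sc (tether handled separately)
  for (int s = 0; s < sp_i.size(); ++s) {
    int i = sp_i[s], j = sp_j[s];
    if (!active[i] || !active[j]) continue;
    int cat = sp_cat[s]; // 1 cov 2 bb 3 sc
    spring_pair(X, i, j, sp_L0[s], sp_k[s], F,
                want_terms ? &terms[cat - 1] : nullptr);
  }
  // synthesis tether: exit particle <-> current terminal backbone
  if (tether_to >= 0 && exit_id >= 0 && active[exit_id] && active[tether_to]) {
    spring_pair(X, exit_id, tether_to, tether_L0, tether_k, F,
                want_terms ? &terms[5] : nullptr); // boundary bucket
  }
  // vdw: purely repulsive linear ramp between bb/sc/crowder particles,
  // spring-linked pairs excluded
  for (int i = 0; i < n; ++i) {
    if (!active[i]) continue;
    int ri = role[i];
    if (ri != ROLE_BB && ri != ROLE_SC && ri != ROLE_CROWDER) continue;
    for (int j = i + 1; j < n; ++j) {
      if (!active[j]) continue;
      int rj = role[j];
      if (rj != ROLE_BB && rj != ROLE_SC && rj != ROLE_CROWDER) continue;
      double contact = ff.vdw_contact[ri][rj];
      double d[3] = {X[3 * j] - X[3 * i], X[3 * j + 1] - X[3 * i + 1],
                     X[3 * j + 2] - X[3 * i + 2]};
      if (std::fabs(d[0]) > contact || std::fabs(d[1]) > contact ||
          std::fabs(d[2]) > contact)
        continue;
      double r2 = dot3(d, d);
      if (r2 >= contact * contact) continue;
      if (ff.excl.count((long long)i * n + j)) continue;
      double r = std::sqrt(r2);
      if (r < 1e-12) continue; // coincident: direction undefined
      double mag = ff.vdw_maxrep[ri][rj] * (1.0 - r / contact); // repulsive
      for (int c = 0; c < 3; ++c) {
        double fr = -mag * d[c] / r; // push i away from j
        F[3 * i + c] += fr;
        F[3 * j + c] -= fr;
        if (want_terms) {
          terms[3][3 * i + c] += fr;
          terms[3][3 * j + c] -= fr;
        }
      }
    }
  }
  // hydrogen bonding between backbone particles via virtual O/H sites placed
  // at +/- hb_offset along the local chain bisector; termini have no bisector
  int L = res_bb.size();
  if (ff.hb_strength > 0 && L >= ff.hb_min_sep + 1) {
    std::vector<double> siteA(3 * L), siteB(3 * L);
    std::vector<char> has_site(L, 0);
    for (int r = 1; r < L - 1; ++r) {
      int p = res_bb[r], pm = res_bb[r - 1], pp = res_bb[r + 1];
      if (p < 0 || pm < 0 || pp < 0) continue;
      if (!active[p] || !active[pm] || !active[pp]) continue;
      double u[3], v[3];
      for (int c = 0; c < 3; ++c) {
        u[c] = X[3 * pm + c] - X[3 * p + c];
        v[c] = X[3 * pp + c] - X[3 * p + c];
      }
      double nu = norm3(u), nv = norm3(v);
      if (nu < 1e-9 || nv < 1e-9) continue;
      double b[3];
      for (int c = 0; c < 3; ++c) b[c] = u[c] / nu + v[c] / nv;
      double nb = norm3(b);
      if (nb < 1e-9) continue;
      for (int c = 0; c < 3; ++c) {
        // bisector points into the chain elbow; sites sit on +/- of it
        double bis = b[c] / nb;
        siteA[3 * r + c] = X[3 * p + c] + ff.hb_offset * bis;
        siteB[3 * r + c] = X[3 * p + c] - ff.hb_offset * bis;
      }
      has_site[r] = 1;
    }
    double th2 = ff.hb_threshold * ff.hb_threshold;
    for (int i = 0; i < L; ++i) {
      if (!has_site[i]) continue;
      for (int j = i + ff.hb_min_sep; j < L; ++j) {
        if (!has_site[j]) continue;
        // closest pairing of opposite-sense virtual sites
        double best = R_PosInf;
        double ax[3];
        const double* cand_i[2] = {&siteA[3 * i], &siteB[3 * i]};
        const double* cand_j[2] = {&siteB[3 * j], &siteA[3 * j]};
        for (int a = 0; a < 2; ++a) {
          double dd[3];
          for (int c = 0; c < 3; ++c) dd[c] = cand_j[a][c] - cand_i[a][c];
          double r2 = dot3(dd, dd);
          if (r2 < best) {
            best = r2;
            for (int c = 0; c < 3; ++c) ax[c] = dd[c];
          }
        }
        if (best >= th2) continue;
        double r = std::sqrt(best);
        if (r < 1e-12) continue;
        int pi = res_bb[i], pj = res_bb[j];
        for (int c = 0; c < 3; ++c) {
          double fr = ff.hb_strength * ax[c] / r; // pull i toward j
          F[3 * pi + c] += fr;
          F[3 * pj + c] -= fr;
          if (want_terms) {
            terms[4][3 * pi + c] += fr;
            terms[4][3 * pj + c] -= fr;
          }
        }
      }
    }
  }
  // boundary: container keeps particle surfaces inside; ribosome sphere
  // excludes particle surfaces; exit anchor spring to a fixed point
  for (int i = 0; i < n; ++i) {
    if (!active[i] || role[i] == ROLE_RIBOSOME) continue;
    if (sc.has_container) {
      double d[3] = {X[3 * i] - sc.cc[0], X[3 * i + 1] - sc.cc[1],
                     X[3 * i + 2] - sc.cc[2]};
      double r = norm3(d);
      double over = r + srad[i] - sc.container_radius;
      if (over > 0 && r > 1e-12) {
        for (int c = 0; c < 3; ++c) {
          double fr = -sc.k_boundary * over * d[c] / r;
          F[3 * i + c] += fr;
          if (want_terms) terms[5][3 * i + c] += fr;
        }
      }
    }
    if (sc.has_ribosome) {
      double d[3] = {X[3 * i] - sc.rc[0], X[3 * i + 1] - sc.rc[1],
                     X[3 * i + 2] - sc.rc[2]};
      double r = norm3(d);
      double pen = sc.ribosome_radius + srad[i] - r;
      if (pen > 0 && r > 1e-12) {
        for (int c = 0; c < 3; ++c) {
          double fr = sc.k_boundary * pen * d[c] / r;
          F[3 * i + c] += fr;
          if (want_terms) terms[5][3 * i + c] += fr;
        }
      }
    }
  }
  if (sc.anchor_id >= 0 && active[sc.anchor_id]) {
    int i = sc.anchor_id;
    double d[3] = {sc.anchor_point[0] - X[3 * i],
                   sc.anchor_point[1] - X[3 * i + 1],
                   sc.anchor_point[2] - X[3 * i + 2]};
    double r = norm3(d);
    if (r > 1e-12) {
      double mag = sc.anchor_k * (r - sc.anchor_L0);
      for (int c = 0; c < 3; ++c) {
        double fr = mag * d[c] / r;
        F[3 * i + c] += fr;
        if (want_terms) terms[5][3 * i + c] += fr;
      }
    }
  }
}

// Neighbour lists and ray-cast exposure fractions.
static void update_exposure(const std::vector<double>& X, int n,
                            const NumericVector& srad,
                            const std::vector<int>& active,
                            const std::vector<int>& role, const LPC& lp,
                            std::vector<std::vector<int> >& nbrs,
                            std::vector<double>& frac,
                            std::vector<double>& area) {
  int K = lp.rays.nrow();
  for (int i = 0; i < n; ++i) {
    nbrs[i].clear();
    frac[i] = 0.0;
    area[i] = 0.0;
  }
  for (int i = 0; i < n; ++i) {
    if (!active[i]) continue;
    for (int j = i + 1; j < n; ++j) {
      if (!active[j]) continue;
      double d[3] = {X[3 * j] - X[3 * i], X[3 * j + 1] - X[3 * i + 1],
                     X[3 * j + 2] - X[3 * i + 2]};
      double r = norm3(d);
      // a neighbour can occlude if its sphere comes within the cutoff of the
      // particle centre
      if (r - srad[j] < lp.neighbor_cutoff) nbrs[i].push_back(j);
      if (r - srad[i] < lp.neighbor_cutoff) nbrs[j].push_back(i);
    }
  }
  std::vector<double> ray(3);
  for (int i = 0; i < n; ++i) {
    if (!active[i] || role[i] == ROLE_RIBOSOME) continue;
    if (nbrs[i].empty()) {
      frac[i] = 1.0;
    } else {
      int open = 0;
      for (int k = 0; k < K; ++k) {
        double u[3] = {lp.rays(k, 0), lp.rays(k, 1), lp.rays(k, 2)};
        bool blocked = false;
        for (size_t q = 0; q < nbrs[i].size(); ++q) {
          int j = nbrs[i][q];
          double rel[3] = {X[3 * j] - X[3 * i], X[3 * j + 1] - X[3 * i + 1],
                           X[3 * j + 2] - X[3 * i + 2]};
          double b = dot3(rel, u);
          if (b <= 0) continue;
          double perp2 = dot3(rel, rel) - b * b;
          if (perp2 < srad[j] * srad[j]) {
            blocked = true;
            break;
          }
        }
        if (!blocked) ++open;
      }
      frac[i] = (double)open / K;
    }
    area[i] = frac[i] * 4.0 * M_PI * srad[i] * srad[i];
  }
}

// Is direction u blocked for particle i (used for kick rejection)?
static bool dir_blocked(const std::vector<double>& X, int i, const double* u,
                        const NumericVector& srad,
                        const std::vector<int>& nbrs_i) {
  for (size_t q = 0; q < nbrs_i.size(); ++q) {
    int j = nbrs_i[q];
    double rel[3] = {X[3 * j] - X[3 * i], X[3 * j + 1] - X[3 * i + 1],
                     X[3 * j + 2] - X[3 * i + 2]};
    double b = dot3(rel, u);
    if (b <= 0) continue;
    double perp2 = dot3(rel, rel) - b * b;
    if (perp2 < srad[j] * srad[j]) return true;
  }
  return false;
}

static void random_unit(double* u) {
  double r2;
  do {
    u[0] = norm_rand();
    u[1] = norm_rand();
    u[2] = norm_rand();
    r2 = u[0] * u[0] + u[1] * u[1] + u[2] * u[2];
  } while (r2 < 1e-12);
  double r = std::sqrt(r2);
  u[0] /= r;
  u[1] /= r;
  u[2] /= r;
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, NumericVector srad, IntegerVector role,
                LogicalVector active, IntegerVector sp_i, IntegerVector sp_j,
                NumericVector sp_L0, NumericVector sp_k, IntegerVector sp_cat,
                int tether_to, double tether_k, double tether_L0, int exit_id,
                IntegerVector res_bb, List scene, List ffc) {
  int n = pos.nrow();
  SceneC sc = parse_scene(scene);
  FFC ff = parse_ff(ffc, n);
  std::vector<double> X(3 * n), F(3 * n);
  std::vector<int> rl(n), ac(n);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < 3; ++c) X[3 * i + c] = pos(i, c);
    rl[i] = role[i];
    ac[i] = active[i] ? 1 : 0;
  }
  std::vector<std::vector<double> > terms;
  compute_forces(X, n, rl, ac, srad, sp_i, sp_j, sp_L0, sp_k, sp_cat,
                 tether_to, tether_k, tether_L0, exit_id, res_bb, sc, ff, F,
                 true, terms);
  const char* nm[6] = {"cov", "bb", "sc", "vdw", "hb", "boundary"};
  List out;
  NumericMatrix tot(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) tot(i, c) = F[3 * i + c];
  out["total"] = tot;
  for (int t = 0; t < 6; ++t) {
    NumericMatrix m(n, 3);
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c) m(i, c) = terms[t][3 * i + c];
    out[nm[t]] = m;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_exposure(NumericMatrix pos, NumericVector srad, IntegerVector role,
                  LogicalVector active, NumericMatrix rays, double cutoff) {
  int n = pos.nrow();
  LPC lp;
  lp.rays = rays;
  lp.neighbor_cutoff = cutoff;
  std::vector<double> X(3 * n);
  std::vector<int> rl(n), ac(n);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < 3; ++c) X[3 * i + c] = pos(i, c);
    rl[i] = role[i];
    ac[i] = active[i] ? 1 : 0;
  }
  std::vector<std::vector<int> > nbrs(n);
  std::vector<double> frac(n), area(n);
  update_exposure(X, n, srad, ac, rl, lp, nbrs, frac, area);
  return List::create(_["fraction"] = NumericVector(frac.begin(), frac.end()),
                      _["area"] = NumericVector(area.begin(), area.end()));
}

// [[Rcpp::export]]
List cpp_sample_kicks(NumericMatrix pos, NumericVector srad,
                      IntegerVector role, LogicalVector hydrophobic,
                      LogicalVector active, NumericVector mass,
                      NumericVector area, double neighbor_cutoff,
                      double kick_rate, double kick_speed, double hmult) {
  int n = pos.nrow();
  std::vector<double> X(3 * n);
  std::vector<int> ac(n);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < 3; ++c) X[3 * i + c] = pos(i, c);
    ac[i] = active[i] ? 1 : 0;
  }
  // neighbour lists for kick-direction rejection
  std::vector<std::vector<int> > nbrs(n);
  for (int i = 0; i < n; ++i) {
    if (!ac[i]) continue;
    for (int j = 0; j < n; ++j) {
      if (j == i || !ac[j]) continue;
      double d[3] = {X[3 * j] - X[3 * i], X[3 * j + 1] - X[3 * i + 1],
                     X[3 * j + 2] - X[3 * i + 2]};
      if (norm3(d) - srad[j] < neighbor_cutoff) nbrs[i].push_back(j);
    }
  }
  NumericMatrix dv(n, 3);
  IntegerVector attempted(n), landed(n);
  double u[3];
  for (int i = 0; i < n; ++i) {
    if (!ac[i] || role[i] == ROLE_RIBOSOME) continue;
    double lam = kick_rate * area[i];
    if (role[i] == ROLE_SC && hydrophobic[i]) lam *= hmult;
    if (lam <= 0) continue;
    int nk = (int)R::rpois(lam);
    attempted[i] = nk;
    for (int k = 0; k < nk; ++k) {
      random_unit(u);
      // kick arrives from direction -u and must not be blocked there
      double from[3] = {-u[0], -u[1], -u[2]};
      if (dir_blocked(X, i, from, srad, nbrs[i])) continue;
      ++landed[i];
      for (int c = 0; c < 3; ++c) dv(i, c) += kick_speed * u[c] / mass[i];
    }
  }
  return List::create(_["dv"] = dv, _["attempted"] = attempted,
                      _["landed"] = landed);
}

// [[Rcpp::export]]
List cpp_engine_run(NumericMatrix pos0, NumericMatrix vel0, NumericVector mass,
                    NumericVector srad, IntegerVector role,
                    LogicalVector hydrophobic, LogicalVector active0,
                    IntegerVector sp_i, IntegerVector sp_j, NumericVector sp_L0,
                    NumericVector sp_k, IntegerVector sp_cat, List scene,
                    List ffc, List lpc, List synth, int n_steps,
                    int sample_interval, int it_offset,
                    IntegerVector record_ids, int tether_to0) {
  int n = pos0.nrow();
  SceneC sc = parse_scene(scene);
  FFC ff = parse_ff(ffc, n);
  LPC lp = parse_lp(lpc);
  IntegerVector res_bb = synth["res_bb"]; // 0-based particle per residue
  IntegerVector res_sc = synth["res_sc"]; // -1 = no side chain
  bool synth_on = as<bool>(synth["enabled"]);
  int rate = as<int>(synth["rate"]);
  int n_res = res_bb.size();
  int synthesized = as<int>(synth["synthesized"]);
  double tether_k = as<double>(synth["tether_k"]);
  double tether_L0 = as<double>(synth["tether_L0"]);
  int exit_id = as<int>(synth["exit_id"]); // -1 = none
  int tether_to = tether_to0;

  std::vector<double> X(3 * n), V(3 * n), F(3 * n);
  std::vector<int> rl(n), ac(n);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < 3; ++c) {
      X[3 * i + c] = pos0(i, c);
      V[3 * i + c] = vel0(i, c);
    }
    rl[i] = role[i];
    ac[i] = active0[i] ? 1 : 0;
  }
  std::vector<std::vector<int> > nbrs(n);
  std::vector<double> frac(n, 1.0), area(n, 0.0);
  std::vector<std::vector<double> > terms; // unused in fast path

  int n_rec = record_ids.size();
  int n_samp = (sample_interval > 0) ? n_steps / sample_interval : 0;
  NumericVector samples((R_xlen_t)n_samp * n_rec * 3);
  IntegerVector sample_its(n_samp);
  long long kicks_total = 0;
  double u[3];

  for (int it = 1; it <= n_steps; ++it) {
    long long git = (long long)it_offset + it; // global iteration index
    // synthesis: residue k emerges at global iteration (k-1)*rate
    if (synth_on && exit_id >= 0) {
      while (synthesized < n_res &&
             (long long)synthesized * rate <= git - 1) {
        int r = synthesized; // 0-based residue about to appear
        int pb = res_bb[r], ps = res_sc[r];
        double out[3] = {0, 0, 1};
        if (sc.has_ribosome) {
          double d[3] = {X[3 * exit_id] - sc.rc[0],
                         X[3 * exit_id + 1] - sc.rc[1],
                         X[3 * exit_id + 2] - sc.rc[2]};
          double r0 = norm3(d);
          if (r0 > 1e-9)
            for (int c = 0; c < 3; ++c) out[c] = d[c] / r0;
        }
        random_unit(u);
        // tangential jitter so consecutive residues never coincide
        double b = dot3(u, out);
        double tang[3] = {u[0] - b * out[0], u[1] - b * out[1],
                          u[2] - b * out[2]};
        double nt = norm3(tang);
        if (nt < 1e-9) {
          tang[0] = out[1];
          tang[1] = -out[0];
          tang[2] = 0;
          nt = norm3(tang);
          if (nt < 1e-9) {
            tang[0] = 0;
            tang[1] = out[2];
            tang[2] = -out[1];
            nt = norm3(tang);
          }
        }
        for (int c = 0; c < 3; ++c) {
          X[3 * pb + c] =
              X[3 * exit_id + c] + 0.5 * out[c] + 0.3 * tang[c] / nt;
          V[3 * pb + c] = 0.0;
        }
        ac[pb] = 1;
        if (ps >= 0) {
          random_unit(u);
          for (int c = 0; c < 3; ++c) {
            X[3 * ps + c] = X[3 * pb + c] + 0.5 * out[c] + 0.3 * u[c];
            V[3 * ps + c] = 0.0;
          }
          ac[ps] = 1;
        }
        tether_to = pb; // re-point the single synthesis tether
        ++synthesized;
      }
      if (tether_to >= 0 && synthesized == n_res &&
          git >= (long long)n_res * rate) {
        tether_to = -1; // chain complete: untether from the exit point
      }
    }
    if ((it - 1) % lp.exposure_every == 0) {
      update_exposure(X, n, srad, ac, rl, lp, nbrs, frac, area);
    }
    compute_forces(X, n, rl, ac, srad, sp_i, sp_j, sp_L0, sp_k, sp_cat,
                   tether_to, tether_k, tether_L0, exit_id, res_bb, sc, ff, F,
                   false, terms);
    for (int i = 0; i < n; ++i) {
      if (!ac[i] || rl[i] == ROLE_RIBOSOME) continue;
      double geff = lp.gamma * area[i];
      for (int c = 0; c < 3; ++c) {
        V[3 * i + c] +=
            lp.dt * (F[3 * i + c] - geff * V[3 * i + c]) / mass[i];
      }
      // solvent kicks: Poisson count over exposed area, blocked directions
      // discarded
      double lam = lp.kick_rate * area[i];
      if (rl[i] == ROLE_SC && hydrophobic[i]) lam *= lp.hmult;
      if (lam > 0) {
        int nk = (int)R::rpois(lam);
        for (int k = 0; k < nk; ++k) {
          random_unit(u);
          double from[3] = {-u[0], -u[1], -u[2]};
          if (dir_blocked(X, i, from, srad, nbrs[i])) continue;
          ++kicks_total;
          for (int c = 0; c < 3; ++c)
            V[3 * i + c] += lp.kick_speed * u[c] / mass[i];
        }
      }
      double sp = norm3(&V[3 * i]);
      if (sp > lp.speed_cap) {
        double f = lp.speed_cap / sp;
        for (int c = 0; c < 3; ++c) V[3 * i + c] *= f;
      }
      for (int c = 0; c < 3; ++c) {
        X[3 * i + c] += lp.dt * V[3 * i + c];
        if (!std::isfinite(X[3 * i + c])) {
          stop("non-finite coordinate for particle %d at iteration %d "
               "(check stiffnesses / dt / speed_cap)",
               i + 1, it);
        }
      }
    }
    if (sample_interval > 0 && it % sample_interval == 0) {
      int s = it / sample_interval - 1;
      sample_its[s] = it_offset + it;
      for (int q = 0; q < n_rec; ++q) {
        int i = record_ids[q];
        for (int c = 0; c < 3; ++c) {
          samples[(R_xlen_t)s + (R_xlen_t)n_samp * (q + (R_xlen_t)n_rec * c)] =
              ac[i] ? X[3 * i + c] : NA_REAL;
        }
      }
    }
  }
  NumericMatrix pos(n, 3), vel(n, 3);
  LogicalVector active(n);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < 3; ++c) {
      pos(i, c) = X[3 * i + c];
      vel(i, c) = V[3 * i + c];
    }
    active[i] = ac[i] == 1;
  }
  samples.attr("dim") = IntegerVector::create(n_samp, n_rec, 3);
  return List::create(
      _["pos"] = pos, _["vel"] = vel, _["active"] = active,
      _["samples"] = samples, _["sample_iterations"] = sample_its,
      _["synthesized"] = synthesized, _["tether_to"] = tether_to,
      _["kicks"] = (double)kicks_total,
      _["exposure"] = NumericVector(frac.begin(), frac.end()));
}
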