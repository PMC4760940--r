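// Stochastic engine for the sticky-cell surface-colonization model.
//
// World state: a well-mixed liquid (carrying capacity K) plus a 2-D lattice
// surface (one cell per site). Each time step every cell alive at the start
// of the step, taken in freshly shuffled order, draws ONE of five events
// uniformly at random (migrate to surface, migrate to liquid, differentiate,
// die, divide), each applied with its event-specific gate. After all cells
// are processed the liquid is diluted back down to K. State changes are
// visible immediately within the step (sequential updating).
//
// All randomness goes through a single xoshiro256++ stream seeded from the
// config, so runs are replayable bit-for-bit. Draw order per step:
// (1) Fisher-Yates shuffle of the cell order, (2) per cell one uniform for
// the event choice followed by the event's own draws in the order given in
// each ev_* function, (3) dilution draws.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG ----

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  inline int bounded(int n) {
    return (int)(((unsigned __int128)next() * (uint64_t)n) >> 64);
  }
  inline double gauss() {
    double u1 = unif();
    while (u1 <= 0.0) u1 = unif();
    double u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
};

// ----------------------------------------------------------- geometry ----

// geometry codes: 0 = hex6 (axial/rhombic), 1 = square4, 2 = moore8,
//                 3 = tri3 (honeycomb; needs even height when periodic)
// boundary codes: 0 = periodic (torus), 1 = bounded
//
// Hex addressing is axial on a rectangular array: the six offsets
// (0,+1),(0,-1),(+1,0),(-1,0),(-1,+1),(+1,-1) form a negation-closed set,
// so the neighbour relation is symmetric on a torus of any size. tri3 uses
// (0,+1),(0,-1) plus (+1,0) when (row+col) is even, (-1,0) when odd.

static void geometry_offsets(int geom, int row, int col,
                             int offs[][2], int* n) {
  switch (geom) {
  case 0: { // hex6
    static const int h[6][2] = {{0,1},{0,-1},{1,0},{-1,0},{-1,1},{1,-1}};
    for (int i = 0; i < 6; ++i) { offs[i][0] = h[i][0]; offs[i][1] = h[i][1]; }
    *n = 6; break;
  }
  case 1: { // square4
    static const int h[4][2] = {{0,1},{0,-1},{1,0},{-1,0}};
    for (int i = 0; i < 4; ++i) { offs[i][0] = h[i][0]; offs[i][1] = h[i][1]; }
    *n = 4; break;
  }
  case 2: { // moore8
    int k = 0;
    for (int dr = -1; dr <= 1; ++dr)
      for (int dc = -1; dc <= 1; ++dc)
        if (dr || dc) { offs[k][0] = dr; offs[k][1] = dc; ++k; }
    *n = 8; break;
  }
  case 3: { // tri3 honeycomb
    offs[0][0] = 0; offs[0][1] = 1;
    offs[1][0] = 0; offs[1][1] = -1;
    offs[2][0] = ((row + col) % 2 == 0) ? 1 : -1; offs[2][1] = 0;
    *n = 3; break;
  }
  default:
    stop("unknown geometry code");
  }
}

// Precompute, for every site, its neighbouring site indices.
static void build_neighbour_table(int height, int width, int geom,
                                  int boundary,
                                  std::vector<int>& nbr,
                                  std::vector<int>& deg,
                                  int maxdeg) {
  const int nsites = height * width;
  nbr.assign((size_t)nsites * maxdeg, -1);
  deg.assign(nsites, 0);
  int offs[8][2]; int no;
  for (int r = 0; r < height; ++r) {
    for (int c = 0; c < width; ++c) {
      const int site = r * width + c;
      geometry_offsets(geom, r, c, offs, &no);
      int d = 0;
      for (int i = 0; i < no; ++i) {
        int rr = r + offs[i][0], cc = c + offs[i][1];
        if (boundary == 0) {
          rr = (rr + height) % height;
          cc = (cc + width) % width;
        } else if (rr < 0 || rr >= height || cc < 0 || cc >= width) {
          continue;
        }
        nbr[(size_t)site * maxdeg + d++] = rr * width + cc;
      }
      deg[site] = d;
    }
  }
}

// ------------------------------------------------------------- world ----

enum Kind { PURE = 0, PROB = 1, DECISION = 2 };
enum Event { EV_TO_SURFACE = 0, EV_TO_LIQUID = 1, EV_DIFF = 2,
             EV_DEATH = 3, EV_DIVIDE = 4 };

struct World {
  // parameters
  double R, Pm, Pd, mu_r, mu_s;
  int K, width, height, nsites, geom, boundary, scope, event_mode;
  static const int MAXDEG = 8;

  Xoshiro rng;
  long long t;

  // lattice
  std::vector<int> nbr, deg;
  std::vector<int> occupancy; // site -> cell slot, -1 vacant

  // genotypes (struct of arrays, refcounted, slot-stable)
  std::vector<int> g_kind;
  std::vector<double> g_allele, g_P, g_W1, g_W2, g_theta, g_override;
  std::vector<long long> g_id;
  std::vector<int> g_ref;
  std::vector<char> g_used, g_pinned;
  std::vector<int> g_free;
  long long next_gid;
  int n_geno_live; // used && ref > 0

  // cells (slot-stable)
  std::vector<int> c_geno, c_site, c_lpos;
  std::vector<char> c_sticky, c_alive;
  std::vector<long long> c_id;
  std::vector<int> c_free;
  long long next_cid;

  std::vector<int> liquid_slots;
  int n_surface, stick_liq, stick_surf;

  // counters
  long long drawn[5];
  long long n_attach, n_dislodge, n_diff_switch, n_deaths, n_dilutions,
            n_divisions, n_sticky_divisions, n_daughters_liquid,
            n_daughters_surface, n_div_to_liquid_from_surface;

  // scratch
  std::vector<int> order;
  std::vector<long long> order_id;

  World(double R_, double Pm_, double Pd_, int K_, int height_, int width_,
        int geom_, int boundary_, double mu_r_, double mu_s_, int scope_,
        int event_mode_, uint64_t seed)
    : R(R_), Pm(Pm_), Pd(Pd_), mu_r(mu_r_), mu_s(mu_s_), K(K_),
      width(width_), height(height_), nsites(height_ * width_),
      geom(geom_), boundary(boundary_), scope(scope_),
      event_mode(event_mode_), rng(seed), t(0),
      next_gid(1), n_geno_live(0), next_cid(1),
      n_surface(0), stick_liq(0), stick_surf(0) {
    build_neighbour_table(height, width, geom, boundary, nbr, deg, MAXDEG);
    occupancy.assign(nsites, -1);
    for (int i = 0; i < 5; ++i) drawn[i] = 0;
    n_attach = n_dislodge = n_diff_switch = n_deaths = n_dilutions =
      n_divisions = n_sticky_divisions = n_daughters_liquid =
      n_daughters_surface = n_div_to_liquid_from_surface = 0;
  }

  // ---- genotypes ----
  int geno_alloc() {
    int g;
    if (!g_free.empty()) { g = g_free.back(); g_free.pop_back(); }
    else {
      g = (int)g_kind.size();
      g_kind.push_back(0); g_allele.push_back(0); g_P.push_back(0);
      g_W1.push_back(0); g_W2.push_back(0); g_theta.push_back(0);
      g_override.push_back(NA_REAL); g_id.push_back(0);
      g_ref.push_back(0); g_used.push_back(0); g_pinned.push_back(0);
    }
    g_used[g] = 1; g_ref[g] = 0; g_pinned[g] = 0;
    g_id[g] = next_gid++;
    return g;
  }
  inline void geno_incref(int g) {
    if (g_ref[g]++ == 0) ++n_geno_live;
  }
  inline void geno_decref(int g) {
    if (--g_ref[g] == 0) {
      --n_geno_live;
      if (!g_pinned[g]) { g_used[g] = 0; g_free.push_back(g); }
    }
  }

  // Mutate a parent genotype into a (possibly new) daughter genotype and
  // take a reference on the result. Draw order: per-variable mutation coins
  // first (W1, W2, theta for the decision kind), then Gaussian perturbations
  // in the same variable order.
  int mutate_from(int gp) {
    if (mu_r <= 0.0) { geno_incref(gp); return gp; }
    const int k = g_kind[gp];
    if (k == PURE) {
      if (rng.unif() < mu_r) {
        int g = geno_alloc();
        g_kind[g] = PURE; g_allele[g] = 1.0 - g_allele[gp];
        g_P[g] = g_P[gp]; g_W1[g] = g_W1[gp]; g_W2[g] = g_W2[gp];
        g_theta[g] = g_theta[gp]; g_override[g] = g_override[gp];
        geno_incref(g); return g;
      }
    } else if (k == PROB) {
      if (rng.unif() < mu_r) {
        int g = geno_alloc();
        g_kind[g] = PROB; g_allele[g] = g_allele[gp];
        double p = g_P[gp] + rng.gauss() * mu_s;
        if (p < 0.0) p = 0.0; if (p > 1.0) p = 1.0;
        g_P[g] = p; g_W1[g] = g_W1[gp]; g_W2[g] = g_W2[gp];
        g_theta[g] = g_theta[gp]; g_override[g] = g_override[gp];
        geno_incref(g); return g;
      }
    } else {
      const bool m1 = rng.unif() < mu_r;
      const bool m2 = rng.unif() < mu_r;
      const bool m3 = rng.unif() < mu_r;
      if (m1 || m2 || m3) {
        int g = geno_alloc();
        g_kind[g] = DECISION; g_allele[g] = g_allele[gp]; g_P[g] = g_P[gp];
        g_W1[g] = g_W1[gp] + (m1 ? rng.gauss() * mu_s : 0.0);
        g_W2[g] = g_W2[gp] + (m2 ? rng.gauss() * mu_s : 0.0);
        g_theta[g] = g_theta[gp] + (m3 ? rng.gauss() * mu_s : 0.0);
        g_override[g] = g_override[gp];
        geno_incref(g); return g;
      }
    }
    geno_incref(gp); return gp;
  }

  // ---- cells ----
  int cell_alloc() {
    int c;
    if (!c_free.empty()) { c = c_free.back(); c_free.pop_back(); }
    else {
      c = (int)c_geno.size();
      c_geno.push_back(-1); c_site.push_back(-1); c_lpos.push_back(-1);
      c_sticky.push_back(0); c_alive.push_back(0); c_id.push_back(0);
    }
    c_alive[c] = 1; c_id[c] = next_cid++;
    return c;
  }
  inline void liquid_add(int c) {
    c_lpos[c] = (int)liquid_slots.size();
    liquid_slots.push_back(c);
  }
  inline void liquid_remove(int c) {
    const int pos = c_lpos[c];
    const int last = liquid_slots.back();
    liquid_slots[pos] = last; c_lpos[last] = pos;
    liquid_slots.pop_back(); c_lpos[c] = -1;
  }

  // Add a cell with an already-referenced genotype.
  int add_cell(int g, bool sticky, int site) {
    const int c = cell_alloc();
    c_geno[c] = g; c_sticky[c] = sticky ? 1 : 0; c_site[c] = site;
    if (site >= 0) {
      if (occupancy[site] >= 0) stop("site already occupied");
      occupancy[site] = c; ++n_surface;
      if (sticky) ++stick_surf;
    } else {
      liquid_add(c);
      if (sticky) ++stick_liq;
    }
    return c;
  }

  void kill(int c, bool dilution) {
    if (c_site[c] >= 0) {
      occupancy[c_site[c]] = -1; --n_surface;
      if (c_sticky[c]) --stick_surf;
    } else {
      liquid_remove(c);
      if (c_sticky[c]) --stick_liq;
    }
    geno_decref(c_geno[c]);
    c_alive[c] = 0;
    c_free.push_back(c);
    if (dilution) ++n_dilutions; else ++n_deaths;
  }

  inline int n_liquid() const { return (int)liquid_slots.size(); }

  inline int sticky_nbr_count(int site) const {
    int n = 0;
    const int d = deg[site];
    const int* nb = &nbr[(size_t)site * MAXDEG];
    for (int i = 0; i < d; ++i) {
      const int o = occupancy[nb[i]];
      if (o >= 0 && c_sticky[o]) ++n;
    }
    return n;
  }
  inline bool has_sticky_neighbour(int site) const {
    const int d = deg[site];
    const int* nb = &nbr[(size_t)site * MAXDEG];
    for (int i = 0; i < d; ++i) {
      const int o = occupancy[nb[i]];
      if (o >= 0 && c_sticky[o]) return true;
    }
    return false;
  }

  inline void set_phenotype(int c, bool sticky) {
    if ((bool)c_sticky[c] == sticky) return;
    ++n_diff_switch;
    if (c_site[c] >= 0) stick_surf += sticky ? 1 : -1;
    else stick_liq += sticky ? 1 : -1;
    c_sticky[c] = sticky ? 1 : 0;
  }

  // ---- the five events ----

  void ev_migrate_to_surface(int c) {
    if (c_site[c] >= 0) return;              // surface cells: no-op
    if (rng.unif() >= Pm) return;
    const int s = rng.bounded(nsites);       // uniform over ALL sites
    if (occupancy[s] >= 0) return;           // occupied: back to the liquid
    if (!c_sticky[c] && !has_sticky_neighbour(s)) return;
    liquid_remove(c);
    occupancy[s] = c; c_site[c] = s; ++n_surface;
    if (c_sticky[c]) { --stick_liq; ++stick_surf; }
    ++n_attach;
  }

  void ev_migrate_to_liquid(int c) {
    const int s = c_site[c];
    if (s < 0) return;                       // liquid cells: no-op
    if (c_sticky[c]) return;
    if (has_sticky_neighbour(s)) return;
    occupancy[s] = -1; c_site[c] = -1; --n_surface;
    liquid_add(c);                           // may transiently exceed K
    ++n_dislodge;
  }

  void ev_differentiate(int c) {
    const int g = c_geno[c];
    const int k = g_kind[g];
    if (k == PURE) return;                   // switching is mutational only
    bool sticky;
    if (k == PROB) {
      sticky = rng.unif() < g_P[g];
    } else {
      double N, S;
      const int s = c_site[c];
      if (s >= 0) {
        N = 1.0;
        S = deg[s] > 0 ? (double)sticky_nbr_count(s) / (double)deg[s] : 0.0;
      } else {
        N = 0.0;
        if (scope == 0) { // global: sticky fraction of the whole population
          const int tot = n_liquid() + n_surface;
          S = tot > 0 ? (double)(stick_liq + stick_surf) / (double)tot : 0.0;
        } else {          // liquid only
          S = n_liquid() > 0 ? (double)stick_liq / (double)n_liquid() : 0.0;
        }
      }
      sticky = g_W1[g] * N + g_W2[g] * S > g_theta[g]; // strict
    }
    set_phenotype(c, sticky);
  }

  void ev_death(int c) {
    double p = Pd;
    const int g = c_geno[c];
    if (c_sticky[c] && !ISNAN(g_override[g])) p = g_override[g];
    if (rng.unif() < p) kill(c, false);
  }

  void ev_divide(int c) {
    if (c_sticky[c] && rng.unif() >= R) return; // cost gate for sticky cells
    const int s = c_site[c];
    if (s < 0) {
      if (n_liquid() >= K) return;
      const int g = mutate_from(c_geno[c]);
      const bool dsticky =
        g_kind[g] == PURE ? g_allele[g] > 0.5 : (bool)c_sticky[c];
      add_cell(g, dsticky, -1);
      ++n_divisions; ++n_daughters_liquid;
      if (c_sticky[c]) ++n_sticky_divisions;
      return;
    }
    // surface parent: daughter genotype/phenotype decide site eligibility
    const int g = mutate_from(c_geno[c]);
    const bool dsticky =
      g_kind[g] == PURE ? g_allele[g] > 0.5 : (bool)c_sticky[c];
    int elig[MAXDEG]; int ne = 0;
    const int d = deg[s];
    const int* nb = &nbr[(size_t)s * MAXDEG];
    for (int i = 0; i < d; ++i) {
      const int s2 = nb[i];
      if (occupancy[s2] >= 0) continue;
      if (dsticky || has_sticky_neighbour(s2)) elig[ne++] = s2;
    }
    const int liquid_open = n_liquid() < K ? 1 : 0;
    const int total = ne + liquid_open;
    if (total == 0) { geno_decref(g); return; } // division fails
    const int pick = rng.bounded(total);
    if (pick < ne) {
      add_cell(g, dsticky, elig[pick]);
      ++n_daughters_surface;
    } else {
      add_cell(g, dsticky, -1);
      ++n_daughters_liquid; ++n_div_to_liquid_from_surface;
    }
    ++n_divisions;
    if (c_sticky[c]) ++n_sticky_divisions;
  }

  void dispatch(int c, int e) {
    switch (e) {
    case EV_TO_SURFACE: ev_migrate_to_surface(c); break;
    case EV_TO_LIQUID:  ev_migrate_to_liquid(c);  break;
    case EV_DIFF:       ev_differentiate(c);      break;
    case EV_DEATH:      ev_death(c);              break;
    case EV_DIVIDE:     ev_divide(c);             break;
    default: stop("unknown event code");
    }
  }

  void normalize_liquid() {
    while (n_liquid() > K) {
      const int idx = rng.bounded(n_liquid());
      kill(liquid_slots[idx], true);
    }
  }

  void step() {
    order.clear(); order_id.clear();
    const int cap = (int)c_geno.size();
    for (int c = 0; c < cap; ++c)
      if (c_alive[c]) { order.push_back(c); order_id.push_back(c_id[c]); }
    // Fisher-Yates shuffle
    for (int i = (int)order.size() - 1; i > 0; --i) {
      const int j = rng.bounded(i + 1);
      std::swap(order[i], order[j]);
      std::swap(order_id[i], order_id[j]);
    }
    const int n = (int)order.size();
    for (int i = 0; i < n; ++i) {
      const int c = order[i];
      if (!c_alive[c] || c_id[c] != order_id[i]) continue; // slot reused
      if (event_mode == 0) {
        const int e = rng.bounded(5);
        ++drawn[e];
        dispatch(c, e);
      } else {
        // sensitivity mode: attempt all five events in fixed order
        for (int e = 0; e < 5; ++e) {
          if (!c_alive[c]) break;
          ++drawn[e];
          dispatch(c, e);
        }
      }
    }
    normalize_liquid();
    ++t;
  }
};

typedef XPtr<World> WorldPtr;

// ------------------------------------------------------- R interface ----

// [[Rcpp::export]]
SEXP cpp_world_new(double R, double Pm, double Pd, int K, int height,
                   int width, int geom, int boundary, double mu_r,
                   double mu_s, int scope, int event_mode, double seed) {
  World* w = new World(R, Pm, Pd, K, height, width, geom, boundary,
                       mu_r, mu_s, scope, event_mode, (uint64_t)seed);
  return WorldPtr(w, true);
}

// [[Rcpp::export]]
int cpp_world_add_genotype(SEXP wp, int kind, double allele, double P,
                           double W1, double W2, double theta,
                           double sticky_death) {
  WorldPtr w(wp);
  const int g = w->geno_alloc();
  w->g_kind[g] = kind; w->g_allele[g] = allele; w->g_P[g] = P;
  w->g_W1[g] = W1; w->g_W2[g] = W2; w->g_theta[g] = theta;
  w->g_override[g] = sticky_death;
  w->g_pinned[g] = 1; // explicit genotypes keep their slot for the run
  return g;
}

// [[Rcpp::export]]
void cpp_world_seed_liquid(SEXP wp, int geno, int n, bool sticky) {
  WorldPtr w(wp);
  for (int i = 0; i < n; ++i) {
    w->geno_incref(geno);
    w->add_cell(geno, sticky, -1);
  }
}

// [[Rcpp::export]]
void cpp_world_place_at(SEXP wp, int geno, int row, int col, bool sticky) {
  WorldPtr w(wp);
  if (row < 0 || row >= w->height || col < 0 || col >= w->width)
    stop("position out of range");
  const int site = row * w->width + col;
  if (w->occupancy[site] >= 0) stop("site already occupied");
  w->geno_incref(geno);
  w->add_cell(geno, sticky, site);
}

// [[Rcpp::export]]
void cpp_world_place_random(SEXP wp, int geno, int n, bool sticky) {
  WorldPtr w(wp);
  int vacant = 0;
  for (int s = 0; s < w->nsites; ++s) if (w->occupancy[s] < 0) ++vacant;
  if (n > vacant) stop("not enough vacant sites");
  int placed = 0;
  while (placed < n) {
    const int s = w->rng.bounded(w->nsites);
    if (w->occupancy[s] >= 0) continue;
    w->geno_incref(geno);
    w->add_cell(geno, sticky, s);
    ++placed;
  }
}

// [[Rcpp::export]]
void cpp_world_step(SEXP wp, int nsteps) {
  WorldPtr w(wp);
  for (int i = 0; i < nsteps; ++i) w->step();
}

// Run nsteps, recording a summary row every `every` steps (and the final
// state if nsteps is not a multiple). Optionally track per-genotype cell
// counts (overall and sticky-only) at each record; genotype slots must be
// fixed (mutation off) for the tracked matrices to be meaningful.
// [[Rcpp::export]]
List cpp_world_run(SEXP wp, int nsteps, int every, bool include_initial,
                   bool track_genotypes) {
  WorldPtr w(wp);
  if (every < 1) every = 1;
  std::vector<double> rows; // t, n_liquid, n_surface, stick_liq, stick_surf, n_geno
  const int gcap = (int)w->g_kind.size();
  std::vector<double> gall, gsticky;

  auto record = [&]() {
    rows.push_back((double)w->t);
    rows.push_back((double)w->n_liquid());
    rows.push_back((double)w->n_surface);
    rows.push_back((double)w->stick_liq);
    rows.push_back((double)w->stick_surf);
    rows.push_back((double)w->n_geno_live);
    if (track_genotypes) {
      std::vector<double> ca(gcap, 0.0), cs(gcap, 0.0);
      const int cap = (int)w->c_geno.size();
      for (int c = 0; c < cap; ++c) {
        if (!w->c_alive[c]) continue;
        const int g = w->c_geno[c];
        if (g < gcap) {
          ca[g] += 1.0;
          if (w->c_sticky[c]) cs[g] += 1.0;
        }
      }
      gall.insert(gall.end(), ca.begin(), ca.end());
      gsticky.insert(gsticky.end(), cs.begin(), cs.end());
    }
  };

  if (include_initial) record();
  for (int i = 1; i <= nsteps; ++i) {
    w->step();
    if (i % every == 0 || i == nsteps) record();
  }

  const int ncol = 6;
  const int nrow = (int)(rows.size() / ncol);
  NumericMatrix traj(nrow, ncol);
  for (int i = 0; i < nrow; ++i)
    for (int j = 0; j < ncol; ++j)
      traj(i, j) = rows[(size_t)i * ncol + j];
  colnames(traj) = CharacterVector::create(
    "t", "n_liquid", "n_surface", "sticky_liquid", "sticky_surface",
    "n_genotypes");

  List out = List::create(_["trajectory"] = traj);
  if (track_genotypes) {
    NumericMatrix ma(nrow, gcap), ms(nrow, gcap);
    for (int i = 0; i < nrow; ++i)
      for (int j = 0; j < gcap; ++j) {
        ma(i, j) = gall[(size_t)i * gcap + j];
        ms(i, j) = gsticky[(size_t)i * gcap + j];
      }
    out["genotype_counts"] = ma;
    out["genotype_sticky_counts"] = ms;
  }
  return out;
}

// Apply one named event to one cell (by cell id); test/assay hook using the
// exact production code path.
// [[Rcpp::export]]
bool cpp_world_apply_event(SEXP wp, double cell_id, int event) {
  WorldPtr w(wp);
  const long long id = (long long)cell_id;
  const int cap = (int)w->c_geno.size();
  for (int c = 0; c < cap; ++c) {
    if (w->c_alive[c] && w->c_id[c] == id) {
      w->dispatch(c, event);
      return true;
    }
  }
  return false;
}

// Apply one named event to every cell alive at call time (shuffled order).
// [[Rcpp::export]]
int cpp_world_apply_event_all(SEXP wp, int event) {
  WorldPtr w(wp);
  std::vector<int> slots; std::vector<long long> ids;
  const int cap = (int)w->c_geno.size();
  for (int c = 0; c < cap; ++c)
    if (w->c_alive[c]) { slots.push_back(c); ids.push_back(w->c_id[c]); }
  for (int i = (int)slots.size() - 1; i > 0; --i) {
    const int j = w->rng.bounded(i + 1);
    std::swap(slots[i], slots[j]);
    std::swap(ids[i], ids[j]);
  }
  int applied = 0;
  for (size_t i = 0; i < slots.size(); ++i) {
    const int c = slots[i];
    if (!w->c_alive[c] || w->c_id[c] != ids[i]) continue;
    w->dispatch(c, event);
    ++applied;
  }
  return applied;
}

// [[Rcpp::export]]
void cpp_world_normalize_liquid(SEXP wp) {
  WorldPtr w(wp);
  w->normalize_liquid();
}

// [[Rcpp::export]]
List cpp_world_state(SEXP wp) {
  WorldPtr w(wp);
  return List::create(
    _["t"] = (double)w->t,
    _["n_liquid"] = w->n_liquid(),
    _["n_surface"] = w->n_surface,
    _["sticky_liquid"] = w->stick_liq,
    _["sticky_surface"] = w->stick_surf,
    _["n_genotypes"] = w->n_geno_live,
    _["K"] = w->K,
    _["n_sites"] = w->nsites);
}

// [[Rcpp::export]]
DataFrame cpp_world_cells(SEXP wp) {
  WorldPtr w(wp);
  std::vector<double> id, gid;
  std::vector<int> sticky, niche, row, col;
  const int cap = (int)w->c_geno.size();
  for (int c = 0; c < cap; ++c) {
    if (!w->c_alive[c]) continue;
    id.push_back((double)w->c_id[c]);
    gid.push_back((double)w->g_id[w->c_geno[c]]);
    sticky.push_back(w->c_sticky[c]);
    const int s = w->c_site[c];
    niche.push_back(s >= 0 ? 1 : 0);
    row.push_back(s >= 0 ? s / w->width : NA_INTEGER);
    col.push_back(s >= 0 ? s % w->width : NA_INTEGER);
  }
  return DataFrame::create(
    _["cell_id"] = id, _["genotype_id"] = gid, _["sticky"] = sticky,
    _["on_surface"] = niche, _["row"] = row, _["col"] = col);
}

// Occupied sites in row-major (row, col) order.
// [[Rcpp::export]]
DataFrame cpp_world_grid(SEXP wp) {
  WorldPtr w(wp);
  std::vector<int> row, col, sticky;
  std::vector<double> id, gid;
  for (int s = 0; s < w->nsites; ++s) {
    const int c = w->occupancy[s];
    if (c < 0) continue;
    row.push_back(s / w->width);
    col.push_back(s % w->width);
    id.push_back((double)w->c_id[c]);
    gid.push_back((double)w->g_id[w->c_geno[c]]);
    sticky.push_back(w->c_sticky[c]);
  }
  return DataFrame::create(
    _["row"] = row, _["col"] = col, _["cell_id"] = id,
    _["genotype_id"] = gid, _["sticky"] = sticky);
}

// [[Rcpp::export]]
DataFrame cpp_world_genotypes(SEXP wp) {
  WorldPtr w(wp);
  std::vector<int> slot, kind, ref;
  std::vector<double> id, allele, P, W1, W2, theta, ovr;
  const int cap = (int)w->g_kind.size();
  for (int g = 0; g < cap; ++g) {
    if (!w->g_used[g]) continue;
    if (w->g_ref[g] == 0 && !w->g_pinned[g]) continue;
    slot.push_back(g);
    id.push_back((double)w->g_id[g]);
    kind.push_back(w->g_kind[g]);
    allele.push_back(w->g_allele[g]);
    P.push_back(w->g_P[g]);
    W1.push_back(w->g_W1[g]);
    W2.push_back(w->g_W2[g]);
    theta.push_back(w->g_theta[g]);
    ovr.push_back(w->g_override[g]);
    ref.push_back(w->g_ref[g]);
  }
  return DataFrame::create(
    _["slot"] = slot, _["id"] = id, _["kind"] = kind, _["allele"] = allele,
    _["P"] = P, _["W1"] = W1, _["W2"] = W2, _["theta"] = theta,
    _["sticky_death"] = ovr, _["abundance"] = ref);
}

// [[Rcpp::export]]
List cpp_world_counters(SEXP wp) {
  WorldPtr w(wp);
  NumericVector dr(5);
  for (int i = 0; i < 5; ++i) dr[i] = (double)w->drawn[i];
  dr.names() = CharacterVector::create(
    "migrate_to_surface", "migrate_to_liquid", "differentiate", "death",
    "divide");
  return List::create(
    _["events_drawn"] = dr,
    _["attachments"] = (double)w->n_attach,
    _["dislodgements"] = (double)w->n_dislodge,
    _["phenotype_switches"] = (double)w->n_diff_switch,
    _["deaths"] = (double)w->n_deaths,
    _["dilutions"] = (double)w->n_dilutions,
    _["divisions"] = (double)w->n_divisions,
    _["sticky_divisions"] = (double)w->n_sticky_divisions,
    _["daughters_to_liquid"] = (double)w->n_daughters_liquid,
    _["daughters_to_surface"] = (double)w->n_daughters_surface,
    _["surface_divisions_to_liquid"] =
      (double)w->n_div_to_liquid_from_surface);
}

// ------------------------------------------- standalone geometry calls ----

// [[Rcpp::export]]
IntegerMatrix cpp_neighbours(int height, int width, int geom, int boundary,
                             int row, int col) {
  if (row < 0 || row >= height || col < 0 || col >= width)
    stop("position out of range");
  std::vector<int> nbr, deg;
  // building the whole table for one query is fine at test sizes; the
  // engine reuses its own precomputed copy of the same table
  build_neighbour_table(height, width, geom, boundary, nbr, deg, 8);
  const int site = row * width + col;
  const int d = deg[site];
  IntegerMatrix out(d, 2);
  for (int i = 0; i < d; ++i) {
    const int s = nbr[(size_t)site * 8 + i];
    out(i, 0) = s / width;
    out(i, 1) = s % width;
  }
  return out;
}
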