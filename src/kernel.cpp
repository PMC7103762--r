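// Continuous-time, discrete-event kernel for RNAPII transcription under UV damage.
//
// State: a small set of genes, a finite polymerase pool, per-gene ordered occupant
// lists (downstream first) and lesion lists. Between events every moving polymerase
// advances at the common elongation speed; positions are stored lazily as
// (pos, tref) pairs and materialised on demand. Pending events live in a binary
// min-heap with lazy invalidation: each polymerase carries revision counters for
// its stop and removal schedules, bumped on every reschedule, and events that
// reference an outdated revision are discarded when popped.
//
// All random draws go through R's RNG so a single set.seed() on the R side makes a
// run fully reproducible.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();
static const double EPS = 1e-9;

enum PolStatus { P_FREE = 0, P_MOVING = 1, P_STALL_LESION = 2, P_STALL_QUEUE = 3,
                 P_PAUSED = 4, P_DEGRADED = 5 };
enum StopKind { S_NONE = 0, S_LESION = 1, S_QUEUE = 2, S_COMPLETE = 3,
                S_PAUSE_SITE = 4, S_PAUSE_RESUME = 5 };

// event kinds reported to R (and used in the log)
enum EvKind { E_NONE = 0, E_INIT_PLACED = 1, E_INIT_BLOCKED = 2, E_STALL_LESION = 3,
              E_STALL_QUEUE = 4, E_PAUSE = 5, E_PAUSE_RELEASE = 6, E_RELEASE = 7,
              E_REPAIR = 8, E_REMOVAL_RECYCLED = 9, E_REMOVAL_DEGRADED = 10,
              E_COMPLETION = 11, E_DAMAGE = 12 };

// pending-event types
enum EvType { T_REPAIR = 1, T_STOP = 2, T_REMOVAL = 3, T_INIT = 4 };

struct Lesion {
  double pos;
  double repair_time;
  bool active;
};

struct Ev {
  double time;
  int pri;      // tie-break: repair 0 < completion 1 < stall/pause 2 < removal 3 < init 4
  int type;     // EvType
  int a;        // pol id, or gene for repair
  int b;        // lesion index for repair, stop kind for stop
  long rev;     // revision the event was scheduled under
};
struct EvLater {
  bool operator()(const Ev& x, const Ev& y) const {
    if (x.time != y.time) return x.time > y.time;
    if (x.pri != y.pri) return x.pri > y.pri;
    if (x.a != y.a) return x.a > y.a;
    return x.b > y.b;
  }
};

class Engine {
public:
  // parameters
  int n_genes;
  std::vector<double> glen, gw_cum;
  double wsum;
  int pool_size;
  double init_rate;       // per free polymerase, per second
  double speed;           // nt per second
  double footprint;       // nt
  bool pause_on;
  double pause_offset, pause_dwell;
  double lesion_density;  // per nt
  double lesion_mean;     // mean repair waiting time = halflife / ln 2
  double hz_move, hz_stall;
  double p_rec_removal, p_rec_complete;

  // state
  double clock;
  std::vector<int> pol_gene;      // -1 when not engaged
  std::vector<double> pol_pos, pol_tref;
  std::vector<int> pol_status;
  std::vector<char> pol_paused_done;
  std::vector<double> stop_time, stop_pos;
  std::vector<int> stop_kind;
  std::vector<double> removal_time;
  std::vector<long> stop_rev, rem_rev;
  long init_rev;
  std::vector< std::vector<int> > occ;        // per gene, descending position
  std::vector< std::vector<Lesion> > lesions; // per gene, ascending position
  std::vector<int> freelist;
  int degraded;
  std::vector<double> mrna, init_assigned, init_placed, completions_gene;
  double completions, removals, removals_recycled, blocked;
  double next_init_time;
  bool damaged;
  double damage_time;
  long long n_events;
  std::priority_queue<Ev, std::vector<Ev>, EvLater> pq;

  // optional event log
  bool log_on;
  std::vector<double> lg_time;
  std::vector<int> lg_kind, lg_pol, lg_gene;
  std::vector<double> lg_pos;

  Engine(List par) {
    NumericVector L = par["gene_length"];
    NumericVector W = par["gene_weight"];
    n_genes = L.size();
    glen.assign(L.begin(), L.end());
    wsum = 0.0;
    gw_cum.resize(n_genes);
    for (int g = 0; g < n_genes; ++g) { wsum += W[g]; gw_cum[g] = wsum; }
    pool_size = as<int>(par["pool_size"]);
    init_rate = as<double>(par["initiation_rate"]);
    speed = as<double>(par["elongation_speed"]);
    footprint = as<double>(par["footprint"]);
    pause_offset = as<double>(par["pause_site_offset"]);
    pause_dwell = as<double>(par["pause_mean_dwell"]);
    pause_on = R_finite(pause_offset) && pause_offset > 0 && R_finite(pause_dwell) && pause_dwell > 0;
    lesion_density = as<double>(par["lesion_density"]);
    lesion_mean = as<double>(par["lesion_halflife"]) / M_LN2;
    hz_move = as<double>(par["moving_removal_hazard"]);
    hz_stall = as<double>(par["stalled_removal_hazard"]);
    p_rec_removal = as<double>(par["removal_recycle_prob"]);
    p_rec_complete = as<double>(par["completion_recycle_prob"]);

    clock = 0.0;
    pol_gene.assign(pool_size, -1);
    pol_pos.assign(pool_size, 0.0);
    pol_tref.assign(pool_size, 0.0);
    pol_status.assign(pool_size, P_FREE);
    pol_paused_done.assign(pool_size, 0);
    stop_time.assign(pool_size, INF);
    stop_pos.assign(pool_size, 0.0);
    stop_kind.assign(pool_size, S_NONE);
    removal_time.assign(pool_size, INF);
    stop_rev.assign(pool_size, 0);
    rem_rev.assign(pool_size, 0);
    init_rev = 0;
    occ.assign(n_genes, std::vector<int>());
    lesions.assign(n_genes, std::vector<Lesion>());
    freelist.resize(pool_size);
    for (int i = 0; i < pool_size; ++i) freelist[i] = pool_size - 1 - i; // pop from back -> id 0 first
    degraded = 0;
    mrna.assign(n_genes, 0.0);
    init_assigned.assign(n_genes, 0.0);
    init_placed.assign(n_genes, 0.0);
    completions_gene.assign(n_genes, 0.0);
    completions = removals = removals_recycled = blocked = 0.0;
    damaged = false;
    damage_time = NA_REAL;
    n_events = 0;
    log_on = false;
    reschedule_init();
  }

  int free_pool() const { return (int) freelist.size(); }

  void log(int kind, double t, int pol, int gene, double pos) {
    if (!log_on) return;
    lg_time.push_back(t); lg_kind.push_back(kind);
    lg_pol.push_back(pol); lg_gene.push_back(gene); lg_pos.push_back(pos);
  }

  double pos_at(int i) const {
    if (pol_status[i] == P_MOVING) return pol_pos[i] + speed * (clock - pol_tref[i]);
    return pol_pos[i];
  }

  void materialize(int i) { pol_pos[i] = pos_at(i); pol_tref[i] = clock; }

  int occ_index(int g, int i) const {
    const std::vector<int>& o = occ[g];
    for (size_t k = 0; k < o.size(); ++k) if (o[k] == i) return (int) k;
    return -1;
  }

  static int stop_pri(int kind) { return kind == S_COMPLETE ? 1 : 2; }

  void push_stop(int i) {
    if (R_finite(stop_time[i]))
      pq.push(Ev{stop_time[i], stop_pri(stop_kind[i]), T_STOP, i, stop_kind[i], stop_rev[i]});
  }

  void clear_stop(int i) {
    stop_time[i] = INF; stop_kind[i] = S_NONE; ++stop_rev[i];
  }

  void draw_removal(int i) {
    double hz = (pol_status[i] == P_STALL_LESION || pol_status[i] == P_STALL_QUEUE)
                  ? hz_stall : hz_move;
    ++rem_rev[i];
    removal_time[i] = (hz > 0) ? clock + R::rexp(1.0 / hz) : INF;
    if (R_finite(removal_time[i]))
      pq.push(Ev{removal_time[i], 3, T_REMOVAL, i, 0, rem_rev[i]});
  }

  void clear_removal(int i) { removal_time[i] = INF; ++rem_rev[i]; }

  // next stop (lesion / queue / pause / completion) for a moving polymerase
  void compute_stop(int i) {
    int g = pol_gene[i];
    double x = pos_at(i);
    double target = glen[g];
    int kind = S_COMPLETE;
    if (pause_on && !pol_paused_done[i] && x < pause_offset - EPS && pause_offset < target) {
      target = pause_offset; kind = S_PAUSE_SITE;
    }
    const std::vector<Lesion>& ls = lesions[g];
    for (size_t k = 0; k < ls.size(); ++k) {
      if (ls[k].active && ls[k].pos > x + EPS && ls[k].pos < target) {
        target = ls[k].pos; kind = S_LESION;
      }
    }
    int idx = occ_index(g, i);
    if (idx > 0) {
      int nb = occ[g][idx - 1];
      if (pol_status[nb] != P_MOVING) {
        double q = pol_pos[nb] - footprint;
        if (q <= target + EPS) { target = q; kind = S_QUEUE; }
      }
    }
    if (target < x - EPS) target = x; // numeric guard; cannot move backwards
    ++stop_rev[i];
    stop_pos[i] = target;
    stop_time[i] = clock + std::max(0.0, (target - x)) / speed;
    stop_kind[i] = kind;
    push_stop(i);
  }

  void reschedule_init() {
    double rate = init_rate * free_pool();
    ++init_rev;
    next_init_time = (rate > 0) ? clock + R::rexp(1.0 / rate) : INF;
    if (R_finite(next_init_time))
      pq.push(Ev{next_init_time, 4, T_INIT, -1, 0, init_rev});
  }

  // release a stalled/paused polymerase into motion, then the contiguous queue behind it
  void release_chain(int g, int start_idx) {
    const std::vector<int>& o = occ[g];
    for (size_t k = (size_t) start_idx; k < o.size(); ++k) {
      int i = o[k];
      if (k > (size_t) start_idx && pol_status[i] != P_STALL_QUEUE) break;
      pol_status[i] = P_MOVING;
      pol_tref[i] = clock;
      draw_removal(i);
      compute_stop(i);
      log(E_RELEASE, clock, i, g, pol_pos[i]);
      if (k + 1 < o.size() && pol_status[o[k + 1]] != P_STALL_QUEUE) break;
    }
  }

  // after removing the occupant that sat at occ index `e`, update the polymerase now at `e`
  void on_vacate(int g, int e) {
    if (e >= (int) occ[g].size()) return;
    int u = occ[g][e];
    if (pol_status[u] == P_MOVING) {
      compute_stop(u);
    } else if (pol_status[u] == P_STALL_QUEUE) {
      release_chain(g, e);
    }
  }

  void resolve_fate(int i, double p_recycle, bool is_removal) {
    double u = R::unif_rand();
    clear_stop(i);
    clear_removal(i);
    pol_gene[i] = -1;
    if (u < p_recycle) {
      pol_status[i] = P_FREE;
      freelist.push_back(i);
      if (is_removal) { removals_recycled += 1; log(E_REMOVAL_RECYCLED, clock, i, -1, NA_REAL); }
    } else {
      pol_status[i] = P_DEGRADED;
      degraded += 1;
      if (is_removal) log(E_REMOVAL_DEGRADED, clock, i, -1, NA_REAL);
    }
    reschedule_init();
  }

  void handle_init() {
    double u = R::unif_rand() * wsum;
    int g = 0;
    while (g < n_genes - 1 && u > gw_cum[g]) ++g;
    init_assigned[g] += 1;
    bool clear = true;
    if (!occ[g].empty()) {
      int last = occ[g].back(); // most TSS-proximal occupant
      if (pos_at(last) < footprint - EPS) clear = false;
    }
    if (clear && free_pool() > 0) {
      int i = freelist.back(); freelist.pop_back();
      pol_gene[i] = g;
      pol_pos[i] = 0.0; pol_tref[i] = clock;
      pol_status[i] = P_MOVING;
      pol_paused_done[i] = 0;
      occ[g].push_back(i);
      init_placed[g] += 1;
      compute_stop(i);
      draw_removal(i);
      log(E_INIT_PLACED, clock, i, g, 0.0);
    } else {
      blocked += 1;
      log(E_INIT_BLOCKED, clock, -1, g, NA_REAL);
    }
    reschedule_init();
  }

  int handle_stop(int i) {
    int g = pol_gene[i];
    int kind = stop_kind[i];
    if (kind == S_LESION) {
      // defensive: a stop aimed at a lesion that has since been repaired is stale
      bool live = false;
      for (size_t k = 0; k < lesions[g].size(); ++k)
        if (lesions[g][k].active && std::abs(lesions[g][k].pos - stop_pos[i]) < 1e-6) { live = true; break; }
      if (!live) { compute_stop(i); return E_RELEASE; }
    }
    if (kind == S_COMPLETE) {
      pol_pos[i] = stop_pos[i]; pol_tref[i] = clock;
      int idx = occ_index(g, i);
      occ[g].erase(occ[g].begin() + idx);
      mrna[g] += 1; completions += 1; completions_gene[g] += 1;
      log(E_COMPLETION, clock, i, g, glen[g]);
      resolve_fate(i, p_rec_complete, false);
      on_vacate(g, idx);
      return E_COMPLETION;
    }
    if (kind == S_LESION || kind == S_QUEUE) {
      pol_pos[i] = stop_pos[i]; pol_tref[i] = clock;
      pol_status[i] = (kind == S_LESION) ? P_STALL_LESION : P_STALL_QUEUE;
      clear_stop(i);
      draw_removal(i);
      int idx = occ_index(g, i);
      if (idx + 1 < (int) occ[g].size()) {
        int u = occ[g][idx + 1];
        if (pol_status[u] == P_MOVING) compute_stop(u);
      }
      log(kind == S_LESION ? E_STALL_LESION : E_STALL_QUEUE, clock, i, g, pol_pos[i]);
      return kind == S_LESION ? E_STALL_LESION : E_STALL_QUEUE;
    }
    if (kind == S_PAUSE_SITE) {
      pol_pos[i] = stop_pos[i]; pol_tref[i] = clock;
      pol_status[i] = P_PAUSED;
      ++stop_rev[i];
      stop_kind[i] = S_PAUSE_RESUME;
      stop_time[i] = clock + R::rexp(pause_dwell);
      push_stop(i);
      int idx = occ_index(g, i);
      if (idx + 1 < (int) occ[g].size()) {
        int u = occ[g][idx + 1];
        if (pol_status[u] == P_MOVING) compute_stop(u);
      }
      log(E_PAUSE, clock, i, g, pol_pos[i]);
      return E_PAUSE;
    }
    // S_PAUSE_RESUME
    pol_paused_done[i] = 1;
    clear_stop(i);
    int idx = occ_index(g, i);
    release_chain(g, idx);
    log(E_PAUSE_RELEASE, clock, i, g, pol_pos[i]);
    return E_PAUSE_RELEASE;
  }

  int handle_removal(int i) {
    int g = pol_gene[i];
    materialize(i);
    int idx = occ_index(g, i);
    occ[g].erase(occ[g].begin() + idx);
    removals += 1;
    resolve_fate(i, p_rec_removal, true);
    int out = pol_status[i] == P_DEGRADED ? E_REMOVAL_DEGRADED : E_REMOVAL_RECYCLED;
    on_vacate(g, idx);
    return out;
  }

  void handle_repair(int g, int li) {
    Lesion& L = lesions[g][li];
    L.active = false;
    log(E_REPAIR, clock, -1, g, L.pos);
    // polymerase stalled exactly at the lesion resumes, plus its queue
    const std::vector<int>& o = occ[g];
    for (size_t k = 0; k < o.size(); ++k) {
      int i = o[k];
      if (pol_status[i] == P_STALL_LESION && std::abs(pol_pos[i] - L.pos) < 1e-6) {
        release_chain(g, (int) k);
        break;
      }
    }
    // any moving polymerase whose stop still targets the repaired lesion is stale
    for (size_t k = 0; k < occ[g].size(); ++k) {
      int i = occ[g][k];
      if (pol_status[i] == P_MOVING && stop_kind[i] == S_LESION &&
          std::abs(stop_pos[i] - L.pos) < 1e-6)
        compute_stop(i);
    }
  }

  void apply_damage() {
    if (damaged) stop("apply_damage: damage has already been introduced in this run");
    damaged = true;
    damage_time = clock;
    for (int g = 0; g < n_genes; ++g) {
      int n = (lesion_density > 0) ? (int) R::rpois(glen[g] * lesion_density) : 0;
      for (int k = 0; k < n; ++k) {
        double p = R::unif_rand() * glen[g];
        if (p <= 0 || p >= glen[g]) { --k; continue; } // positions strictly inside (0, L)
        Lesion L;
        L.pos = p;
        L.repair_time = clock + R::rexp(lesion_mean);
        L.active = true;
        lesions[g].push_back(L); // storage order is creation order; indices are stable
      }
      for (size_t k = 0; k < lesions[g].size(); ++k) {
        pq.push(Ev{lesions[g][k].repair_time, 0, T_REPAIR, g, (int) k, 0});
      }
      for (size_t k = 0; k < occ[g].size(); ++k) {
        int i = occ[g][k];
        if (pol_status[i] == P_MOVING) compute_stop(i);
      }
    }
    log(E_DAMAGE, clock, -1, -1, NA_REAL);
  }

  // deterministic lesion placement (tests, bespoke damage layouts)
  void add_lesion(int g, double pos, double repair_time) {
    if (g < 0 || g >= n_genes) stop("unknown gene");
    if (pos <= 0 || pos >= glen[g]) stop("lesion position must lie strictly inside the gene");
    if (repair_time < clock) stop("repair_time precedes the clock");
    Lesion L; L.pos = pos; L.repair_time = repair_time; L.active = true;
    lesions[g].push_back(L);
    pq.push(Ev{repair_time, 0, T_REPAIR, g, (int) lesions[g].size() - 1, 0});
    for (size_t k = 0; k < occ[g].size(); ++k) {
      int i = occ[g][k];
      if (pol_status[i] == P_MOVING) compute_stop(i);
    }
  }

  bool ev_valid(const Ev& e) const {
    switch (e.type) {
      case T_REPAIR: return lesions[e.a][e.b].active;
      case T_STOP: return e.rev == stop_rev[e.a] && R_finite(stop_time[e.a]);
      case T_REMOVAL: return e.rev == rem_rev[e.a] && R_finite(removal_time[e.a]);
      default: return e.rev == init_rev && R_finite(next_init_time);
    }
  }

  // drop stale events from the top of the heap
  void prune() {
    while (!pq.empty() && !ev_valid(pq.top())) pq.pop();
  }

  // next pending event: type 0 when none
  void peek(double& t, int& type, int& a, int& b) {
    prune();
    if (pq.empty()) { t = INF; type = 0; a = -1; b = -1; return; }
    const Ev& e = pq.top();
    t = e.time; type = e.type; a = e.a; b = e.b;
  }

  // handle the earliest pending event; returns its kind (E_NONE if nothing pending)
  int step(double& ev_time, int& ev_pol, int& ev_gene) {
    prune();
    ev_time = INF; ev_pol = -1; ev_gene = -1;
    if (pq.empty()) return E_NONE;
    Ev e = pq.top(); pq.pop();
    ev_time = e.time;
    if (e.time < clock - 1e-6) stop("internal error: event time precedes clock");
    clock = std::max(clock, e.time);
    n_events += 1;
    switch (e.type) {
      case T_REPAIR: ev_gene = e.a; handle_repair(e.a, e.b); return E_REPAIR;
      case T_STOP: ev_pol = e.a; ev_gene = pol_gene[e.a]; return handle_stop(e.a);
      case T_REMOVAL: ev_pol = e.a; ev_gene = pol_gene[e.a]; return handle_removal(e.a);
      default: handle_init(); return E_INIT_PLACED;
    }
  }

  void run_until(double T) {
    for (;;) {
      prune();
      if (pq.empty() || pq.top().time > T) break;
      double et; int ep, eg;
      step(et, ep, eg);
    }
    if (T > clock) clock = T;
  }

  void advance(double dt) {
    if (dt < 0) stop("advance_positions: dt must be non-negative");
    prune();
    if (!pq.empty() && clock + dt > pq.top().time + 1e-9)
      stop("advance_positions: dt would carry the state past the next pending event");
    clock += dt;
  }

  void check_invariants() const {
    int engaged = 0;
    for (int g = 0; g < n_genes; ++g) engaged += (int) occ[g].size();
    if (engaged + free_pool() + degraded != pool_size)
      stop("conservation violated: free + engaged + degraded != pool_size");
    for (int g = 0; g < n_genes; ++g) {
      double prev = INF;
      for (size_t k = 0; k < occ[g].size(); ++k) {
        int i = occ[g][k];
        double x = pos_at(i);
        if (x < -1e-6 || x > glen[g] + 1e-6) stop("position outside gene body");
        if (prev < INF && x > prev - footprint + 1e-6)
          stop("footprint exclusion violated");
        prev = x;
        if (pol_status[i] == P_MOVING) {
          double nearest = INF;
          for (size_t l = 0; l < lesions[g].size(); ++l) {
            const Lesion& L = lesions[g][l];
            if (L.active && L.pos > x + EPS && L.pos < nearest) nearest = L.pos;
          }
          if (nearest < INF && stop_pos[i] > nearest + 1e-6)
            stop("moving polymerase targets a position beyond an unrepaired lesion");
        }
      }
    }
  }
};

static Engine* get(SEXP ptr) {
  Rcpp::XPtr<Engine> xp(ptr);
  return xp.get();
}

// [[Rcpp::export(name = ".engine_new")]]
SEXP engine_new(List par) {
  Engine* e = new Engine(par);
  Rcpp::XPtr<Engine> xp(e, true);
  return xp;
}

// [[Rcpp::export(name = ".engine_clock")]]
double engine_clock(SEXP ptr) { return get(ptr)->clock; }

// [[Rcpp::export(name = ".engine_run_until")]]
void engine_run_until(SEXP ptr, double t) { get(ptr)->run_until(t); }

// [[Rcpp::export(name = ".engine_advance")]]
void engine_advance(SEXP ptr, double dt) { get(ptr)->advance(dt); }

// [[Rcpp::export(name = ".engine_apply_damage")]]
void engine_apply_damage(SEXP ptr) { get(ptr)->apply_damage(); }

// [[Rcpp::export(name = ".engine_step")]]
List engine_step(SEXP ptr) {
  Engine* e = get(ptr);
  double t; int pol, gene;
  int kind = e->step(t, pol, gene);
  return List::create(_["time"] = R_finite(t) ? t : NA_REAL,
                      _["kind"] = kind,
                      _["pol"] = pol >= 0 ? pol + 1 : NA_INTEGER,
                      _["gene"] = gene >= 0 ? gene + 1 : NA_INTEGER);
}

// [[Rcpp::export(name = ".engine_peek")]]
List engine_peek(SEXP ptr) {
  Engine* e = get(ptr);
  double t; int type, a, b;
  e->peek(t, type, a, b);
  int kind_b = (type == T_STOP) ? b : -1;
  return List::create(_["time"] = R_finite(t) ? t : NA_REAL,
                      _["type"] = type,
                      _["a"] = a,
                      _["b"] = kind_b);
}

// [[Rcpp::export(name = ".engine_next_stop")]]
List engine_next_stop(SEXP ptr, int pol) {
  Engine* e = get(ptr);
  int i = pol - 1;
  if (i < 0 || i >= e->pool_size) stop("unknown polymerase id");
  if (e->pol_status[i] != P_MOVING) stop("polymerase is not moving");
  // preview only: recompute, then restore (the extra heap entries stay stale-safe
  // because compute_stop bumps the revision and we bump it again on restore)
  double saved_t = e->stop_time[i], saved_p = e->stop_pos[i];
  int saved_k = e->stop_kind[i];
  e->compute_stop(i);
  List out = List::create(_["time"] = e->stop_time[i],
                          _["position"] = e->stop_pos[i],
                          _["kind"] = e->stop_kind[i]);
  ++e->stop_rev[i];
  e->stop_time[i] = saved_t; e->stop_pos[i] = saved_p; e->stop_kind[i] = saved_k;
  e->push_stop(i);
  return out;
}

// [[Rcpp::export(name = ".engine_add_lesion")]]
void engine_add_lesion(SEXP ptr, int gene, double pos, double repair_time) {
  get(ptr)->add_lesion(gene - 1, pos, repair_time);
}

// [[Rcpp::export(name = ".engine_counts")]]
NumericVector engine_counts(SEXP ptr) {
  Engine* e = get(ptr);
  int engaged = 0;
  for (int g = 0; g < e->n_genes; ++g) engaged += (int) e->occ[g].size();
  return NumericVector::create(
    _["clock"] = e->clock,
    _["free_pool"] = e->free_pool(),
    _["engaged"] = engaged,
    _["degraded"] = e->degraded,
    _["placed"] = std::accumulate(e->init_placed.begin(), e->init_placed.end(), 0.0),
    _["assigned"] = std::accumulate(e->init_assigned.begin(), e->init_assigned.end(), 0.0),
    _["blocked"] = e->blocked,
    _["completions"] = e->completions,
    _["removals"] = e->removals,
    _["removals_recycled"] = e->removals_recycled,
    _["n_events"] = (double) e->n_events);
}

// [[Rcpp::export(name = ".engine_gene_counts")]]
List engine_gene_counts(SEXP ptr) {
  Engine* e = get(ptr);
  return List::create(_["mrna"] = NumericVector(e->mrna.begin(), e->mrna.end()),
                      _["init_assigned"] = NumericVector(e->init_assigned.begin(), e->init_assigned.end()),
                      _["init_placed"] = NumericVector(e->init_placed.begin(), e->init_placed.end()),
                      _["completions"] = NumericVector(e->completions_gene.begin(), e->completions_gene.end()));
}

// [[Rcpp::export(name = ".engine_snapshot")]]
List engine_snapshot(SEXP ptr) {
  Engine* e = get(ptr);
  std::vector<int> pid, pgene, pstat;
  std::vector<double> ppos;
  for (int g = 0; g < e->n_genes; ++g) {
    for (size_t k = 0; k < e->occ[g].size(); ++k) {
      int i = e->occ[g][k];
      pid.push_back(i + 1);
      pgene.push_back(g + 1);
      ppos.push_back(e->pos_at(i));
      pstat.push_back(e->pol_status[i]);
    }
  }
  std::vector<int> lgene;
  std::vector<double> lpos, lrep;
  std::vector<int> lact;
  for (int g = 0; g < e->n_genes; ++g) {
    for (size_t k = 0; k < e->lesions[g].size(); ++k) {
      const Lesion& L = e->lesions[g][k];
      lgene.push_back(g + 1);
      lpos.push_back(L.pos);
      lrep.push_back(L.repair_time);
      lact.push_back(L.active ? 1 : 0);
    }
  }
  return List::create(
    _["clock"] = e->clock,
    _["pol_id"] = IntegerVector(pid.begin(), pid.end()),
    _["pol_gene"] = IntegerVector(pgene.begin(), pgene.end()),
    _["pol_position"] = NumericVector(ppos.begin(), ppos.end()),
    _["pol_status"] = IntegerVector(pstat.begin(), pstat.end()),
    _["lesion_gene"] = IntegerVector(lgene.begin(), lgene.end()),
    _["lesion_position"] = NumericVector(lpos.begin(), lpos.end()),
    _["lesion_repair_time"] = NumericVector(lrep.begin(), lrep.end()),
    _["lesion_active"] = IntegerVector(lact.begin(), lact.end()),
    _["free_pool"] = e->free_pool(),
    _["degraded"] = e->degraded,
    _["mrna"] = NumericVector(e->mrna.begin(), e->mrna.end()),
    _["damaged"] = e->damaged,
    _["damage_time"] = e->damage_time);
}

// [[Rcpp::export(name = ".engine_validate")]]
bool engine_validate(SEXP ptr) {
  get(ptr)->check_invariants();
  return true;
}

// [[Rcpp::export(name = ".engine_set_log")]]
void engine_set_log(SEXP ptr, bool on) { get(ptr)->log_on = on; }

// [[Rcpp::export(name = ".engine_get_log")]]
DataFrame engine_get_log(SEXP ptr) {
  Engine* e = get(ptr);
  IntegerVector pol(e->lg_pol.size()), gene(e->lg_gene.size());
  for (size_t k = 0; k < e->lg_pol.size(); ++k)
    pol[k] = e->lg_pol[k] >= 0 ? e->lg_pol[k] + 1 : NA_INTEGER;
  for (size_t k = 0; k < e->lg_gene.size(); ++k)
    gene[k] = e->lg_gene[k] >= 0 ? e->lg_gene[k] + 1 : NA_INTEGER;
  return DataFrame::create(
    _["time"] = NumericVector(e->lg_time.begin(), e->lg_time.end()),
    _["kind"] = IntegerVector(e->lg_kind.begin(), e->lg_kind.end()),
    _["pol_id"] = pol,
    _["gene"] = gene,
    _["position"] = NumericVector(e->lg_pos.begin(), e->lg_pos.end()));
}
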