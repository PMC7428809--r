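// Discrete-event engine for the crypt metapopulation microsimulation.
//
// Every living stem cell carries two clocks: a pooled division clock
// (symmetric + asymmetric, rate (1 + asym_ratio) * r_sym, floored at
// division_min_time; the kind is drawn 1:asym_ratio when the clock fires)
// and a loss clock (floored at loss_min_time).  Flooring the pooled clock
// is distributionally identical to flooring each component because
// min_i max(E_i, m) = max(min_i E_i, m).  Clocks are drawn when a cell is
// created and redrawn whenever the cell's rates change: a change in its
// crypt's population or dead-neighbor count, or a fitness mutation of its
// own.  For pure exponentials this redraw-on-change policy is exact by
// memorylessness; the min-time floors deform the exponential only once per
// scheduled event.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <string>
#include <limits>

namespace {

const double INF = std::numeric_limits<double>::infinity();

// Deterministic 64-bit Mersenne-Twister-free generator: splitmix64 seeded
// xoshiro256** gives a portable, implementation-independent stream.
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // exponential deviate; rate <= 0 means the event never happens
  double rexp(double rate) {
    if (rate <= 0.0) return INF;
    double u = unif();            // in [0, 1) so 1 - u in (0, 1]
    return -std::log1p(-u) / rate;
  }
};

struct Params {
  double max_days, base_division_rate, asym_to_sym_ratio, base_loss_rate;
  double mutation_rate, mutation_rate_max, tsg_mutation_rate, tsg_mutation_rate_max;
  double mutator_factor, division_min_time, loss_min_time;
  double ta_cells_per_stem;
  int    crypt_size;
  double crypt_deviation, bifurcation_factor;
  double loss_effect_base, division_effect_base, dead_neighbor_division_multiplier;
  double uncontrolled_threshold;
  int    tsg_hits_for_initiation;
  double deleterious_fraction;
  double ben_div, ben_surv, ben_mutator;   // beneficial_split
  double del_div, del_surv;                // deleterious_split
  double fitness_factor;
  int    grid_rows, grid_cols;
};

struct Cell {
  int n_ben_div = 0, n_ben_surv = 0, n_del_div = 0, n_del_surv = 0;
  int tsg_hits = 0;
  bool is_mutator = false;
  double fit_div = 1.0;    // k^(n_ben_div - n_del_div), multiplies division rate
  double fit_loss = 1.0;   // k^(n_del_surv - n_ben_surv), multiplies loss rate
  int64_t id = 0;
  double birth_time = 0.0;
  double t_div = INF, t_loss = INF;   // absolute next-event times
};

struct Crypt {
  std::vector<Cell> cells;
  bool alive = false;
  double created_time = 0.0;
  double extinct_time = -1.0;
  int n_dead_neighbors = 0;
  // cached minimum over the crypt's clocks, kept in sync by the engine
  double min_time = INF;
  int min_cell = -1;
  bool min_is_div = false;
};

struct EventRec {
  double time;
  int kind;        // 0 sym division, 1 asym division, 2 loss, 3 mutation
  int q, r;
  int64_t cell_id;
  int n_cells_after;
  int mut_category; // -1 none; 0 del_div 1 del_surv 2 ben_div 3 ben_surv 4 mutator 5 tsg_hit
  int tsg_hits_after;
};

struct TurnoverRec {
  int kind;    // 0 birth, 1 death
  double time;
  int q, r, parent_q, parent_r; // parent_* = -1 for deaths
  double lifespan;              // NA (-1) for births
};

class Engine {
public:
  Params p;
  Rng rng;
  bool record_events, enable_uncontrolled;
  std::vector<Crypt> crypts;                 // slot-indexed, q-major
  std::vector<std::vector<int>> nbrs;        // per-slot neighbor slot indices
  double t = 0.0;
  int64_t next_id = 0;
  int n_total_cells = 0, n_living_crypts = 0;

  // counters
  int64_t n_symmetric = 0, n_asymmetric = 0, n_losses = 0;
  int64_t mut_counts[6] = {0, 0, 0, 0, 0, 0};
  double cell_time_integral = 0.0, crypt_time_integral = 0.0;

  // outcome
  std::string endpoint = "censored";
  double endpoint_time = 0.0;
  int initiating_was_mutator = NA_INTEGER;

  std::vector<EventRec> events;
  std::vector<TurnoverRec> turnover;

  Engine(const Params& pars, uint64_t seed, bool rec, bool unc)
    : p(pars), rng(seed), record_events(rec), enable_uncontrolled(unc) {}

  int slot_of(int q, int r) const { return q * p.grid_rows + r; }
  int q_of(int slot) const { return slot / p.grid_rows; }
  int r_of(int slot) const { return slot % p.grid_rows; }

  void build_topology() {
    int n = p.grid_rows * p.grid_cols;
    nbrs.assign(n, {});
    const int dq[6] = { 1, -1, 0, 0, 1, -1 };
    const int dr[6] = { 0, 0, 1, -1, -1, 1 };
    for (int q = 0; q < p.grid_cols; ++q)
      for (int r = 0; r < p.grid_rows; ++r) {
        int s = slot_of(q, r);
        for (int k = 0; k < 6; ++k) {
          int nq = q + dq[k], nr = r + dr[k];
          if (nq >= 0 && nq < p.grid_cols && nr >= 0 && nr < p.grid_rows)
            nbrs[s].push_back(slot_of(nq, nr));
        }
      }
  }

  void init() {
    build_topology();
    int n = p.grid_rows * p.grid_cols;
    crypts.assign(n, Crypt());
    for (int s = 0; s < n; ++s) {
      Crypt& c = crypts[s];
      c.alive = true;
      c.created_time = 0.0;
      c.cells.resize(p.crypt_size);
      for (Cell& cell : c.cells) { cell.id = next_id++; }
      n_total_cells += p.crypt_size;
      ++n_living_crypts;
      schedule_crypt(s);
    }
  }

  // crypt-level rate factors
  void crypt_factors(const Crypt& c, double& div_factor, double& loss_factor) const {
    double n = (double)c.cells.size();
    div_factor = std::pow(p.division_effect_base,
                          std::max(0.0, p.crypt_size - n) / p.crypt_deviation);
    if (c.n_dead_neighbors > 0) {
      div_factor *= std::pow(p.dead_neighbor_division_multiplier,
                             (double)c.n_dead_neighbors);
      loss_factor = 1.0;   // homeostatic apoptotic signal released
    } else {
      loss_factor = std::pow(p.loss_effect_base,
                             std::max(0.0, n - p.crypt_size) / p.crypt_deviation);
    }
  }

  void schedule_cell(Cell& cell, double div_factor, double loss_factor) {
    double sym = p.base_division_rate * cell.fit_div * div_factor;
    double div_total = sym * (1.0 + p.asym_to_sym_ratio);
    double loss = p.base_loss_rate * cell.fit_loss * loss_factor;
    double td = rng.rexp(div_total);
    double tl = rng.rexp(loss);
    cell.t_div  = std::isfinite(td) ? t + std::max(td, p.division_min_time) : INF;
    cell.t_loss = std::isfinite(tl) ? t + std::max(tl, p.loss_min_time) : INF;
  }

  void update_crypt_min(int s) {
    Crypt& c = crypts[s];
    c.min_time = INF; c.min_cell = -1; c.min_is_div = false;
    if (!c.alive) return;
    for (int i = 0; i < (int)c.cells.size(); ++i) {
      const Cell& cell = c.cells[i];
      if (cell.t_div < c.min_time) {
        c.min_time = cell.t_div; c.min_cell = i; c.min_is_div = true;
      }
      if (cell.t_loss < c.min_time) {
        c.min_time = cell.t_loss; c.min_cell = i; c.min_is_div = false;
      }
    }
  }

  void schedule_crypt(int s) {
    Crypt& c = crypts[s];
    if (!c.alive) return;
    double df, lf;
    crypt_factors(c, df, lf);
    for (Cell& cell : c.cells) schedule_cell(cell, df, lf);
    update_crypt_min(s);
  }

  void reschedule_one(int s, int ci) {
    Crypt& c = crypts[s];
    double df, lf;
    crypt_factors(c, df, lf);
    schedule_cell(c.cells[ci], df, lf);
    update_crypt_min(s);
  }

  void log_event(int kind, int s, int64_t cell_id, int n_after,
                 int mut_cat, int tsg_after) {
    if (!record_events) return;
    events.push_back(EventRec{t, kind, q_of(s), r_of(s), cell_id,
                              n_after, mut_cat, tsg_after});
  }

  // one mutation opportunity on a cell; returns true if fitness rates changed,
  // sets initiated if the TSG reached the required number of hits
  bool mutate(Cell& cell, int s, bool& initiated) {
    bool rates_changed = false;
    double f = cell.is_mutator ? p.mutator_factor : 1.0;
    double general = std::min(p.mutation_rate * f, p.mutation_rate_max);
    double tsg = std::min(p.tsg_mutation_rate * f, p.tsg_mutation_rate_max);
    if (rng.unif() < general) {
      int cat;
      double u = rng.unif();
      if (u < p.deleterious_fraction) {
        cat = (rng.unif() < p.del_div) ? 0 : 1;
      } else {
        double v = rng.unif();
        cat = (v < p.ben_div) ? 2 : (v < p.ben_div + p.ben_surv ? 3 : 4);
      }
      switch (cat) {
      case 0: ++cell.n_del_div;  cell.fit_div  /= p.fitness_factor; rates_changed = true; break;
      case 1: ++cell.n_del_surv; cell.fit_loss *= p.fitness_factor; rates_changed = true; break;
      case 2: ++cell.n_ben_div;  cell.fit_div  *= p.fitness_factor; rates_changed = true; break;
      case 3: ++cell.n_ben_surv; cell.fit_loss /= p.fitness_factor; rates_changed = true; break;
      case 4: cell.is_mutator = true; break;  // repeat mutator hits: no further effect
      }
      ++mut_counts[cat];
      log_event(3, s, cell.id, (int)crypts[s].cells.size(), cat, cell.tsg_hits);
    }
    if (rng.unif() < tsg) {
      if (cell.tsg_hits < p.tsg_hits_for_initiation) ++cell.tsg_hits;
      ++mut_counts[5];
      log_event(3, s, cell.id, (int)crypts[s].cells.size(), 5, cell.tsg_hits);
      if (cell.tsg_hits >= p.tsg_hits_for_initiation) {
        initiated = true;
        initiating_was_mutator = cell.is_mutator ? 1 : 0;
      }
    }
    return rates_changed;
  }

  void record_turnover_death(int s) {
    Crypt& c = crypts[s];
    turnover.push_back(TurnoverRec{1, t, q_of(s), r_of(s), -1, -1,
                                   t - c.created_time});
  }

  void mark_extinct(int s) {
    Crypt& c = crypts[s];
    c.alive = false;
    c.extinct_time = t;
    c.min_time = INF; c.min_cell = -1;
    --n_living_crypts;
    record_turnover_death(s);
    for (int nb : nbrs[s]) {
      if (crypts[nb].alive) {
        ++crypts[nb].n_dead_neighbors;
        schedule_crypt(nb);   // loss feedback released, division boosted
      }
    }
  }

  void try_bifurcate(int s) {
    Crypt& c = crypts[s];
    if ((double)c.cells.size() < p.bifurcation_factor * p.crypt_size) return;
    std::vector<int> dead;
    for (int nb : nbrs[s]) if (!crypts[nb].alive) dead.push_back(nb);
    if (dead.empty()) return;
    int target = dead[(int)(rng.unif() * dead.size())];
    // partition: move floor(n/2) uniformly chosen cells (partial Fisher-Yates)
    int n = (int)c.cells.size();
    int m = n / 2;
    for (int i = 0; i < m; ++i) {
      int j = i + (int)(rng.unif() * (n - i));
      std::swap(c.cells[i], c.cells[j]);
    }
    Crypt& d = crypts[target];
    d.cells.assign(c.cells.begin(), c.cells.begin() + m);
    c.cells.erase(c.cells.begin(), c.cells.begin() + m);
    d.alive = true;
    d.created_time = t;
    d.extinct_time = -1.0;
    ++n_living_crypts;
    turnover.push_back(TurnoverRec{0, t, q_of(target), r_of(target),
                                   q_of(s), r_of(s), -1.0});
    // recount the new crypt's dead neighbors; release its living neighbors
    d.n_dead_neighbors = 0;
    for (int nb : nbrs[target]) {
      if (!crypts[nb].alive) ++d.n_dead_neighbors;
      else if (nb != s) { --crypts[nb].n_dead_neighbors; schedule_crypt(nb); }
    }
    --c.n_dead_neighbors;
    schedule_crypt(s);
    schedule_crypt(target);
  }

  void advance_time(double new_t) {
    double dt = new_t - t;
    cell_time_integral += n_total_cells * dt;
    crypt_time_integral += n_living_crypts * dt;
    t = new_t;
  }

  void run() {
    init();
    while (true) {
      // next event: scan the per-crypt cached minima
      double best = INF;
      int bs = -1, bc = -1;
      bool is_div = false;
      for (int s = 0; s < (int)crypts.size(); ++s) {
        const Crypt& c = crypts[s];
        if (c.min_time < best) {
          best = c.min_time; bs = s; bc = c.min_cell; is_div = c.min_is_div;
        }
      }
      if (!(best < p.max_days)) {       // includes best == INF (no living cells caught below)
        advance_time(p.max_days);
        endpoint = "censored";
        endpoint_time = p.max_days;
        return;
      }
      advance_time(best);
      Crypt& c = crypts[bs];
      if (is_div) {
        bool symmetric = rng.unif() * (1.0 + p.asym_to_sym_ratio) < 1.0;
        bool initiated = false;
        if (symmetric) {
          ++n_symmetric;
          Cell daughter = c.cells[bc];      // inherits full state
          c.cells[bc].id = next_id++;
          c.cells[bc].birth_time = t;
          daughter.id = next_id++;
          daughter.birth_time = t;
          c.cells.push_back(daughter);
          ++n_total_cells;
          log_event(0, bs, c.cells[bc].id, (int)c.cells.size(), -1,
                    c.cells[bc].tsg_hits);
          mutate(c.cells[bc], bs, initiated);
          if (initiated) { endpoint = "initiation"; endpoint_time = t; return; }
          mutate(c.cells.back(), bs, initiated);
          if (initiated) { endpoint = "initiation"; endpoint_time = t; return; }
          schedule_crypt(bs);               // population changed: all rates fresh
          if (enable_uncontrolled &&
              (double)c.cells.size() >= p.uncontrolled_threshold * p.crypt_size) {
            endpoint = "uncontrolled_proliferation"; endpoint_time = t; return;
          }
          try_bifurcate(bs);
        } else {
          ++n_asymmetric;
          log_event(1, bs, c.cells[bc].id, (int)c.cells.size(), -1,
                    c.cells[bc].tsg_hits);
          bool changed = mutate(c.cells[bc], bs, initiated);
          if (initiated) { endpoint = "initiation"; endpoint_time = t; return; }
          if (changed) {
            reschedule_one(bs, bc);         // genotype changed both clocks
          } else {
            // only the fired division clock is consumed; redraw it alone
            double df, lf;
            crypt_factors(c, df, lf);
            Cell& cell = c.cells[bc];
            double sym = p.base_division_rate * cell.fit_div * df;
            double td = rng.rexp(sym * (1.0 + p.asym_to_sym_ratio));
            cell.t_div = std::isfinite(td)
              ? t + std::max(td, p.division_min_time) : INF;
            update_crypt_min(bs);
          }
        }
      } else {
        ++n_losses;
        int64_t lost_id = c.cells[bc].id;
        int tsg_after = c.cells[bc].tsg_hits;
        c.cells[bc] = c.cells.back();
        c.cells.pop_back();
        --n_total_cells;
        log_event(2, bs, lost_id, (int)c.cells.size(), -1, tsg_after);
        if (c.cells.empty()) {
          mark_extinct(bs);
          if (n_total_cells == 0) {
            endpoint = "tissue_death"; endpoint_time = t; return;
          }
        } else {
          schedule_crypt(bs);
        }
      }
    }
  }
};

Params params_from_list(Rcpp::List pl) {
  Params p;
  p.max_days = Rcpp::as<double>(pl["max_days"]);
  p.base_division_rate = Rcpp::as<double>(pl["base_division_rate"]);
  p.asym_to_sym_ratio = Rcpp::as<double>(pl["asym_to_sym_ratio"]);
  p.base_loss_rate = Rcpp::as<double>(pl["base_loss_rate"]);
  p.mutation_rate = Rcpp::as<double>(pl["mutation_rate"]);
  p.mutation_rate_max = Rcpp::as<double>(pl["mutation_rate_max"]);
  p.tsg_mutation_rate = Rcpp::as<double>(pl["tsg_mutation_rate"]);
  p.tsg_mutation_rate_max = Rcpp::as<double>(pl["tsg_mutation_rate_max"]);
  p.mutator_factor = Rcpp::as<double>(pl["mutator_factor"]);
  p.division_min_time = Rcpp::as<double>(pl["division_min_time"]);
  p.loss_min_time = Rcpp::as<double>(pl["loss_min_time"]);
  p.ta_cells_per_stem = Rcpp::as<double>(pl["ta_cells_per_stem"]);
  p.crypt_size = Rcpp::as<int>(pl["crypt_size"]);
  p.crypt_deviation = Rcpp::as<double>(pl["crypt_deviation"]);
  p.bifurcation_factor = Rcpp::as<double>(pl["bifurcation_factor"]);
  p.loss_effect_base = Rcpp::as<double>(pl["loss_effect_base"]);
  p.division_effect_base = Rcpp::as<double>(pl["division_effect_base"]);
  p.dead_neighbor_division_multiplier =
    Rcpp::as<double>(pl["dead_neighbor_division_multiplier"]);
  p.uncontrolled_threshold = Rcpp::as<double>(pl["uncontrolled_threshold"]);
  p.tsg_hits_for_initiation = Rcpp::as<int>(pl["tsg_hits_for_initiation"]);
  p.deleterious_fraction = Rcpp::as<double>(pl["deleterious_fraction"]);
  Rcpp::NumericVector bs = pl["beneficial_split"];
  p.ben_div = bs[0]; p.ben_surv = bs[1]; p.ben_mutator = bs[2];
  Rcpp::NumericVector ds = pl["deleterious_split"];
  p.del_div = ds[0]; p.del_surv = ds[1];
  p.fitness_factor = Rcpp::as<double>(pl["fitness_factor"]);
  p.grid_rows = Rcpp::as<int>(pl["grid_rows"]);
  p.grid_cols = Rcpp::as<int>(pl["grid_cols"]);
  return p;
}

const char* KIND_NAMES[4] = {"symmetric_division", "asymmetric_division",
                             "cell_loss", "mutation"};
const char* MUT_NAMES[6] = {"deleterious_div", "deleterious_surv",
                            "beneficial_div", "beneficial_surv",
                            "mutator", "tsg_hit"};

} // namespace

// [[Rcpp::export(name = ".run_engine")]]
Rcpp::List run_engine(Rcpp::List params, double seed,
                      bool record_events, bool enable_uncontrolled) {
  Params p = params_from_list(params);
  Engine eng(p, (uint64_t)seed, record_events, enable_uncontrolled);
  eng.run();

  int nslot = p.grid_rows * p.grid_cols;
  Rcpp::IntegerVector sq(nslot), sr(nslot), sn(nslot), smut(nslot),
    s_bd(nslot), s_bs(nslot), s_dd(nslot), s_ds(nslot), s_tsg(nslot);
  Rcpp::LogicalVector salive(nslot);
  Rcpp::NumericVector screated(nslot), sextinct(nslot),
    s_fit_div(nslot), s_fit_loss(nslot);
  for (int s = 0; s < nslot; ++s) {
    const Crypt& c = eng.crypts[s];
    sq[s] = eng.q_of(s); sr[s] = eng.r_of(s);
    salive[s] = c.alive;
    sn[s] = (int)c.cells.size();
    screated[s] = c.created_time;
    sextinct[s] = c.alive ? NA_REAL : c.extinct_time;
    int nm = 0, bd = 0, bsv = 0, dd = 0, dsv = 0, mt = 0;
    double fd = 0.0, fl = 0.0;
    for (const Cell& cell : c.cells) {
      if (cell.is_mutator) ++nm;
      bd += cell.n_ben_div; bsv += cell.n_ben_surv;
      dd += cell.n_del_div; dsv += cell.n_del_surv;
      mt = std::max(mt, cell.tsg_hits);
      fd += cell.fit_div; fl += cell.fit_loss;
    }
    smut[s] = nm; s_bd[s] = bd; s_bs[s] = bsv; s_dd[s] = dd; s_ds[s] = dsv;
    s_tsg[s] = mt;
    s_fit_div[s] = c.cells.empty() ? NA_REAL : fd / c.cells.size();
    s_fit_loss[s] = c.cells.empty() ? NA_REAL : fl / c.cells.size();
  }
  Rcpp::DataFrame snapshot = Rcpp::DataFrame::create(
    Rcpp::Named("q") = sq, Rcpp::Named("r") = sr,
    Rcpp::Named("alive") = salive, Rcpp::Named("n_cells") = sn,
    Rcpp::Named("n_mutator") = smut,
    Rcpp::Named("created_time") = screated,
    Rcpp::Named("extinct_time") = sextinct,
    Rcpp::Named("n_beneficial_div") = s_bd,
    Rcpp::Named("n_beneficial_surv") = s_bs,
    Rcpp::Named("n_deleterious_div") = s_dd,
    Rcpp::Named("n_deleterious_surv") = s_ds,
    Rcpp::Named("max_tsg_hits") = s_tsg,
    Rcpp::Named("mean_div_fitness") = s_fit_div,
    Rcpp::Named("mean_loss_fitness") = s_fit_loss);

  int nt = (int)eng.turnover.size();
  Rcpp::CharacterVector tev(nt);
  Rcpp::NumericVector ttime(nt), tlife(nt);
  Rcpp::IntegerVector tq(nt), tr(nt), tpq(nt), tpr(nt);
  for (int i = 0; i < nt; ++i) {
    const TurnoverRec& rec = eng.turnover[i];
    tev[i] = rec.kind == 0 ? "crypt_birth" : "crypt_death";
    ttime[i] = rec.time; tq[i] = rec.q; tr[i] = rec.r;
    tpq[i] = rec.kind == 0 ? rec.parent_q : NA_INTEGER;
    tpr[i] = rec.kind == 0 ? rec.parent_r : NA_INTEGER;
    tlife[i] = rec.kind == 1 ? rec.lifespan : NA_REAL;
  }
  Rcpp::DataFrame turn = Rcpp::DataFrame::create(
    Rcpp::Named("event") = tev, Rcpp::Named("time") = ttime,
    Rcpp::Named("q") = tq, Rcpp::Named("r") = tr,
    Rcpp::Named("parent_q") = tpq, Rcpp::Named("parent_r") = tpr,
    Rcpp::Named("lifespan") = tlife,
    Rcpp::Named("stringsAsFactors") = false);

  Rcpp::RObject events = R_NilValue;
  if (record_events) {
    int ne = (int)eng.events.size();
    Rcpp::NumericVector et(ne), ecid(ne);
    Rcpp::CharacterVector ek(ne), ecat(ne);
    Rcpp::IntegerVector eq(ne), er(ne), en(ne), etsg(ne);
    for (int i = 0; i < ne; ++i) {
      const EventRec& rec = eng.events[i];
      et[i] = rec.time;
      ek[i] = KIND_NAMES[rec.kind];
      eq[i] = rec.q; er[i] = rec.r;
      ecid[i] = (double)rec.cell_id;
      en[i] = rec.n_cells_after;
      if (rec.mut_category >= 0) ecat[i] = MUT_NAMES[rec.mut_category];
      else ecat[i] = "-";
      etsg[i] = rec.tsg_hits_after;
    }
    events = Rcpp::DataFrame::create(
      Rcpp::Named("time") = et, Rcpp::Named("event_kind") = ek,
      Rcpp::Named("q") = eq, Rcpp::Named("r") = er,
      Rcpp::Named("cell_id") = ecid, Rcpp::Named("n_cells_after") = en,
      Rcpp::Named("mutation_category") = ecat,
      Rcpp::Named("tsg_hits_after") = etsg,
      Rcpp::Named("stringsAsFactors") = false);
  }

  Rcpp::NumericVector mc(6);
  Rcpp::CharacterVector mcn(6);
  for (int i = 0; i < 6; ++i) { mc[i] = (double)eng.mut_counts[i]; mcn[i] = MUT_NAMES[i]; }
  mc.names() = mcn;

  return Rcpp::List::create(
    Rcpp::Named("endpoint") = eng.endpoint,
    Rcpp::Named("endpoint_time") = eng.endpoint_time,
    Rcpp::Named("initiating_cell_was_mutator") =
      eng.initiating_was_mutator == NA_INTEGER ? Rcpp::LogicalVector(1, NA_LOGICAL)
        : Rcpp::LogicalVector(1, eng.initiating_was_mutator == 1),
    Rcpp::Named("n_symmetric_divisions") = (double)eng.n_symmetric,
    Rcpp::Named("n_asymmetric_divisions") = (double)eng.n_asymmetric,
    Rcpp::Named("n_losses") = (double)eng.n_losses,
    Rcpp::Named("mutation_counts") = mc,
    Rcpp::Named("cell_time_integral") = eng.cell_time_integral,
    Rcpp::Named("crypt_time_integral") = eng.crypt_time_integral,
    Rcpp::Named("n_living_crypts") = eng.n_living_crypts,
    Rcpp::Named("n_living_cells") = eng.n_total_cells,
    Rcpp::Named("snapshot") = snapshot,
    Rcpp::Named("turnover") = turn,
    Rcpp::Named("events") = events);
}
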