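#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Discrete-time engine for filament growth and rule-based fragmentation.
//
// State is a set of parallel arrays over cells (pole ages, compound,
// next-division time) and connections (age). All randomness comes from R's
// RNG so runs are reproducible from set.seed(), and the draw order is a
// strict contract mirrored by the pure-R reference engine used in tests:
//
//   per step: (1) ages += dt; (2) compound production + diffusion;
//   (3) divisions due at this step boundary, left to right, each drawing
//   the left daughter's division interval then the right daughter's;
//   division-driven cues (mechanical stress, at-division breakage) are
//   re-evaluated after every single division — they can only newly fire
//   when a division changes the filament — and a firing ends the step's
//   division processing (remaining due cells divide next step);
//   (4) time-driven cues (cell age, connection age, compound, per-step
//   stochastic breakage, Boolean combinations) are evaluated once on the
//   fresh end-of-step state, scanning cells/connections left to right with
//   one uniform per severing-policy tie, then one uniform per broken
//   connection for death on connection-level cues; (5) on a tie for
//   largest daughter, one uniform.

enum Cue { CELL_AGE = 0, CONN_AGE = 1, COMPOUND = 2, STRESS = 3,
           STOCH_DIV = 4, STOCH_TIME = 5 };
enum Logic { SINGLE = 0, LOGIC_AND = 1, LOGIC_OR = 2 };

struct Decision {
  std::vector<char> sever, kill;
  bool any = false;
  void init(int n) {
    sever.assign(std::max(n - 1, 0), 0);
    kill.assign(n, 0);
    any = false;
  }
  void mark_sever(int j) { if (j >= 0) { sever[j] = 1; any = true; } }
  void mark_kill(int i) { kill[i] = 1; any = true; }
};

struct Engine {
  // state
  std::vector<double> pole_l, pole_r, comp, next_div, conn_age;
  // config
  int cue1, cue2, logic;
  double theta1, theta2;
  bool death, aging, count_shedding;
  double dt, division_mean, division_sd, D, production;
  int n_events, max_cells;
  double max_steps;
  // log
  std::vector<double> ev_time;
  std::vector<int> ev_parent, off_len, off_sizes;
  int n_shed = 0, n_extinct = 0;
  double steps = 0;

  int n() const { return (int)pole_l.size(); }

  double trunc_norm() {
    double x;
    do { x = R::rnorm(division_mean, division_sd); } while (x < dt);
    return x;
  }

  void init_founder(double t) {
    pole_l.assign(1, 0.0); pole_r.assign(1, 0.0);
    comp.assign(1, 0.0);
    next_div.assign(1, t + trunc_norm());
    conn_age.clear();
    // (aging adds the founder's age, which is 0)
  }

  double cue_value(int cue, int i) const {
    switch (cue) {
      case CELL_AGE: return (pole_l[i] + pole_r[i]) / 2.0;
      case COMPOUND: return comp[i];
      case STRESS:   return (double)std::min(i, n() - 1 - i);
    }
    return 0.0;
  }

  // which connection (0-based) cell i severs under a cell-level cue;
  // -1 for a singleton; one uniform on an exact tie
  int severing_policy(int cue, int i) {
    int m = n();
    if (m == 1) return -1;
    if (i == 0) return 0;
    if (i == m - 1) return m - 2;
    double lv, rv;
    switch (cue) {
      case CELL_AGE: lv = conn_age[i - 1]; rv = conn_age[i]; break;
      case COMPOUND: lv = comp[i - 1];     rv = comp[i + 1]; break;
      default:       lv = (double)i;       rv = (double)(m - 1 - i); break;
    }
    if (lv > rv) return i - 1;
    if (rv > lv) return i;
    return (unif_rand() < 0.5) ? i - 1 : i;
  }

  void eval_cell_level(int cue, double theta, bool kill_trigger,
                       const std::vector<char> *skip, Decision &d) {
    int m = n();
    for (int i = 0; i < m; ++i) {
      if (skip && (*skip)[i]) continue;
      if (cue_value(cue, i) > theta) {
        if (kill_trigger) d.mark_kill(i);
        else d.mark_sever(severing_policy(cue, i));
      }
    }
  }

  // one flanking cell per broken connection, fair coin, increasing order
  void kill_adjacent(Decision &d) {
    for (size_t j = 0; j < d.sever.size(); ++j) {
      if (d.sever[j])
        d.mark_kill((unif_rand() < 0.5) ? (int)j : (int)j + 1);
    }
  }

  // evaluation of the time-driven cues on the end-of-step state
  void eval_time_driven(Decision &d) {
    int m = n();
    d.init(m);
    if (logic == SINGLE) {
      if (cue1 == CONN_AGE || cue1 == STOCH_TIME) {
        for (int j = 0; j < m - 1; ++j) {
          bool hit = (cue1 == CONN_AGE) ? (conn_age[j] > theta1)
                                        : (unif_rand() < theta1);
          if (hit) d.mark_sever(j);
        }
        if (d.any && death) kill_adjacent(d);
      } else {
        eval_cell_level(cue1, theta1, death, NULL, d);
      }
    } else if (logic == LOGIC_AND) {
      for (int i = 0; i < m; ++i) {
        if (cue_value(cue1, i) > theta1 && cue_value(cue2, i) > theta2)
          d.mark_sever(severing_policy(cue1, i));
      }
    } else {  // OR: rule1's policy wins for cells satisfying both
      if (cue1 == CONN_AGE) {
        for (int j = 0; j < m - 1; ++j)
          if (conn_age[j] > theta1) d.mark_sever(j);
      } else {
        eval_cell_level(cue1, theta1, false, NULL, d);
      }
      if (cue2 == CONN_AGE) {
        for (int j = 0; j < m - 1; ++j)
          if (conn_age[j] > theta2) d.mark_sever(j);
      } else {
        std::vector<char> skip_mask;
        const std::vector<char> *skip = NULL;
        if (cue1 != CONN_AGE) {
          skip_mask.assign(m, 0);
          for (int i = 0; i < m; ++i)
            if (cue_value(cue1, i) > theta1) skip_mask[i] = 1;
          skip = &skip_mask;
        }
        eval_cell_level(cue2, theta2, false, skip, d);
      }
    }
  }

  // apply a nonempty decision; log an event if >= 2 viable offspring;
  // continue with the largest viable fragment (or a fresh founder after
  // an extinction)
  void apply_decision(const Decision &d, double t) {
    int m = n();
    std::vector<char> cut(std::max(m - 1, 0), 0);
    for (int j = 0; j < m - 1; ++j)
      cut[j] = d.sever[j] || d.kill[j] || d.kill[j + 1];
    std::vector<int> frag_start, frag_end;  // inclusive cell ranges
    int start = 0;
    for (int i = 0; i < m; ++i) {
      if (d.kill[i]) {
        if (i - 1 >= start) { frag_start.push_back(start); frag_end.push_back(i - 1); }
        start = i + 1;
      } else if (i < m - 1 && cut[i]) {
        frag_start.push_back(start); frag_end.push_back(i);
        start = i + 1;
      }
    }
    if (m - 1 >= start) { frag_start.push_back(start); frag_end.push_back(m - 1); }

    int n_frag = (int)frag_start.size();
    int keep;
    if (n_frag >= 2) {
      ev_time.push_back(t);
      ev_parent.push_back(m);
      off_len.push_back(n_frag);
      int best = 0;
      std::vector<int> tied;
      for (int f = 0; f < n_frag; ++f) {
        int sz = frag_end[f] - frag_start[f] + 1;
        off_sizes.push_back(sz);
        if (sz > best) { best = sz; tied.clear(); tied.push_back(f); }
        else if (sz == best) tied.push_back(f);
      }
      if (tied.size() == 1) keep = tied[0];
      else {
        double u = unif_rand();
        int idx = (int)(u * (double)tied.size());
        if (idx >= (int)tied.size()) idx = (int)tied.size() - 1;
        keep = tied[idx];
      }
    } else if (n_frag == 1) {
      // shedding: a dead cell dropped off, one viable fragment remains
      ++n_shed;
      keep = 0;
      if (count_shedding) {
        ev_time.push_back(t);
        ev_parent.push_back(m);
        off_len.push_back(1);
        off_sizes.push_back(frag_end[0] - frag_start[0] + 1);
      }
    } else {
      ++n_extinct;
      init_founder(t);
      return;
    }

    int a = frag_start[keep], b = frag_end[keep];
    pole_l = std::vector<double>(pole_l.begin() + a, pole_l.begin() + b + 1);
    pole_r = std::vector<double>(pole_r.begin() + a, pole_r.begin() + b + 1);
    comp = std::vector<double>(comp.begin() + a, comp.begin() + b + 1);
    next_div = std::vector<double>(next_div.begin() + a, next_div.begin() + b + 1);
    if (b > a)
      conn_age = std::vector<double>(conn_age.begin() + a, conn_age.begin() + b);
    else
      conn_age.clear();
  }

  List run() {
    init_founder(0.0);
    bool division_driven =
      (logic == SINGLE && (cue1 == STRESS || cue1 == STOCH_DIV));
    std::vector<double> tmp;

    while ((int)ev_time.size() < n_events) {
      steps += 1;
      if (steps > max_steps)
        stop("rule never produced %d fragmentation events within the step "
             "budget; threshold may be unreachable", n_events);
      double t = steps * dt;
      int m = n();
      if (m > max_cells)
        stop("filament exceeded %d cells without fragmenting; threshold "
             "may be unreachable", max_cells);

      // (1) ages
      for (int i = 0; i < m; ++i) { pole_l[i] += dt; pole_r[i] += dt; }
      for (size_t j = 0; j < conn_age.size(); ++j) conn_age[j] += dt;

      // (2) compound production + diffusion (explicit Euler, zero-
      // concentration environment beyond both ends)
      tmp.resize(m);
      for (int i = 0; i < m; ++i) {
        double left = (i > 0) ? comp[i - 1] : 0.0;
        double right = (i < m - 1) ? comp[i + 1] : 0.0;
        double v = (comp[i] + production) +
                   D * ((left + right) - 2.0 * comp[i]);
        tmp[i] = (v > 0.0) ? v : 0.0;
      }
      comp.swap(tmp);

      // (3) divisions due at this step boundary, left to right
      std::vector<int> due;
      for (int i = 0; i < m; ++i)
        if (next_div[i] <= t) due.push_back(i);
      bool fired = false;
      for (size_t k = 0; k < due.size() && !fired; ++k) {
        int i = due[k] + (int)k;  // earlier divisions shifted us right
        double pl = pole_l[i], pr = pole_r[i];
        double half = comp[i] / 2.0;
        double t_left = t + trunc_norm() + (aging ? pl / 2.0 : 0.0);
        double t_right = t + trunc_norm() + (aging ? pr / 2.0 : 0.0);
        // left daughter replaces the parent in place
        pole_l[i] = pl; pole_r[i] = 0.0;
        comp[i] = half; next_div[i] = t_left;
        pole_l.insert(pole_l.begin() + i + 1, 0.0);
        pole_r.insert(pole_r.begin() + i + 1, pr);
        comp.insert(comp.begin() + i + 1, half);
        next_div.insert(next_div.begin() + i + 1, t_right);
        conn_age.insert(conn_age.begin() + i, 0.0);
        if (!division_driven) continue;
        Decision d;
        if (cue1 == STOCH_DIV) {
          // the new connection is tested once, at creation
          d.init(n());
          if (unif_rand() < theta1) {
            d.mark_sever(i);
            if (death) kill_adjacent(d);
          }
        } else {  // stress: profile only changes when a division happens
          d.init(n());
          eval_cell_level(STRESS, theta1, death, NULL, d);
        }
        if (d.any) {
          apply_decision(d, t);
          fired = true;  // remaining due cells divide next step
        }
      }
      if (fired || division_driven) continue;

      // (4) time-driven rule evaluation on the end-of-step state
      Decision d;
      eval_time_driven(d);
      if (d.any) apply_decision(d, t);
    }

    return List::create(
      _["time"] = NumericVector(ev_time.begin(), ev_time.end()),
      _["parent_size"] = IntegerVector(ev_parent.begin(), ev_parent.end()),
      _["n_offspring"] = IntegerVector(off_len.begin(), off_len.end()),
      _["offspring_concat"] = IntegerVector(off_sizes.begin(), off_sizes.end()),
      _["n_shed"] = n_shed,
      _["n_extinct"] = n_extinct,
      _["n_steps"] = steps
    );
  }
};

// [[Rcpp::export]]
List run_engine_cpp(int cue1, double theta1, int cue2, double theta2,
                    int logic, bool death, bool aging,
                    double dt, double division_mean, double division_sd,
                    double D, double production,
                    int n_events, bool count_shedding,
                    int max_cells, double max_steps) {
  Engine e;
  e.cue1 = cue1; e.theta1 = theta1; e.cue2 = cue2; e.theta2 = theta2;
  e.logic = logic; e.death = death; e.aging = aging;
  e.dt = dt; e.division_mean = division_mean; e.division_sd = division_sd;
  e.D = D; e.production = production;
  e.n_events = n_events; e.count_shedding = count_shedding;
  e.max_cells = max_cells; e.max_steps = max_steps;
  return e.run();
}
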