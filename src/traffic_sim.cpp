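// Exact continuous-time kinetic Monte Carlo core for the multi-lane TASEP-LK
// with hard-core exclusion, an interaction range, and elevated detachment of
// constrained (blocked) motors.
//
// The chain is simulated by thinning: every bound motor carries the rate
// bound b = step_rate + max(omega_D, omega_DC) and every candidate binding
// position the rate ka_site, so each attempted event costs O(1) regardless of
// occupancy. Rejected attempts advance time only, which leaves the law of the
// process unchanged.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

static inline int oidx(int lane, int site, int L) { return lane * L + site; }

struct Motor {
  int lane;
  int front;       // plus-end-most occupied site (wrapped on rings)
  double bind_time;
  int bind_site;   // front site at binding; unwrapped anchor for displacement
  long steps;      // steps taken since binding
};

// 0 = blocked (constrained), 1 = can step, 2 = step exits the open lattice.
// Stepping requires the target site empty and, after the step, a gap of at
// least interaction_range motor sizes (= irange * footprint sites) to the
// motor ahead. Sites beyond the plus end of an open lattice count as empty.
static int step_kind(const std::vector<int> &occ, int lane, int front,
                     int L, int footprint, int irange, bool ring) {
  if (!ring && front == L - 1) return 2;
  const int need = 1 + irange * footprint;
  for (int j = 1; j <= need; ++j) {
    int s = front + j;
    if (ring) {
      s %= L;
    } else if (s >= L) {
      break;
    }
    if (occ[oidx(lane, s, L)] != -1) return 0;
  }
  return 1;
}

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(int L, int n_lanes, int footprint, double step_rate,
              double ka_site, double omega_D, double omega_DC,
              int interaction_range, bool ring, bool langmuir,
              int n_init, double duration, double burn_in,
              NumericVector snapshot_times, int n_batches) {
  if (L < footprint) stop("lattice shorter than one motor footprint");
  if (ring && 1 + interaction_range * footprint > L - footprint)
    stop("interaction range does not fit on this ring");

  std::vector<int> occ((size_t)n_lanes * L, -1);
  std::vector<Motor> motors;          // indexed by motor id (never shrinks)
  std::vector<int> active;            // ids of bound motors
  std::vector<int> slot_of;           // id -> position in `active` (-1 if gone)

  // run records
  std::vector<int> r_lane, r_bind_site, r_unbind_site;
  std::vector<double> r_bind_t, r_unbind_t;
  std::vector<int> r_cens;

  // snapshots (front sites)
  std::vector<double> s_time;
  std::vector<int> s_lane, s_site, s_id;

  const double det_max = std::max(omega_D, omega_DC);
  const double b = step_rate + (langmuir ? det_max : 0.0);
  const double attach_tot = langmuir ? ka_site * (double)L * n_lanes : 0.0;

  // batch accumulators over [burn_in, duration]
  const int B = std::max(1, n_batches);
  const double span = duration - burn_in;
  const double bdur = span / B;
  std::vector<double> bat_mtime(B, 0.0);
  std::vector<double> bat_steps(B, 0.0);
  double motor_time = 0.0;   // sum of N * dt after burn-in
  double steps_post = 0.0;   // steps after burn-in
  long n_attach = 0, n_events = 0, n_attempts = 0;

  // initial motors at random non-overlapping positions
  if (n_init > 0) {
    long tries = 0;
    int placed = 0;
    while (placed < n_init) {
      if (++tries > 1000L * n_init + 10000L)
        stop("could not place %d initial motors on %d lanes x %d sites",
             n_init, n_lanes, L);
      int lane = (int)std::floor(R::unif_rand() * n_lanes);
      if (lane >= n_lanes) lane = n_lanes - 1;
      int rear = (int)std::floor(R::unif_rand() * L);
      if (rear >= L) rear = L - 1;
      if (!ring && rear + footprint - 1 >= L) continue;
      bool free = true;
      for (int j = 0; j < footprint && free; ++j) {
        int s = rear + j;
        if (ring) s %= L;
        if (occ[oidx(lane, s, L)] != -1) free = false;
      }
      if (!free) continue;
      Motor m;
      m.lane = lane;
      m.front = ring ? (rear + footprint - 1) % L : rear + footprint - 1;
      m.bind_time = 0.0;
      m.bind_site = m.front;
      m.steps = 0;
      int id = (int)motors.size();
      motors.push_back(m);
      slot_of.push_back((int)active.size());
      active.push_back(id);
      for (int j = 0; j < footprint; ++j) {
        int s = rear + j;
        if (ring) s %= L;
        occ[oidx(lane, s, L)] = id;
      }
      ++placed;
    }
  }

  // helper lambdas ----------------------------------------------------------
  auto accumulate = [&](double a, double bb, int N) {
    // N motors bound on [a, bb); add post-burn-in motor-time, split by batch
    if (N <= 0) return;
    double lo = std::max(a, burn_in);
    double hi = std::min(bb, duration);
    if (hi <= lo) return;
    motor_time += N * (hi - lo);
    if (span <= 0) return;
    double x = lo;
    while (x < hi) {
      int k = (int)std::floor((x - burn_in) / bdur);
      if (k >= B) k = B - 1;
      double edge = burn_in + (k + 1) * bdur;
      double seg = std::min(hi, edge) - x;
      bat_mtime[k] += N * seg;
      x += seg;
      if (seg <= 0) break;  // numeric guard
    }
  };
  auto count_step = [&](double t) {
    if (t < burn_in || span <= 0) return;
    steps_post += 1.0;
    int k = (int)std::floor((t - burn_in) / bdur);
    if (k >= B) k = B - 1;
    if (k < 0) k = 0;
    bat_steps[k] += 1.0;
  };
  auto clear_footprint = [&](const Motor &m) {
    for (int j = 0; j < footprint; ++j) {
      int s = m.front - j;
      if (ring) s = ((s % L) + L) % L;
      occ[oidx(m.lane, s, L)] = -1;
    }
  };
  auto remove_active = [&](int id) {
    int sl = slot_of[id];
    int last = active.back();
    active[sl] = last;
    slot_of[last] = sl;
    active.pop_back();
    slot_of[id] = -1;
  };
  auto record_run = [&](const Motor &m, double t, bool censored) {
    r_lane.push_back(m.lane + 1);          // 1-based for R
    r_bind_t.push_back(m.bind_time);
    r_unbind_t.push_back(t);
    r_bind_site.push_back(m.bind_site + 1);
    r_unbind_site.push_back((int)(m.bind_site + m.steps) + 1);
    r_cens.push_back(censored ? 1 : 0);
  };

  // main loop ---------------------------------------------------------------
  double t = 0.0;
  R_xlen_t snap_i = 0;
  const R_xlen_t n_snap = snapshot_times.size();
  long iter = 0;
  while (true) {
    if ((++iter & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    double Rb = attach_tot + (double)active.size() * b;
    double t_next = (Rb > 0) ? t + R::exp_rand() / Rb : duration;
    double t_stop = std::min(t_next, duration);

    while (snap_i < n_snap && snapshot_times[snap_i] <= t_stop) {
      double ts = snapshot_times[snap_i++];
      for (int id : active) {
        s_time.push_back(ts);
        s_lane.push_back(motors[id].lane + 1);
        s_site.push_back(motors[id].front + 1);
        s_id.push_back(id + 1);
      }
    }
    accumulate(t, t_stop, (int)active.size());
    if (t_next >= duration || Rb <= 0) { t = duration; break; }
    t = t_next;
    ++n_attempts;

    double u = R::unif_rand() * Rb;
    if (u < attach_tot) {
      // attachment attempt at a uniform (lane, rear-site) candidate
      long idx = (long)std::floor(u / ka_site);
      long ncand = (long)n_lanes * L;
      if (idx >= ncand) idx = ncand - 1;
      int lane = (int)(idx / L);
      int rear = (int)(idx % L);
      if (!ring && rear + footprint - 1 >= L) continue;  // footprint overflow
      bool free = true;
      for (int j = 0; j < footprint && free; ++j) {
        int s = rear + j;
        if (ring) s %= L;
        if (occ[oidx(lane, s, L)] != -1) free = false;
      }
      if (!free) continue;  // rejected attempt (site blocked)
      Motor m;
      m.lane = lane;
      m.front = ring ? (rear + footprint - 1) % L : rear + footprint - 1;
      m.bind_time = t;
      m.bind_site = m.front;
      m.steps = 0;
      int id = (int)motors.size();
      motors.push_back(m);
      slot_of.push_back((int)active.size());
      active.push_back(id);
      for (int j = 0; j < footprint; ++j) {
        int s = rear + j;
        if (ring) s %= L;
        occ[oidx(lane, s, L)] = id;
      }
      ++n_attach; ++n_events;
    } else {
      double w = u - attach_tot;
      int sl = (int)std::floor(w / b);
      if (sl >= (int)active.size()) sl = (int)active.size() - 1;
      double wm = w - (double)sl * b;
      int id = active[sl];
      Motor &m = motors[id];
      int kind = step_kind(occ, m.lane, m.front, L, footprint,
                           interaction_range, ring);
      double r_step = (kind != 0) ? step_rate : 0.0;
      double r_det = langmuir ? ((kind == 0) ? omega_DC : omega_D) : 0.0;
      if (wm < r_step) {
        ++n_events;
        if (kind == 2) {
          // front leaves the open lattice: whole motor exits, run censored
          m.steps += 1;
          count_step(t);
          // footprint still occupies sites front-footprint+1 .. front
          for (int j = 0; j < footprint; ++j)
            occ[oidx(m.lane, m.front - j, L)] = -1;
          record_run(m, t, true);
          remove_active(id);
        } else {
          int newf = m.front + 1;
          int rear = m.front - footprint + 1;
          if (ring) {
            newf %= L;
            rear = ((rear % L) + L) % L;
          }
          occ[oidx(m.lane, newf, L)] = id;
          occ[oidx(m.lane, rear, L)] = -1;
          m.front = newf;
          m.steps += 1;
          count_step(t);
        }
      } else if (wm < r_step + r_det) {
        ++n_events;
        clear_footprint(m);
        record_run(m, t, false);
        remove_active(id);
      }
      // else: rejected attempt, no state change
    }
  }

  // close out still-bound motors as censored runs at `duration`
  for (int id : active) record_run(motors[id], duration, true);

  return List::create(
      _["runs"] = DataFrame::create(
          _["lane"] = IntegerVector(r_lane.begin(), r_lane.end()),
          _["bind_time_s"] = NumericVector(r_bind_t.begin(), r_bind_t.end()),
          _["unbind_time_s"] = NumericVector(r_unbind_t.begin(), r_unbind_t.end()),
          _["bind_site"] = IntegerVector(r_bind_site.begin(), r_bind_site.end()),
          _["unbind_site"] = IntegerVector(r_unbind_site.begin(), r_unbind_site.end()),
          _["censored"] = LogicalVector(r_cens.begin(), r_cens.end())),
      _["snapshots"] = DataFrame::create(
          _["time_s"] = NumericVector(s_time.begin(), s_time.end()),
          _["lane"] = IntegerVector(s_lane.begin(), s_lane.end()),
          _["site"] = IntegerVector(s_site.begin(), s_site.end()),
          _["motor"] = IntegerVector(s_id.begin(), s_id.end())),
      _["stats"] = List::create(
          _["motor_time_s"] = motor_time,
          _["steps_post"] = steps_post,
          _["batch_motor_time_s"] = NumericVector(bat_mtime.begin(), bat_mtime.end()),
          _["batch_steps"] = NumericVector(bat_steps.begin(), bat_steps.end()),
          _["batch_duration_s"] = bdur,
          _["n_attach"] = (double)n_attach,
          _["n_events"] = (double)n_events,
          _["n_attempts"] = (double)n_attempts));
}
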