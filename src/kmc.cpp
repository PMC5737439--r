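// Event-driven kinetic Monte Carlo for motors translocating through
// dynamically rebinding roadblocks on a 1D lattice.
//
// Conventions (match the R-level rule functions):
//  * positions are 0-based leftmost occupied sites; a particle of footprint w
//    covers [p, p+w-1]; the motor "front" is p + delta_m - 1.
//  * uniform interaction: a motor steps at k_tp into any intact-roadblock-
//    covered site, evicting the roadblock on first footprint contact.
//    evict_mode 0 ("contact", Bus-Route-Model convention): the motor is fast
//    again immediately after the evicting step. evict_mode 1 ("traversal",
//    transcription convention): the evicting motor keeps a crossing memory -
//    it steps at k_tp until its front has traversed the remaining footprint
//    length (slow_left counter), so it crosses the nucleosome region at
//    exactly k_tp while followers behind it draft at k_ip. State transitions
//    are identical in modes 0 and 1; only waiting times differ.
//  * dyad interaction (evict_mode 2): only the roadblock's dyad site
//    (leftmost + floor(drb/2)) impedes, with the renormalized rate k_dyad;
//    stepping onto the dyad evicts.
//  * roadblock binding is realized by exact thinning: candidate leftmost
//    positions fire at k_b each; a proposal is accepted iff the full footprint
//    is free of motors and roadblocks (open mode: and clear of the initiation
//    footprint [0, delta_m-1]).
//  * open mode: initiation at k_in when [0, delta_m-1] is motor-free; a step
//    that would carry the front past L-1 removes the motor (rate k_ip).
#include <Rcpp.h>
#include <deque>
#include <set>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export]]
List run_kmc(int delta_m, int delta_rb, double k_ip, double k_tp, double k_dyad,
             double k_in, double k_b, int L, bool open_boundary, int evict_mode,
             IntegerVector motors0, IntegerVector rbs0,
             double t_max, double dt_sample, double burn_in,
             bool record_events, bool record_site_stats, double max_events) {
  const int dyad_off = delta_rb / 2;
  const bool dyad_mode = evict_mode == 2;

  std::vector<int> rb_cover(L, -1);   // site -> leftmost of covering roadblock
  std::vector<char> mot_cover(L, 0);
  std::vector<double> rb_since(L, 0.0);
  std::set<int> rb_set;

  std::deque<int> mot;                // ascending cyclic order; back = leading
  std::deque<int> slow_left;          // remaining hindered steps (traversal mode)
  std::deque<double> rate, since;

  auto md = [&](int x) { x %= L; if (x < 0) x += L; return x; };
  auto dyad_site = [&](int q) { return open_boundary ? q + dyad_off : md(q + dyad_off); };

  for (int j = 0; j < rbs0.size(); ++j) {
    int q = rbs0[j];
    for (int k = 0; k < delta_rb; ++k) rb_cover[open_boundary ? q + k : md(q + k)] = q;
    rb_set.insert(q);
  }
  {
    std::vector<int> m0(motors0.begin(), motors0.end());
    std::sort(m0.begin(), m0.end());
    for (size_t j = 0; j < m0.size(); ++j) {
      int p = m0[j];
      for (int k = 0; k < delta_m; ++k) mot_cover[open_boundary ? p + k : md(p + k)] = 1;
      mot.push_back(p);
      rate.push_back(0.0);
      since.push_back(0.0);
      slow_left.push_back(0);
    }
  }

  auto compute_rate = [&](int i) -> double {
    int p = mot[i];
    int nxt = p + delta_m;              // site the front would newly occupy
    if (open_boundary && nxt > L - 1)   // exit step
      return (evict_mode == 1 && slow_left[i] > 0) ? k_tp : k_ip;
    int s = open_boundary ? nxt : md(nxt);
    if (mot_cover[s]) return 0.0;       // steric block by motor ahead
    int q = rb_cover[s];
    if (q < 0) {
      return (evict_mode == 1 && slow_left[i] > 0) ? k_tp : k_ip;
    }
    if (!dyad_mode) return k_tp;
    return (s == dyad_site(q)) ? k_dyad : k_ip;
  };
  for (size_t i = 0; i < mot.size(); ++i) rate[i] = compute_rate((int)i);

  // accumulators (post burn-in)
  std::vector<double> motor_time(L, 0.0), rb_time(L, 0.0), front_time(L, 0.0);
  std::vector<double> steps_from(L, 0.0);

  auto flush_motor = [&](int i, double t) {
    double t0 = std::max(since[i], burn_in);
    if (record_site_stats && t > t0) {
      double d = t - t0;
      int p = mot[i];
      for (int k = 0; k < delta_m; ++k)
        motor_time[open_boundary ? p + k : md(p + k)] += d;
      front_time[open_boundary ? p + delta_m - 1 : md(p + delta_m - 1)] += d;
    }
    since[i] = t;
  };
  auto flush_rb = [&](int q, double t) {
    double t0 = std::max(rb_since[q], burn_in);
    if (record_site_stats && t > t0) {
      double d = t - t0;
      for (int k = 0; k < delta_rb; ++k)
        rb_time[open_boundary ? q + k : md(q + k)] += d;
    }
  };
  auto remove_rb = [&](int q, double t) {
    flush_rb(q, t);
    for (int k = 0; k < delta_rb; ++k) rb_cover[open_boundary ? q + k : md(q + k)] = -1;
    rb_set.erase(q);
  };

  // outputs
  std::vector<double> ev_time;
  std::vector<int> ev_kind, ev_pos;   // 1 step, 2 initiate, 3 terminate, 4 bind
  std::vector<double> sn_time;
  std::vector<int> sn_kind, sn_pos;   // 1 motor, 2 roadblock
  std::vector<double> snap_times;
  std::vector<double> term_times, init_times;

  auto emit_snapshot = [&](double ts) {
    snap_times.push_back(ts);
    for (size_t i = 0; i < mot.size(); ++i) {
      sn_time.push_back(ts); sn_kind.push_back(1); sn_pos.push_back(mot[i]);
    }
    for (std::set<int>::iterator it = rb_set.begin(); it != rb_set.end(); ++it) {
      sn_time.push_back(ts); sn_kind.push_back(2); sn_pos.push_back(*it);
    }
  };

  const int ncand = open_boundary ? std::max(0, L - delta_rb - delta_m + 1) : L;
  double t = 0.0, next_snap = burn_in;
  double n_events = 0.0, n_iter = 0.0;

  for (;;) {
    double total = 0.0;
    for (size_t i = 0; i < rate.size(); ++i) total += rate[i];
    bool init_ok = open_boundary && k_in > 0.0 && !mot_cover[delta_m - 1];
    if (init_ok) total += k_in;
    total += k_b * ncand;

    if (total <= 0.0) {
      while (next_snap <= t_max + 1e-9) { emit_snapshot(next_snap); next_snap += dt_sample; }
      t = t_max;
      break;
    }
    double tn = t + R::exp_rand() / total;
    while (next_snap <= std::min(tn, t_max) + 1e-12 && next_snap <= t_max + 1e-9) {
      emit_snapshot(next_snap);
      next_snap += dt_sample;
    }
    if (tn > t_max) { t = t_max; break; }
    t = tn;
    if (++n_iter > max_events)
      stop("event budget exceeded (max_events = %.0f); shorten t_max or raise max_events", max_events);

    double u = R::unif_rand() * total;
    int chosen = -1;
    for (size_t i = 0; i < rate.size(); ++i) {
      if (u < rate[i]) { chosen = (int)i; break; }
      u -= rate[i];
    }

    if (chosen >= 0) {
      // motor step
      int i = chosen, p = mot[i], n = (int)mot.size();
      flush_motor(i, t);
      if (record_site_stats && t >= burn_in)
        steps_from[open_boundary ? p + delta_m - 1 : md(p + delta_m - 1)] += 1.0;
      bool exiting = open_boundary && (p + delta_m > L - 1);
      if (exiting) {
        for (int k = 0; k < delta_m; ++k) mot_cover[p + k] = 0;
        term_times.push_back(t);
        if (record_events) { ev_time.push_back(t); ev_kind.push_back(3); ev_pos.push_back(p); }
        mot.erase(mot.begin() + i); rate.erase(rate.begin() + i);
        since.erase(since.begin() + i); slow_left.erase(slow_left.begin() + i);
        if (i - 1 >= 0) rate[i - 1] = compute_rate(i - 1);
      } else {
        int nxt = open_boundary ? p + delta_m : md(p + delta_m);
        int q = rb_cover[nxt];
        int evicted_q = -1;
        if (evict_mode == 1 && slow_left[i] > 0) --slow_left[i];
        if (q >= 0) {
          bool evict = (evict_mode != 2) || nxt == dyad_site(q);
          if (evict) {
            remove_rb(q, t);
            evicted_q = q;
            if (evict_mode == 1) {
              // hindered until the front has traversed the rest of the footprint
              int j = open_boundary ? nxt - q : md(nxt - q);
              slow_left[i] = delta_rb - 1 - j;
            }
          }
        }
        mot_cover[open_boundary ? p : md(p)] = 0;
        mot_cover[nxt] = 1;
        mot[i] = open_boundary ? p + 1 : md(p + 1);
        if (record_events) { ev_time.push_back(t); ev_kind.push_back(1); ev_pos.push_back(p); }
        rate[i] = compute_rate(i);
        if (n > 1) {
          int tr = open_boundary ? i - 1 : (i - 1 + n) % n;
          if (tr >= 0 && tr != i) rate[tr] = compute_rate(tr);
        }
        if (evicted_q >= 0) {
          // any motor hopping into the vacated footprint speeds up
          for (size_t j = 0; j < mot.size(); ++j) {
            int nx = mot[j] + delta_m;
            if (open_boundary && nx > L - 1) continue;
            int s = open_boundary ? nx : md(nx);
            int rel = s - evicted_q;
            if (!open_boundary) rel = md(rel);
            if (rel >= 0 && rel < delta_rb) rate[j] = compute_rate((int)j);
          }
        }
      }
      n_events += 1.0;
    } else if (init_ok && u < k_in) {
      // initiation
      mot.push_front(0); since.push_front(t); rate.push_front(0.0);
      slow_left.push_front(0);
      for (int k = 0; k < delta_m; ++k) mot_cover[k] = 1;
      rate[0] = compute_rate(0);
      init_times.push_back(t);
      if (record_events) { ev_time.push_back(t); ev_kind.push_back(2); ev_pos.push_back(0); }
      n_events += 1.0;
    } else {
      // roadblock binding attempt (thinning: reject if footprint not free)
      int idx = (int)(R::unif_rand() * ncand);
      if (idx >= ncand) idx = ncand - 1;
      int q = open_boundary ? delta_m + idx : idx;
      bool ok = true;
      for (int k = 0; k < delta_rb; ++k) {
        int s = open_boundary ? q + k : md(q + k);
        if (mot_cover[s] || rb_cover[s] >= 0) { ok = false; break; }
      }
      if (ok) {
        for (int k = 0; k < delta_rb; ++k) rb_cover[open_boundary ? q + k : md(q + k)] = q;
        rb_set.insert(q);
        rb_since[q] = t;
        if (record_events) { ev_time.push_back(t); ev_kind.push_back(4); ev_pos.push_back(q); }
        for (size_t i = 0; i < mot.size(); ++i) {
          int nx = mot[i] + delta_m;
          if (open_boundary && nx > L - 1) continue;
          int s = open_boundary ? nx : md(nx);
          if (rb_cover[s] == q) rate[i] = compute_rate((int)i);
        }
        n_events += 1.0;
      }
    }
  }

  for (size_t i = 0; i < mot.size(); ++i) flush_motor((int)i, t);
  for (std::set<int>::iterator it = rb_set.begin(); it != rb_set.end(); ++it) flush_rb(*it, t);

  IntegerVector fm(mot.begin(), mot.end());
  IntegerVector fr(rb_set.begin(), rb_set.end());

  List out = List::create(
    _["ev_time"] = record_events ? wrap(ev_time) : R_NilValue,
    _["ev_kind"] = record_events ? wrap(ev_kind) : R_NilValue,
    _["ev_pos"]  = record_events ? wrap(ev_pos) : R_NilValue,
    _["sn_time"] = wrap(sn_time),
    _["sn_kind"] = wrap(sn_kind),
    _["sn_pos"]  = wrap(sn_pos),
    _["snap_times"] = wrap(snap_times),
    _["motor_time"] = wrap(motor_time),
    _["rb_time"] = wrap(rb_time),
    _["front_time"] = wrap(front_time),
    _["steps_from"] = wrap(steps_from),
    _["termination_times"] = wrap(term_times),
    _["initiation_times"] = wrap(init_times),
    _["final_motors"] = fm,
    _["final_roadblocks"] = fr,
    _["n_events"] = n_events,
    _["t_end"] = t);
  return out;
}
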