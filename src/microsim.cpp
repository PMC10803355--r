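// Discrete-time car-following kernel: Krauss safe-velocity rule with a
// minimal overtaking model, camera-dependent behavioural target speeds and
// Poisson arrivals fed in from R as per-step counts.
//
// Units inside the kernel: metres, seconds, m/s. Lane 0 is the rightmost.
// Vehicle `pos` is the front bumper; a vehicle occupies [pos - veh_len, pos].

#include <Rcpp.h>
#include <deque>
#include <limits>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static inline double krauss_safe(double v_lead, double gap, double b, double tau) {
  // v_safe = -b*tau + sqrt((b*tau)^2 + v_lead^2 + 2*b*gap)
  double bt = b * tau;
  return -bt + std::sqrt(bt * bt + v_lead * v_lead + 2.0 * b * gap);
}

// Counter-based uniform draw for the driver-imperfection term, keyed on
// (seed, driver, step). Each driver carries their own noise stream, so for
// a fixed scenario seed the imperfection draws are identical across camera
// layouts: layout contrasts are paired and the common noise cancels.
static inline double noise_u(uint64_t seed, uint64_t driver, uint64_t step) {
  uint64_t x = seed + driver * 0x9E3779B97F4A7C15ULL +
               step * 0xD1B54A32D192ED03ULL;
  x ^= x >> 30; x *= 0xBF58476D1CE4E5B9ULL;
  x ^= x >> 27; x *= 0x94D049BB133111EBULL;
  x ^= x >> 31;
  return (double)(x >> 11) * (1.0 / 9007199254740992.0);
}

struct Sim {
  // road + parameters
  double length; int nlanes;
  double dt, accel, decel, tau, sigma, veh_len, min_gap, limit;
  double unsafe_ms, warmup;
  bool record = false;
  uint64_t noise_seed = 0;
  uint64_t step_no = 0;

  // static driver attributes (index = driver id - 1)
  NumericVector v_free;      // free target speed, m/s (already capped for A/telematics)
  LogicalVector responsive;  // capped to `limit` inside zones (group B, no telematics)
  IntegerVector group;       // 1 = A, 2 = B, 3 = C
  LogicalVector telem;
  NumericMatrix zones;       // k x 2 [start, end] enforced intervals

  // dynamic vehicle state (parallel arrays, grow-only)
  std::vector<double> pos, spd, entry_t;
  std::vector<int> drv, vid, lnv;
  std::vector<char> exited_f;
  std::vector<std::vector<int>> lanes;  // per lane, front (max pos) first

  // arrival handling
  std::deque<int> queue;
  std::vector<int> order; size_t cursor = 0;
  int next_vid = 1;

  // accounting
  long n_inserted = 0, n_exited = 0, n_collisions = 0;
  double dist_g[3] = {0, 0, 0}, time_g[3] = {0, 0, 0}, unsafe_g[3] = {0, 0, 0};
  double dist_tel = 0, time_tel = 0, unsafe_tel = 0;

  // trajectory records (post-warmup only)
  std::vector<int> r_id, r_lane;
  std::vector<double> r_t, r_pos, r_spd;

  double target(int d, double p) const {
    if (responsive[d]) {
      for (int k = 0; k < zones.nrow(); ++k)
        if (p >= zones(k, 0) && p <= zones(k, 1)) return limit;
    }
    return v_free[d];
  }

  int next_driver() {
    if (order.empty()) stop("driver pool is empty");
    if (cursor >= order.size()) {
      // reshuffle (Fisher-Yates on R's RNG) and cycle again
      for (size_t i = order.size(); i > 1; --i) {
        size_t j = (size_t)std::floor(R::runif(0.0, 1.0) * (double)i);
        if (j >= i) j = i - 1;
        std::swap(order[i - 1], order[j]);
      }
      cursor = 0;
    }
    return order[cursor++];
  }

  int add_vehicle(int d, double p, double v, int l, double t) {
    int idx = (int)pos.size();
    pos.push_back(p); spd.push_back(v); entry_t.push_back(t);
    drv.push_back(d); vid.push_back(next_vid++); lnv.push_back(l);
    exited_f.push_back(0);
    return idx;
  }

  // Arrivals enter the waiting queue; queued drivers are placed on the lane
  // with the largest entry headway, deferred while the entry gap is below
  // min_gap + vehicle_length.
  void insert_arrivals(int k, double t) {
    for (int i = 0; i < k; ++i) queue.push_back(next_driver());
    while (!queue.empty()) {
      int best = -1; double best_space = -1.0;
      for (int l = 0; l < nlanes; ++l) {
        double space = lanes[l].empty()
          ? std::numeric_limits<double>::infinity()
          : pos[lanes[l].back()];
        if (space > best_space) { best_space = space; best = l; }
      }
      if (best_space < veh_len + min_gap) break;
      int d = queue.front(); queue.pop_front();
      double v0 = std::min(v_free[d], limit);
      if (!lanes[best].empty()) {
        int L = lanes[best].back();
        double g = pos[L] - veh_len - min_gap;
        v0 = std::min(v0, krauss_safe(spd[L], std::max(g, 0.0), decel, tau));
      }
      if (v0 < 0) v0 = 0;
      int idx = add_vehicle(d, 0.0, v0, best, t);
      lanes[best].push_back(idx);
      ++n_inserted;
    }
  }

  bool try_change(int i, int from, int from_rank, int to, double vcf,
                  double vdes, bool improving) {
    std::vector<int>& L = lanes[to];
    int r = 0;
    while (r < (int)L.size() && pos[L[r]] > pos[i]) ++r;
    int nl = (r > 0) ? L[r - 1] : -1;
    int nf = (r < (int)L.size()) ? L[r] : -1;
    double inf = std::numeric_limits<double>::infinity();
    double g_l = (nl < 0) ? inf : pos[nl] - pos[i] - veh_len - min_gap;
    double g_f = (nf < 0) ? inf : pos[i] - pos[nf] - veh_len - min_gap;
    if (g_l < 0.0 || g_f < 0.0) return false;
    double v_unc = std::min(vdes, spd[i] + accel * dt);
    double v_new = v_unc;
    if (nl >= 0) v_new = std::min(v_new, krauss_safe(spd[nl], g_l, decel, tau));
    if (improving) {
      if (v_new <= vcf + 1e-9) return false;       // left only if strictly faster
    } else {
      if (v_new < v_unc - 1e-9) return false;      // right only if unconstrained there
    }
    // the new follower must not be forced below its current speed
    if (nf >= 0 && krauss_safe(spd[i], g_f, decel, tau) < spd[nf] - 1e-9) return false;
    std::vector<int>& F = lanes[from];
    F.erase(F.begin() + from_rank);
    L.insert(L.begin() + r, i);
    lnv[i] = to;
    return true;
  }

  // Minimal overtaking: a vehicle held below 80% of its target speed moves
  // left when safe; an unblocked vehicle keeps right when the right lane is
  // free. One change per vehicle per step.
  void do_lane_changes() {
    std::vector<char> moved(pos.size(), 0);
    for (int l = 0; l < nlanes; ++l) {
      std::vector<int>& L = lanes[l];
      for (size_t r = 0; r < L.size(); /* advanced below */) {
        int i = L[r];
        if (moved[i] || exited_f[i]) { ++r; continue; }
        double vdes = target(drv[i], pos[i]);
        if (vdes <= 0) { ++r; continue; }
        double vcf = std::min(vdes, spd[i] + accel * dt);
        if (r > 0) {
          int lead = L[r - 1];
          double g = pos[lead] - pos[i] - veh_len - min_gap;
          vcf = std::min(vcf, krauss_safe(spd[lead], std::max(g, 0.0), decel, tau));
        }
        bool blocked = vcf < 0.8 * vdes - 1e-12;
        bool did = false;
        if (blocked && l + 1 < nlanes)
          did = try_change(i, l, (int)r, l + 1, vcf, vdes, true);
        else if (!blocked && l > 0)
          did = try_change(i, l, (int)r, l - 1, vcf, vdes, false);
        if (did) moved[i] = 1; else ++r;
      }
    }
  }

  // One car-following update. Processed front-to-back per lane; the follower
  // is additionally hard-clamped behind the leader's updated position, which
  // makes the no-collision invariant exact rather than asymptotic.
  void do_update(double t_new) {
    bool in_obs = (t_new >= warmup - 1e-9);
    for (int l = 0; l < nlanes; ++l) {
      std::vector<int>& L = lanes[l];
      std::vector<int> keep; keep.reserve(L.size());
      double prev_old_pos = 0, prev_new_pos = 0, prev_new_v = 0;
      bool has_prev = false;
      for (size_t r = 0; r < L.size(); ++r) {
        int i = L[r];
        double vdes = target(drv[i], pos[i]);
        double vt = std::min(vdes, spd[i] + accel * dt);
        if (has_prev) {
          double g = prev_old_pos - pos[i] - veh_len - min_gap;
          if (g < -1e-9) ++n_collisions;
          vt = std::min(vt, krauss_safe(prev_new_v, std::max(g, 0.0), decel, tau));
        }
        if (sigma > 0)
          vt -= sigma * accel * dt * noise_u(noise_seed, (uint64_t)drv[i], step_no);
        if (vt < 0) vt = 0;
        double p_new = pos[i] + vt * dt;
        if (has_prev) {
          double cap = prev_new_pos - veh_len - min_gap;
          if (p_new > cap) {
            p_new = std::max(cap, pos[i]);
            vt = (p_new - pos[i]) / dt;
          }
        }
        prev_old_pos = pos[i]; prev_new_pos = p_new; prev_new_v = vt;
        has_prev = true;
        pos[i] = p_new; spd[i] = vt;
        if (p_new > length) { exited_f[i] = 1; ++n_exited; continue; }
        keep.push_back(i);
        if (in_obs) {
          double d = vt * dt;
          int g0 = group[drv[i]] - 1;
          dist_g[g0] += d; time_g[g0] += dt;
          bool unsafe = vt > unsafe_ms + 1e-12;
          if (unsafe) unsafe_g[g0] += d;
          if (telem[drv[i]]) {
            dist_tel += d; time_tel += dt;
            if (unsafe) unsafe_tel += d;
          }
          if (record) {
            r_id.push_back(vid[i]); r_t.push_back(t_new); r_pos.push_back(p_new);
            r_spd.push_back(vt * 3.6); r_lane.push_back(l);
          }
        }
      }
      L.swap(keep);
      // audit the spacing invariant
      for (size_t r = 1; r < L.size(); ++r) {
        int a = L[r - 1], b = L[r];
        if (pos[b] + veh_len + min_gap > pos[a] + 1e-6) ++n_collisions;
      }
    }
  }

  List result(bool with_world) {
    long on_road = 0;
    for (int l = 0; l < nlanes; ++l) on_road += (long)lanes[l].size();
    List summary = List::create(
      _["inserted"] = (double)n_inserted,
      _["exited"] = (double)n_exited,
      _["on_road"] = (double)on_road,
      _["queued"] = (double)queue.size(),
      _["collisions"] = (double)n_collisions,
      _["dist_m"] = NumericVector::create(_["A"] = dist_g[0], _["B"] = dist_g[1], _["C"] = dist_g[2]),
      _["time_s"] = NumericVector::create(_["A"] = time_g[0], _["B"] = time_g[1], _["C"] = time_g[2]),
      _["unsafe_m"] = NumericVector::create(_["A"] = unsafe_g[0], _["B"] = unsafe_g[1], _["C"] = unsafe_g[2]),
      _["telematics_dist_m"] = dist_tel,
      _["telematics_time_s"] = time_tel,
      _["telematics_unsafe_m"] = unsafe_tel);
    DataFrame traj = DataFrame::create(
      _["vehicle_id"] = wrap(r_id), _["time_s"] = wrap(r_t),
      _["position_m"] = wrap(r_pos), _["speed_kmh"] = wrap(r_spd),
      _["lane"] = wrap(r_lane));
    int nv = (int)pos.size();
    IntegerVector v_id(nv), v_drv(nv);
    NumericVector v_entry(nv);
    LogicalVector v_exit(nv);
    for (int i = 0; i < nv; ++i) {
      v_id[i] = vid[i]; v_drv[i] = drv[i] + 1;
      v_entry[i] = entry_t[i]; v_exit[i] = exited_f[i] != 0;
    }
    DataFrame veh = DataFrame::create(
      _["vehicle_id"] = v_id, _["driver_id"] = v_drv,
      _["entry_time_s"] = v_entry, _["exited"] = v_exit);
    List out = List::create(
      _["trajectories"] = traj, _["vehicles"] = veh, _["summary"] = summary);
    if (with_world) {
      NumericVector w_pos(nv), w_spd(nv);
      IntegerVector w_lane(nv);
      for (int i = 0; i < nv; ++i) { w_pos[i] = pos[i]; w_spd[i] = spd[i]; w_lane[i] = lnv[i]; }
      out["world"] = DataFrame::create(
        _["vehicle_id"] = v_id, _["driver_id"] = v_drv,
        _["position_m"] = w_pos, _["speed_ms"] = w_spd, _["lane"] = w_lane,
        _["exited"] = v_exit);
    }
    return out;
  }
};

static void init_params(Sim& S, double limit_ms, double length, int nlanes,
                        double dt, double accel, double decel, double tau,
                        double sigma, double veh_len, double min_gap,
                        double unsafe_ms) {
  S.limit = limit_ms; S.length = length; S.nlanes = nlanes;
  S.dt = dt; S.accel = accel; S.decel = decel; S.tau = tau; S.sigma = sigma;
  S.veh_len = veh_len; S.min_gap = min_gap; S.unsafe_ms = unsafe_ms;
  S.lanes.assign(nlanes, std::vector<int>());
}

// [[Rcpp::export]]
List ms_run_kernel(NumericVector v_free, IntegerVector group, LogicalVector telem,
                   LogicalVector responsive, NumericMatrix zones,
                   double limit_ms, double length, int nlanes,
                   double dt, double accel, double decel, double tau, double sigma,
                   double veh_len, double min_gap, double warmup,
                   IntegerVector arrivals_per_step,
                   double unsafe_ms, bool record, double noise_seed) {
  Sim S;
  init_params(S, limit_ms, length, nlanes, dt, accel, decel, tau, sigma,
              veh_len, min_gap, unsafe_ms);
  S.warmup = warmup; S.record = record;
  S.noise_seed = (uint64_t)noise_seed;
  S.v_free = v_free; S.responsive = responsive; S.group = group;
  S.telem = telem; S.zones = zones;
  int npop = v_free.size();
  S.order.resize(npop);
  for (int i = 0; i < npop; ++i) S.order[i] = i;
  int nsteps = arrivals_per_step.size();
  size_t est = (size_t)(nsteps * 2);
  S.r_id.reserve(record ? est : 0);
  for (int s = 0; s < nsteps; ++s) {
    S.step_no = (uint64_t)s;
    S.insert_arrivals(arrivals_per_step[s], s * dt);
    S.do_lane_changes();
    S.do_update((s + 1) * dt);
    if ((s & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return S.result(false);
}

// Single update step on an explicit world state (used for unit-level checks
// of the car-following rule; no insertion).
// [[Rcpp::export]]
List ms_step_kernel(DataFrame world,
                    NumericVector v_free, IntegerVector group, LogicalVector telem,
                    LogicalVector responsive, NumericMatrix zones,
                    double limit_ms, double length, int nlanes,
                    double dt, double accel, double decel, double tau, double sigma,
                    double veh_len, double min_gap,
                    double unsafe_ms, bool lane_change, bool record,
                    double noise_seed) {
  Sim S;
  init_params(S, limit_ms, length, nlanes, dt, accel, decel, tau, sigma,
              veh_len, min_gap, unsafe_ms);
  S.warmup = 0.0; S.record = record;
  S.noise_seed = (uint64_t)noise_seed;
  S.v_free = v_free; S.responsive = responsive; S.group = group;
  S.telem = telem; S.zones = zones;
  IntegerVector wid = world["vehicle_id"];
  IntegerVector wdrv = world["driver_id"];
  NumericVector wpos = world["position_m"];
  NumericVector wspd = world["speed_ms"];
  IntegerVector wlane = world["lane"];
  int n = wid.size();
  for (int i = 0; i < n; ++i) {
    if (wlane[i] < 0 || wlane[i] >= nlanes) stop("lane index out of range");
    int idx = S.add_vehicle(wdrv[i] - 1, wpos[i], wspd[i], wlane[i], 0.0);
    S.vid[idx] = wid[i];
    S.lanes[wlane[i]].push_back(idx);
  }
  S.next_vid = n > 0 ? *std::max_element(wid.begin(), wid.end()) + 1 : 1;
  for (int l = 0; l < nlanes; ++l)
    std::sort(S.lanes[l].begin(), S.lanes[l].end(),
              [&](int a, int b) { return S.pos[a] > S.pos[b]; });
  if (lane_change) S.do_lane_changes();
  S.do_update(dt);
  return S.result(true);
}
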