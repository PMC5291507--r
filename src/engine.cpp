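// Millisecond-resolution engine for Izhikevich networks with additive STDP,
// multiplicative weight decay, and Tsodyks-Markram short-term plasticity (STP),
// driven by closed-loop stimulation protocols or an embodied robot arena.
//
// Conventions shared with the R layer:
//  * neurons 0..n_exc-1 are excitatory (regular spiking), the rest inhibitory
//    (fast spiking); all zone index vectors arrive 0-based;
//  * the weight matrix arrives transposed (wt[post, pre], column-major), so the
//    outgoing weights of a presynaptic neuron are contiguous;
//  * spikes emitted at step t are delivered as synaptic input at step t+1;
//  * uniform multiplicative decay is tracked lazily through a scalar factor g
//    (w_effective = g * w_stored) and folded into the matrix before returning,
//    which is exact because folding is a single multiplication per weight.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

constexpr double SPIKE_THRESHOLD = 30.0; // mV
// Hyperpolarization floor (a reversal-potential-like bound). Without it, an
// extreme inhibitory volley can push v so far negative that the quadratic
// term catapults it upward and the Euler scheme diverges.
constexpr double V_FLOOR = -90.0;        // mV

struct Dyn {
  double sigma, stdp_A, stdp_tau, w_max, decay_mu;
  int stdp_cutoff, substeps;
  bool decay_all;           // true: decay every weight; false: plastic (E->E) only
  bool stdp_enabled, stp_enabled;
  double stp_U, stp_tau_d, stp_tau_f;
};

Dyn read_dyn(const List& d) {
  Dyn y;
  y.sigma        = as<double>(d["sigma"]);
  y.stdp_A       = as<double>(d["stdp_A"]);
  y.stdp_tau     = as<double>(d["stdp_tau"]);
  y.stdp_cutoff  = as<int>(d["stdp_cutoff_ms"]);
  y.w_max        = as<double>(d["w_max"]);
  y.decay_mu     = as<double>(d["decay_mu"]);
  y.decay_all    = as<std::string>(d["decay_scope"]) == "all";
  y.substeps     = as<int>(d["substeps"]);
  y.stdp_enabled = as<bool>(d["stdp_enabled"]);
  y.stp_enabled  = as<bool>(d["stp_enabled"]);
  y.stp_U        = as<double>(d["stp_U"]);
  y.stp_tau_d    = as<double>(d["stp_tau_d"]);
  y.stp_tau_f    = as<double>(d["stp_tau_f"]);
  return y;
}

// Core state advanced one ms at a time.
struct Net {
  int n, n_exc;
  std::vector<double> a, b, c, d, v, u;
  std::vector<double> w;      // w[pre * n + post], stored (pre-decay-fold) weight
  std::vector<char>   ex;     // connection-present flags, same layout
  std::vector<double> sx, su; // STP depression x / facilitation u per neuron
  std::vector<int>    last_spike;
  std::vector<int>    fired_prev, fired_now;
  std::vector<char>   fired_now_flag;
  double g;                   // lazy decay factor
  long long t;                // current ms (global clock)
  Dyn dyn;
  std::vector<double> pot;    // STDP lookup: pot[s] = A exp(-s/tau), s = 1..cutoff

  void init_tables() {
    pot.assign(dyn.stdp_cutoff + 1, 0.0);
    for (int s = 1; s <= dyn.stdp_cutoff; ++s)
      pot[s] = dyn.stdp_A * std::exp(-s / dyn.stdp_tau);
  }

  inline double decf(int pre, int post) const {
    if (dyn.decay_all) return g;
    return (pre < n_exc && post < n_exc) ? g : 1.0;
  }

  // One millisecond: given per-neuron external input e (stimulation only),
  // add noise + synaptic input, advance neurons, update STP, apply STDP+decay.
  // Condition checks happen in the caller between neuron update and STDP,
  // matching the protocol ordering.
  void gather_and_integrate(const std::vector<double>& e_ext,
                            std::vector<double>& I) {
    const int N = n;
    for (int i = 0; i < N; ++i)
      I[i] = e_ext[i] + (dyn.sigma > 0 ? dyn.sigma * norm_rand() : 0.0);
    for (size_t k = 0; k < fired_prev.size(); ++k) {
      const int j = fired_prev[k];
      double f = 1.0;
      if (dyn.stp_enabled && j < n_exc) f = su[j] * sx[j];
      const double* col = &w[(size_t)j * N];
      if (dyn.decay_all || j >= n_exc) {
        const double m = f * (dyn.decay_all ? g : 1.0);
        for (int i = 0; i < N; ++i) I[i] += m * col[i];
      } else { // plastic-only decay, excitatory presynaptic neuron
        const double mE = f * g, mI = f;
        for (int i = 0; i < n_exc; ++i) I[i] += mE * col[i];
        for (int i = n_exc; i < N; ++i) I[i] += mI * col[i];
      }
    }
    fired_now.clear();
    const double h = 1.0 / dyn.substeps;
    for (int i = 0; i < N; ++i) {
      double vi = v[i], ui = u[i];
      for (int s = 0; s < dyn.substeps; ++s) {
        // once a sub-step crosses threshold the spike is certain; further
        // sub-steps would square an already super-threshold voltage
        if (vi >= SPIKE_THRESHOLD) break;
        vi += h * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + I[i]);
        if (vi < V_FLOOR) vi = V_FLOOR;
      }
      // the model caps spikes at +30 mV: the recovery update must not see
      // the integrator's overshoot above threshold
      ui += a[i] * (b[i] * std::min(vi, SPIKE_THRESHOLD) - ui);
      if (!std::isfinite(vi) || !std::isfinite(ui))
        stop("numerical blow-up: non-finite membrane state at t=%d, neuron %d",
             (int)t, i + 1);
      if (vi >= SPIKE_THRESHOLD) {
        fired_now.push_back(i);
        fired_now_flag[i] = 1;
        vi = c[i];
        ui += d[i];
      }
      v[i] = vi; u[i] = ui;
    }
    if (dyn.stp_enabled) {
      for (int j = 0; j < n_exc; ++j) {
        const double f = fired_now_flag[j] ? 1.0 : 0.0;
        const double xo = sx[j], uo = su[j];
        sx[j] = xo + (1.0 - xo) / dyn.stp_tau_d - uo * xo * f;
        su[j] = uo + (dyn.stp_U - uo) / dyn.stp_tau_f +
                dyn.stp_U * (1.0 - uo) * f;
        if (sx[j] <= 0.0 || sx[j] > 1.0 + 1e-9 || su[j] < 0.0 ||
            su[j] > 1.0 + 1e-9)
          stop("STP state left (0,1] at t=%d", (int)t);
      }
    }
  }

  // Nearest-spike additive STDP over this step's spikes, then decay; finally
  // advance last-spike bookkeeping and the fired sets.
  void plasticity_and_bookkeeping() {
    if (dyn.stdp_enabled) {
      const int N = n;
      for (size_t k = 0; k < fired_now.size(); ++k) {
        const int i = fired_now[k];
        if (i >= n_exc) continue;
        for (int j = 0; j < n_exc; ++j) {
          if (j == i || fired_now_flag[j]) continue; // simultaneous: dw = 0
          const long long ls = last_spike[j];
          if (ls < 0) continue;
          const long long s = t - ls;
          if (s < 1 || s > dyn.stdp_cutoff) continue;
          const double dw = pot[(int)s];
          size_t up = (size_t)j * N + i; // j fired first: potentiate j -> i
          if (ex[up]) {
            double wa = decf(j, i) * w[up] + dw;
            if (wa > dyn.w_max) wa = dyn.w_max;
            if (wa < 0.0) wa = 0.0;
            w[up] = wa / decf(j, i);
          }
          size_t dn = (size_t)i * N + j; // i fired after: depress i -> j
          if (ex[dn]) {
            double wa = decf(i, j) * w[dn] - dw;
            if (wa < 0.0) wa = 0.0;
            if (wa > dyn.w_max) wa = dyn.w_max;
            w[dn] = wa / decf(i, j);
          }
        }
      }
    }
    if (dyn.decay_mu > 0) g *= (1.0 - dyn.decay_mu);
    for (size_t k = 0; k < fired_now.size(); ++k)
      last_spike[fired_now[k]] = (int)t;
    fired_prev = fired_now;
    for (size_t k = 0; k < fired_now.size(); ++k)
      fired_now_flag[fired_now[k]] = 0;
  }

  // Fold the lazy decay factor into the stored matrix; afterwards g = 1.
  void fold_decay() {
    const int N = n;
    for (int j = 0; j < N; ++j)
      for (int i = 0; i < N; ++i)
        w[(size_t)j * N + i] *= decf(j, i);
    g = 1.0;
  }

  NumericMatrix weight_snapshot() const {
    NumericMatrix out(n, n); // out[post, pre] like the input orientation
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i)
        out(i, j) = decf(j, i) * w[(size_t)j * n + i];
    return out;
  }
};

Net build_net(NumericMatrix wt, LogicalMatrix existst, int n_exc,
              NumericVector a, NumericVector b, NumericVector c,
              NumericVector d, NumericVector v0, NumericVector u0,
              const List& dyn) {
  Net net;
  net.n = wt.nrow();
  net.n_exc = n_exc;
  net.dyn = read_dyn(dyn);
  net.init_tables();
  const int N = net.n;
  net.a.assign(a.begin(), a.end());
  net.b.assign(b.begin(), b.end());
  net.c.assign(c.begin(), c.end());
  net.d.assign(d.begin(), d.end());
  net.v.assign(v0.begin(), v0.end());
  net.u.assign(u0.begin(), u0.end());
  net.w.assign(N * (size_t)N, 0.0);
  net.ex.assign(N * (size_t)N, 0);
  for (int pre = 0; pre < N; ++pre)
    for (int post = 0; post < N; ++post) {
      net.w[(size_t)pre * N + post] = wt(post, pre);
      net.ex[(size_t)pre * N + post] = existst(post, pre) ? 1 : 0;
    }
  net.sx.assign(N, 1.0);
  net.su.assign(N, net.dyn.stp_U);
  net.last_spike.assign(N, -1);
  net.fired_now_flag.assign(N, 0);
  net.g = 1.0;
  net.t = 0;
  return net;
}

void restore_state(Net& net, const List& st) {
  net.v = as<std::vector<double> >(st["v"]);
  net.u = as<std::vector<double> >(st["u"]);
  net.sx = as<std::vector<double> >(st["stp_x"]);
  net.su = as<std::vector<double> >(st["stp_u"]);
  net.last_spike = as<std::vector<int> >(st["last_spike"]);
  net.fired_prev = as<std::vector<int> >(st["fired_prev"]);
  net.t = (long long)as<double>(st["t"]);
}

List core_state(const Net& net) {
  return List::create(
      _["v"] = net.v, _["u"] = net.u, _["stp_x"] = net.sx,
      _["stp_u"] = net.su, _["last_spike"] = net.last_spike,
      _["fired_prev"] = net.fired_prev, _["t"] = (double)net.t);
}

inline int draw_delay(int lo, int hi) {
  int d = lo + (int)std::floor(unif_rand() * (hi - lo + 1));
  if (d > hi) d = hi;
  return d;
}

} // namespace

// [[Rcpp::export(name = ".run_network_cpp")]]
List run_network_cpp(NumericMatrix wt, LogicalMatrix existst, int n_exc,
                     NumericVector a, NumericVector b, NumericVector c,
                     NumericVector d, NumericVector v0, NumericVector u0,
                     List dyn, List proto, List rec,
                     Nullable<List> state0 = R_NilValue) {
  Net net = build_net(wt, existst, n_exc, a, b, c, d, v0, u0, dyn);
  const int N = net.n;

  // protocol configuration
  const bool stim_enabled = as<bool>(proto["stim_enabled"]);
  const std::vector<int> zone_in = as<std::vector<int> >(proto["input_zone"]);
  const double amp = as<double>(proto["stim_amplitude"]);
  const std::vector<int> zone_a = as<std::vector<int> >(proto["zone_a"]);
  const std::vector<int> zone_b = as<std::vector<int> >(proto["zone_b"]);
  const int thr_a = as<int>(proto["stop_thr_a"]);
  const int thr_b = as<int>(proto["stop_thr_b"]); // < 0 means clause unset
  const int timeout_ms = as<int>(proto["timeout_ms"]);
  const int delay_min = as<int>(proto["delay_min_ms"]);
  const int delay_max = as<int>(proto["delay_max_ms"]);
  const bool stimulus_enabled = as<bool>(proto["stimulus_enabled"]);
  const int stimulus_thr = as<int>(proto["stimulus_thr"]);
  const double punish_amp = as<double>(proto["punish_amplitude"]);
  const int punish_ms = as<int>(proto["punish_ms"]);
  const std::vector<int> punish_targets =
      as<std::vector<int> >(proto["punish_targets"]);
  const int duration = as<int>(proto["duration_ms"]);

  // recording configuration
  const bool record_raster = as<bool>(rec["record_raster"]);
  const int zone_bin = as<int>(rec["zone_bin_ms"]);
  const int window_ms = as<int>(rec["window_ms"]);
  const int snapshot_ms = as<int>(rec["snapshot_ms"]);

  // protocol state (possibly resumed)
  bool stim_on = false;
  long long onset = 0, next_onset = 0, punish_until = -1;
  int pending_delay = 0;
  if (state0.isNotNull()) {
    List st(state0);
    restore_state(net, st);
    stim_on = as<bool>(st["stim_on"]);
    onset = (long long)as<double>(st["onset"]);
    next_onset = (long long)as<double>(st["next_onset"]);
    punish_until = (long long)as<double>(st["punish_until"]);
    pending_delay = as<int>(st["pending_delay"]);
  }

  std::vector<double> trial_onset, trial_rt, trial_to, trial_delay;
  std::vector<int> ras_t, ras_id;
  const long long t_start = net.t, t_end_all = net.t + duration;
  const int n_bins = zone_bin > 0 ? (duration + zone_bin - 1) / zone_bin : 0;
  std::vector<double> binA(n_bins, 0.0), binB(n_bins, 0.0);
  std::vector<double> cnt_first(N, 0.0), cnt_last(N, 0.0);
  std::vector<double> e_ext(N), I(N);
  List snaps;
  std::vector<double> snap_times;

  RNGScope rng;
  for (long long t = t_start; t < t_end_all; ++t) {
    net.t = t;
    if (stim_enabled && !stim_on && t >= next_onset) {
      stim_on = true;
      onset = t;
    }
    std::fill(e_ext.begin(), e_ext.end(), 0.0);
    if (stim_on)
      for (size_t k = 0; k < zone_in.size(); ++k) e_ext[zone_in[k]] += amp;
    if (t < punish_until)
      for (size_t k = 0; k < punish_targets.size(); ++k)
        e_ext[punish_targets[k]] += punish_amp;

    net.gather_and_integrate(e_ext, I);

    int nA = 0, nB = 0;
    for (size_t k = 0; k < zone_a.size(); ++k)
      nA += net.fired_now_flag[zone_a[k]];
    for (size_t k = 0; k < zone_b.size(); ++k)
      nB += net.fired_now_flag[zone_b[k]];

    if (stim_on) {
      const bool met = nA >= thr_a && (thr_b < 0 || nB < thr_b);
      if (met) {
        const int dly = draw_delay(delay_min, delay_max);
        trial_onset.push_back((double)onset);
        trial_rt.push_back((double)(t - onset));
        trial_to.push_back(0.0);
        trial_delay.push_back((double)dly);
        stim_on = false;
        next_onset = t + dly;
      } else if (t - onset + 1 >= timeout_ms) {
        const int dly = draw_delay(delay_min, delay_max);
        trial_onset.push_back((double)onset);
        trial_rt.push_back(NA_REAL);
        trial_to.push_back(1.0);
        trial_delay.push_back((double)dly);
        stim_on = false;
        next_onset = t + 1 + dly;
      }
    }
    if (stimulus_enabled && nB >= stimulus_thr)
      punish_until = t + 1 + punish_ms;

    net.plasticity_and_bookkeeping();

    // recording
    const long long rel = t - t_start;
    if (n_bins > 0) {
      const int bin = (int)(rel / zone_bin);
      binA[bin] += nA;
      binB[bin] += nB;
    }
    for (size_t k = 0; k < net.fired_prev.size(); ++k) {
      const int id = net.fired_prev[k];
      if (record_raster) {
        ras_t.push_back((int)t);
        ras_id.push_back(id);
      }
      if (rel < window_ms) cnt_first[id] += 1;
      if (rel >= duration - window_ms) cnt_last[id] += 1;
    }
    if (snapshot_ms > 0 && (rel + 1) % snapshot_ms == 0) {
      snaps.push_back(net.weight_snapshot());
      snap_times.push_back((double)(t + 1));
    }
  }
  net.t = t_end_all;
  net.fold_decay();

  List state = core_state(net);
  state["stim_on"] = stim_on;
  state["onset"] = (double)onset;
  state["next_onset"] = (double)next_onset;
  state["punish_until"] = (double)punish_until;
  state["pending_delay"] = pending_delay;

  return List::create(
      _["trials"] = DataFrame::create(
          _["onset_ms"] = trial_onset, _["reaction_time_ms"] = trial_rt,
          _["timed_out"] = trial_to, _["delay_ms"] = trial_delay),
      _["raster_t"] = ras_t, _["raster_id"] = ras_id,
      _["zone_a_counts"] = binA, _["zone_b_counts"] = binB,
      _["counts_first"] = cnt_first, _["counts_last"] = cnt_last,
      _["snapshots"] = snaps, _["snapshot_times"] = snap_times,
      _["w_final"] = net.weight_snapshot(), _["state"] = state);
}

namespace {

// Distance from (x, y) along direction theta to the square [0, side]^2
// boundary (the point is inside, so some positive intersection exists).
inline double ray_to_wall(double x, double y, double theta, double side) {
  const double cx = std::cos(theta), sy = std::sin(theta);
  double best = R_PosInf;
  if (cx > 1e-12) best = std::min(best, (side - x) / cx);
  if (cx < -1e-12) best = std::min(best, -x / cx);
  if (sy > 1e-12) best = std::min(best, (side - y) / sy);
  if (sy < -1e-12) best = std::min(best, -y / sy);
  return best;
}

} // namespace

// [[Rcpp::export(name = ".ray_to_wall_cpp")]]
double ray_to_wall_cpp(double x, double y, double theta, double side) {
  return ray_to_wall(x, y, theta, side);
}

// [[Rcpp::export(name = ".run_robot_cpp")]]
List run_robot_cpp(NumericMatrix wt, LogicalMatrix existst, int n_exc,
                   NumericVector a, NumericVector b, NumericVector c,
                   NumericVector d, NumericVector v0, NumericVector u0,
                   List dyn, List robot) {
  Net net = build_net(wt, existst, n_exc, a, b, c, d, v0, u0, dyn);
  const int N = net.n;

  const std::string mode = as<std::string>(robot["mode"]);
  const double sensitivity = as<double>(robot["sensitivity"]);
  const double const_amp = as<double>(robot["const_amplitude"]); // open loop, per channel
  const std::vector<int> zin_l = as<std::vector<int> >(robot["zone_in_left"]);
  const std::vector<int> zin_r = as<std::vector<int> >(robot["zone_in_right"]);
  const std::vector<int> zout_l = as<std::vector<int> >(robot["zone_out_left"]);
  const std::vector<int> zout_r = as<std::vector<int> >(robot["zone_out_right"]);
  const double side = as<double>(robot["side"]);
  const double radius = as<double>(robot["radius"]);
  const double speed = as<double>(robot["speed"]);
  const double srange = as<double>(robot["sensor_range"]);
  const double sangle = as<double>(robot["sensor_angle"]);
  const double turn = as<double>(robot["turn_per_spike"]);
  const double min_dist = as<double>(robot["min_distance"]);
  // hull-based sensing: distances are measured from the robot's rim, so the
  // sensor input sensitivity/distance spans its full range as the robot
  // approaches a wall (a center-based reading could never drop below the
  // 25 px radius, capping the input at sensitivity/25)
  const double hull_off = as<bool>(robot["hull_based"]) ? radius : 0.0;
  double x = as<double>(robot["x0"]), y = as<double>(robot["y0"]);
  double heading = as<double>(robot["heading0"]);
  const int duration = as<int>(robot["duration_ms"]);
  const int traj_every = as<int>(robot["traj_every_ms"]);

  const bool closed = mode == "closed";
  std::vector<double> e_ext(N), I(N);
  std::vector<double> stim_mv(duration, 0.0);
  LogicalVector near_wall(duration);
  const int n_traj = traj_every > 0 ? duration / traj_every : 0;
  NumericMatrix traj(n_traj, 7); // t, x, y, heading, dist_l, dist_r, stim_mv
  double cum_stim = 0.0;
  int traj_row = 0;

  RNGScope rng;
  for (int t = 0; t < duration; ++t) {
    net.t = t;
    const double dl = ray_to_wall(x, y, heading + sangle, side) - hull_off;
    const double dr = ray_to_wall(x, y, heading - sangle, side) - hull_off;
    double in_l = 0.0, in_r = 0.0;
    if (closed) {
      if (dl <= srange) in_l = sensitivity / std::max(dl, min_dist);
      if (dr <= srange) in_r = sensitivity / std::max(dr, min_dist);
    } else {
      in_l = const_amp;
      in_r = const_amp;
    }
    std::fill(e_ext.begin(), e_ext.end(), 0.0);
    if (in_l > 0)
      for (size_t k = 0; k < zin_l.size(); ++k) e_ext[zin_l[k]] += in_l;
    if (in_r > 0)
      for (size_t k = 0; k < zin_r.size(); ++k) e_ext[zin_r[k]] += in_r;

    net.gather_and_integrate(e_ext, I);

    int n_left = 0, n_right = 0;
    for (size_t k = 0; k < zout_l.size(); ++k)
      n_left += net.fired_now_flag[zout_l[k]];
    for (size_t k = 0; k < zout_r.size(); ++k)
      n_right += net.fired_now_flag[zout_r[k]];
    heading += turn * (n_left - n_right);
    x += speed * std::cos(heading);
    y += speed * std::sin(heading);
    if (x < radius) x = radius;
    if (x > side - radius) x = side - radius;
    if (y < radius) y = radius;
    if (y > side - radius) y = side - radius;

    net.plasticity_and_bookkeeping();

    const double stim_this = in_l + in_r; // per-channel ledger accounting
    cum_stim += stim_this;
    stim_mv[t] = stim_this;
    const double wall_d =
        std::min(std::min(x, side - x), std::min(y, side - y)) - hull_off;
    near_wall[t] = wall_d < srange;
    if (traj_every > 0 && t % traj_every == 0 && traj_row < n_traj) {
      traj(traj_row, 0) = t;
      traj(traj_row, 1) = x;
      traj(traj_row, 2) = y;
      traj(traj_row, 3) = heading;
      traj(traj_row, 4) = dl;
      traj(traj_row, 5) = dr;
      traj(traj_row, 6) = stim_this;
      ++traj_row;
    }
  }
  net.fold_decay();
  return List::create(
      _["trajectory"] = traj, _["near_wall"] = near_wall,
      _["stim_mv"] = stim_mv, _["cumulative_stimulation"] = cum_stim,
      _["w_final"] = net.weight_snapshot(),
      _["final_pose"] = NumericVector::create(x, y, heading));
}
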