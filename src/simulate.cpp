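#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Duration model: fam 0 = exponential, 1 = gamma, 2 = delayed-exponential,
// 3 = point mass (used only for initial-condition distributions).
struct Dur {
  int fam;
  double mean, cv, delay;
};

static Dur dur_from_row(const NumericMatrix& dm, int row) {
  Dur d;
  d.fam   = (int) dm(row, 0);
  d.mean  = dm(row, 1);
  d.cv    = dm(row, 2);
  d.delay = dm(row, 3);
  return d;
}

static double draw_dur(const Dur& d) {
  switch (d.fam) {
  case 0:
    return R::rexp(d.mean);
  case 1: {
    double shape = 1.0 / (d.cv * d.cv);
    return R::rgamma(shape, d.mean / shape);
  }
  case 2:
    return d.delay + R::rexp(d.mean - d.delay);
  case 3:
    return d.mean;
  }
  return R::rexp(d.mean);
}

// Event kinds: 0 = E_P, 1 = E_S1, 2 = E_S2, 3 = E_S3.
// Flow: inactive cycle = E_S1 -> [while r < p2: E_S3] -> E_S2 -> checkpoint
// (r < p1 -> burst of E_P, repeating while r < p1; else new cycle).
// In direct mode the whole inactive cycle is one draw, recorded as E_S1.
//
// Low-level generator shared by the exported entry points.  Appends events
// until t reaches t_end.  init: 0 = start of inactive cycle, 1 = start of
// burst, 2 = first inactive interval drawn from `init_dur`, then burst.
struct SimOut {
  std::vector<int> kind;
  std::vector<double> start, duration;
  std::vector<int> produced;
  std::vector<double> synth;
};

static void simulate_core(const NumericMatrix& durs, double p1, double p2,
                          bool direct, double t_end, int init,
                          const Dur& init_dur, bool keep_events,
                          SimOut& out, R_xlen_t max_events = 50000000) {
  Dur dP  = dur_from_row(durs, 0);
  Dur dS1 = dur_from_row(durs, 1);
  Dur dS2 = dur_from_row(durs, 2);
  Dur dS3 = dur_from_row(durs, 3);

  double t = 0.0;
  R_xlen_t n_ev = 0;
  bool in_burst = (init == 1);
  if (init == 2) {
    double d0 = draw_dur(init_dur);
    if (keep_events) {
      out.kind.push_back(1);
      out.start.push_back(t);
      out.duration.push_back(d0);
      out.produced.push_back(0);
    }
    t += d0;
    in_burst = true;
  }

  while (t < t_end && n_ev < max_events) {
    if (in_burst) {
      // one E_P; transcript appears at completion
      double d = draw_dur(dP);
      if (keep_events) {
        out.kind.push_back(0);
        out.start.push_back(t);
        out.duration.push_back(d);
        out.produced.push_back(1);
      }
      t += d;
      ++n_ev;
      if (t <= t_end) out.synth.push_back(t);
      in_burst = (unif_rand() < p1);
    } else {
      // one inactive cycle
      if (direct) {
        double d = draw_dur(dS1);
        if (keep_events) {
          out.kind.push_back(1);
          out.start.push_back(t);
          out.duration.push_back(d);
          out.produced.push_back(0);
        }
        t += d;
        ++n_ev;
      } else {
        double d = draw_dur(dS1);
        if (keep_events) {
          out.kind.push_back(1);
          out.start.push_back(t);
          out.duration.push_back(d);
          out.produced.push_back(0);
        }
        t += d;
        ++n_ev;
        while (unif_rand() < p2) {
          d = draw_dur(dS3);
          if (keep_events) {
            out.kind.push_back(3);
            out.start.push_back(t);
            out.duration.push_back(d);
            out.produced.push_back(0);
          }
          t += d;
          ++n_ev;
        }
        d = draw_dur(dS2);
        if (keep_events) {
          out.kind.push_back(2);
          out.start.push_back(t);
          out.duration.push_back(d);
          out.produced.push_back(0);
        }
        t += d;
        ++n_ev;
      }
      in_burst = (unif_rand() < p1);
    }
  }
}

// [[Rcpp::export]]
List cpp_simulate_trajectory(NumericMatrix durs, double p1, double p2,
                             bool direct, double tau_m, double t_end,
                             int init, NumericVector init_spec) {
  Dur d0;
  d0.fam = (int) init_spec[0];
  d0.mean = init_spec[1];
  d0.cv = init_spec[2];
  d0.delay = init_spec[3];
  SimOut out;
  simulate_core(durs, p1, p2, direct, t_end, init, d0, true, out);
  R_xlen_t n = out.synth.size();
  NumericVector deg(n);
  for (R_xlen_t i = 0; i < n; ++i) deg[i] = out.synth[i] + R::rexp(tau_m);
  return List::create(
    _["kind"] = wrap(out.kind), _["start"] = wrap(out.start),
    _["duration"] = wrap(out.duration), _["produced"] = wrap(out.produced),
    _["synthesis"] = wrap(out.synth), _["degradation"] = deg);
}

// Running raw-moment accumulators of the mRNA copy number over an ensemble
// of independent trajectories, evaluated at the (increasing) grid times.
// Returns sums of m, m^2, m^3, m^4 per grid point.
// [[Rcpp::export]]
List cpp_ensemble_moments(NumericMatrix durs, double p1, double p2,
                          bool direct, double tau_m, NumericVector t_grid,
                          int n_traj, int init) {
  int ng = t_grid.size();
  double t_max = t_grid[ng - 1];
  NumericVector s1(ng), s2(ng), s3(ng), s4(ng);
  std::vector<double> cnt(ng);
  Dur dummy;
  dummy.fam = 0; dummy.mean = 1.0; dummy.cv = 1.0; dummy.delay = 0.0;

  for (int tr = 0; tr < n_traj; ++tr) {
    SimOut out;
    simulate_core(durs, p1, p2, direct, t_max, init, dummy, false, out);
    std::fill(cnt.begin(), cnt.end(), 0.0);
    for (size_t i = 0; i < out.synth.size(); ++i) {
      double s = out.synth[i];
      double e = s + R::rexp(tau_m);
      // grid points in [s, e)
      int lo = std::lower_bound(t_grid.begin(), t_grid.end(), s) -
               t_grid.begin();
      for (int k = lo; k < ng && t_grid[k] < e; ++k) cnt[k] += 1.0;
    }
    for (int k = 0; k < ng; ++k) {
      double m = cnt[k];
      s1[k] += m;
      s2[k] += m * m;
      s3[k] += m * m * m;
      s4[k] += m * m * m * m;
    }
    if (tr % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["s1"] = s1, _["s2"] = s2, _["s3"] = s3, _["s4"] = s4,
                      _["n"] = n_traj);
}

// Time-averaged copy number of a single long trajectory over
// [burnin, t_end]: sum over molecules of their alive overlap with the
// window, divided by the window length.
// [[Rcpp::export]]
double cpp_time_average(NumericMatrix durs, double p1, double p2, bool direct,
                        double tau_m, double t_end, double burnin) {
  SimOut out;
  Dur dummy;
  dummy.fam = 0; dummy.mean = 1.0; dummy.cv = 1.0; dummy.delay = 0.0;
  simulate_core(durs, p1, p2, direct, t_end, 0, dummy, false, out);
  double acc = 0.0;
  for (size_t i = 0; i < out.synth.size(); ++i) {
    double s = out.synth[i];
    double e = s + R::rexp(tau_m);
    double lo = std::max(s, burnin), hi = std::min(e, t_end);
    if (hi > lo) acc += hi - lo;
  }
  return acc / (t_end - burnin);
}

// Alternating inactive/active renewal process: first activation drawn from
// g0, active phases from f_A (exponential, mean tau_A), inactive phases from
// f_I; mRNA synthesised as a Poisson process with rate 1/tau_P while active,
// degraded after an exponential lifetime with mean tau_m.  Returns, per grid
// time, the number of active trajectories and the count moment sums.
// [[Rcpp::export]]
List cpp_phase_renewal(NumericVector g0_spec, NumericVector fI_spec,
                       double tau_A, double tau_P, double tau_m,
                       NumericVector t_grid, int n_traj) {
  Dur g0, fI;
  g0.fam = (int) g0_spec[0]; g0.mean = g0_spec[1]; g0.cv = g0_spec[2];
  g0.delay = g0_spec[3];
  fI.fam = (int) fI_spec[0]; fI.mean = fI_spec[1]; fI.cv = fI_spec[2];
  fI.delay = fI_spec[3];
  int ng = t_grid.size();
  double t_max = t_grid[ng - 1];
  NumericVector act(ng), s1(ng), s2(ng);
  std::vector<double> cnt(ng);

  for (int tr = 0; tr < n_traj; ++tr) {
    std::fill(cnt.begin(), cnt.end(), 0.0);
    double s = draw_dur(g0);  // first activation time
    while (s < t_max) {
      double a = R::rexp(tau_A);
      double e = std::min(s + a, t_max);
      // active on [s, e): mark active grid points
      int lo = std::lower_bound(t_grid.begin(), t_grid.end(), s) -
               t_grid.begin();
      for (int k = lo; k < ng && t_grid[k] < s + a; ++k) act[k] += 1.0;
      // synthesis events while active
      double ts = s + R::rexp(tau_P);
      while (ts < e) {
        double dend = ts + R::rexp(tau_m);
        int l2 = std::lower_bound(t_grid.begin(), t_grid.end(), ts) -
                 t_grid.begin();
        for (int k = l2; k < ng && t_grid[k] < dend; ++k) cnt[k] += 1.0;
        ts += R::rexp(tau_P);
      }
      s = s + a + draw_dur(fI);
    }
    for (int k = 0; k < ng; ++k) {
      s1[k] += cnt[k];
      s2[k] += cnt[k] * cnt[k];
    }
    if (tr % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["active"] = act, _["s1"] = s1, _["s2"] = s2,
                      _["n"] = n_traj);
}

// Classical two-state (telegraph) gene: OFF -> ON at rate k_on, ON -> OFF at
// rate k_off, synthesis at rate k_syn while ON, first-order degradation.
// [[Rcpp::export]]
List cpp_telegraph_moments(double k_on, double k_off, double k_syn,
                           double tau_m, NumericVector t_grid, int n_traj,
                           int init_on) {
  int ng = t_grid.size();
  double t_max = t_grid[ng - 1];
  NumericVector s1(ng), s2(ng), s3(ng), s4(ng);
  std::vector<double> cnt(ng);
  for (int tr = 0; tr < n_traj; ++tr) {
    std::fill(cnt.begin(), cnt.end(), 0.0);
    double t = 0.0;
    bool on = init_on != 0;
    while (t < t_max) {
      if (on) {
        double dwell = R::rexp(1.0 / k_off);
        double e = std::min(t + dwell, t_max);
        double ts = t + R::rexp(1.0 / k_syn);
        while (ts < e) {
          double dend = ts + R::rexp(tau_m);
          int lo = std::lower_bound(t_grid.begin(), t_grid.end(), ts) -
                   t_grid.begin();
          for (int k = lo; k < ng && t_grid[k] < dend; ++k) cnt[k] += 1.0;
          ts += R::rexp(1.0 / k_syn);
        }
        t += dwell;
      } else {
        t += R::rexp(1.0 / k_on);
      }
      on = !on;
    }
    for (int k = 0; k < ng; ++k) {
      double m = cnt[k];
      s1[k] += m;
      s2[k] += m * m;
      s3[k] += m * m * m;
      s4[k] += m * m * m * m;
    }
    if (tr % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["s1"] = s1, _["s2"] = s2, _["s3"] = s3, _["s4"] = s4,
                      _["n"] = n_traj);
}

// Single telegraph trajectory: state switch times and synthesis/degradation
// times, for trajectory-level inspection.
// [[Rcpp::export]]
List cpp_telegraph_trajectory(double k_on, double k_off, double k_syn,
                              double tau_m, double t_end, int init_on) {
  std::vector<double> sw_time, synth, deg;
  std::vector<int> sw_state;
  double t = 0.0;
  bool on = init_on != 0;
  sw_time.push_back(0.0);
  sw_state.push_back(on ? 1 : 0);
  while (t < t_end) {
    if (on) {
      double dwell = R::rexp(1.0 / k_off);
      double e = std::min(t + dwell, t_end);
      double ts = t + R::rexp(1.0 / k_syn);
      while (ts < e) {
        synth.push_back(ts);
        deg.push_back(ts + R::rexp(tau_m));
        ts += R::rexp(1.0 / k_syn);
      }
      t += dwell;
    } else {
      t += R::rexp(1.0 / k_on);
    }
    on = !on;
    if (t < t_end) {
      sw_time.push_back(t);
      sw_state.push_back(on ? 1 : 0);
    }
  }
  return List::create(_["switch_time"] = wrap(sw_time),
                      _["switch_state"] = wrap(sw_state),
                      _["synthesis"] = wrap(synth),
                      _["degradation"] = wrap(deg));
}
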