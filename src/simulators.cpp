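#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Motor state codes shared by all simulators:
// 0 = DETACHED, 1 = STRONG_ADP (post-powerstroke, ADP bound), 2 = RIGOR.
// The weak state is lumped into the effective attachment step.

namespace {

struct NeighborCounts {
  // per-motor counts of strongly bound motors within the coupling distance,
  // split by side along the filament axis
  std::vector<int> left, right;
};

// multiplier applied to the attachment rate of detached motor i:
// eps when no strongly bound motor is within ell, eps^pe with a bound
// neighbor on exactly one side, 1 when flanked on both sides
inline double act_factor(int nl, int nr, double eps, double eps_pe) {
  if (nl > 0 && nr > 0) return 1.0;
  if (nl > 0 || nr > 0) return eps_pe;
  return eps;
}

// update neighbor counts after motor j binds (sign=+1) or unbinds (sign=-1)
void update_counts(NeighborCounts &nc, const std::vector<double> &anchor,
                   int j, int sign, double ell) {
  const int n = (int)anchor.size();
  if (ell <= 0.0) return;
  for (int i = 0; i < n; ++i) {
    if (i == j) continue;
    double dx = anchor[j] - anchor[i];
    if (std::fabs(dx) < ell) {
      if (dx < 0) nc.left[i] += sign; else nc.right[i] += sign;
    }
  }
}

inline double bell_adp_rate(double force_pN, double kD0, double delta,
                            double kBT) {
  double r = kD0 * std::exp(-force_pN * delta / kBT);
  double rmax = kD0 * std::exp(5.0);
  if (r > rmax) r = rmax;
  if (r < 0.0) r = 0.0;
  return r;
}

} // namespace

// Three-bead laser-trap simulation.  One effective bead/filament coordinate
// x (nm) follows an overdamped Langevin equation in the trap spring plus the
// springs of attached motors; between kinetic transitions the process is an
// Ornstein-Uhlenbeck process which is discretised exactly.  Kinetic
// transitions are evaluated per step with probability rate*dt.
// [[Rcpp::export]]
List cpp_trap_simulate(NumericVector anchor_nm, double k_trap, double gamma,
                       double dt, double duration_s, int sample_every,
                       double atp_uM, double eps, double partial_exponent,
                       double ell_nm, double ka_single, double ka2,
                       double k_ws, double k_m, double d_stroke, double kD0,
                       double delta_nm, double kBT, double kT) {
  const int n = anchor_nm.size();
  const long nsteps = (long)std::llround(duration_s / dt);
  const double eps_pe = std::pow(eps, partial_exponent);

  // stability guard: per-step transition probabilities must stay small
  double max_rate = std::max(std::max(k_ws, kT * atp_uM), kD0);
  if (max_rate * dt >= 0.2)
    stop("rate*dt = %.3f >= 0.2; reduce dt for a stable simulation",
         max_rate * dt);

  std::vector<int> state(n, 0);
  std::vector<double> x0(n, 0.0); // zero-force filament position per motor
  std::vector<double> anchor(anchor_nm.begin(), anchor_nm.end());
  NeighborCounts nc;
  nc.left.assign(n, 0);
  nc.right.assign(n, 0);

  int n_bound = 0;
  double x = 0.0;

  // OU coefficients for the current mechanical configuration
  double k_tot = k_trap, mu = 0.0, a_coef = std::exp(-k_tot * dt / gamma),
         s_coef = std::sqrt(kBT / k_tot * (1.0 - a_coef * a_coef));
  bool dirty = true;

  const long n_samples = nsteps / sample_every;
  NumericVector xs(n_samples);
  long isample = 0;

  // ground-truth bound intervals (any motor strongly bound)
  std::vector<double> ev_start, ev_end, ev_maxx;
  std::vector<int> ev_maxn;
  bool in_event = false;
  double cur_start = 0.0, cur_maxx = 0.0;
  int cur_maxn = 0;

  for (long step = 0; step < nsteps; ++step) {
    if (dirty) {
      k_tot = k_trap;
      double num = 0.0;
      for (int j = 0; j < n; ++j)
        if (state[j] != 0) { k_tot += k_m; num += k_m * x0[j]; }
      mu = num / k_tot;
      a_coef = std::exp(-k_tot * dt / gamma);
      s_coef = std::sqrt(kBT / k_tot * (1.0 - a_coef * a_coef));
      dirty = false;
    }

    // exact OU update of the bead/filament coordinate
    x = mu + (x - mu) * a_coef + s_coef * norm_rand();

    // kinetic transitions, all decided from the state at the start of the step
    int nb0 = n_bound;
    for (int j = 0; j < n; ++j) {
      if (state[j] == 0) {
        double base = (nb0 == 0) ? ka_single : ((nb0 == 1) ? ka2 : k_ws);
        double rate = base * act_factor(nc.left[j], nc.right[j], eps, eps_pe);
        if (unif_rand() < rate * dt) {
          state[j] = 1;
          x0[j] = x + d_stroke; // bind unstrained at current x, then stroke
          ++n_bound;
          update_counts(nc, anchor, j, +1, ell_nm);
          dirty = true;
        }
      } else if (state[j] == 1) {
        double force = k_m * (x0[j] - x); // positive = resisting load
        double rate = bell_adp_rate(force, kD0, delta_nm, kBT);
        if (unif_rand() < rate * dt) state[j] = 2;
      } else { // RIGOR
        if (unif_rand() < kT * atp_uM * dt) {
          state[j] = 0;
          --n_bound;
          update_counts(nc, anchor, j, -1, ell_nm);
          dirty = true;
        }
      }
    }

    // ground-truth event bookkeeping
    if (n_bound > 0 && !in_event) {
      in_event = true;
      cur_start = step * dt;
      cur_maxx = x;
      cur_maxn = n_bound;
    } else if (in_event && n_bound > 0) {
      if (x > cur_maxx) cur_maxx = x;
      if (n_bound > cur_maxn) cur_maxn = n_bound;
    } else if (in_event && n_bound == 0) {
      in_event = false;
      ev_start.push_back(cur_start);
      ev_end.push_back(step * dt);
      ev_maxx.push_back(cur_maxx);
      ev_maxn.push_back(cur_maxn);
    }

    if ((step + 1) % sample_every == 0 && isample < n_samples)
      xs[isample++] = x;
  }
  if (in_event) {
    ev_start.push_back(cur_start);
    ev_end.push_back(nsteps * dt);
    ev_maxx.push_back(cur_maxx);
    ev_maxn.push_back(cur_maxn);
  }

  return List::create(
      _["x"] = xs,
      _["truth"] = DataFrame::create(
          _["t_start_s"] = wrap(ev_start), _["t_end_s"] = wrap(ev_end),
          _["max_x_nm"] = wrap(ev_maxx), _["max_bound"] = wrap(ev_maxn)));
}

// In vitro motility simulation.  The filament is rigid and unloaded; between
// kinetic events it sits quasi-statically at the zero-net-force position of
// the attached motor springs, so all rates are piecewise constant and the
// kinetics are simulated exactly (Gillespie).  Returns the net displacement.
// [[Rcpp::export]]
List cpp_motility_simulate(int n_mot, double spacing_nm, double duration_s,
                           double atp_uM, double eps, double partial_exponent,
                           double ell_nm, double k_ws, double k_m,
                           double d_stroke, double kD0, double delta_nm,
                           double kBT, double kT, bool isometric,
                           double transient_frac) {
  const int n = n_mot;
  const double eps_pe = std::pow(eps, partial_exponent);
  std::vector<double> anchor(n);
  for (int i = 0; i < n; ++i) anchor[i] = i * spacing_nm;

  std::vector<int> state(n, 0);
  std::vector<double> x0(n, 0.0); // zero-force filament offset per motor
  NeighborCounts nc;
  nc.left.assign(n, 0);
  nc.right.assign(n, 0);

  double X = 0.0; // filament offset (nm); fixed at 0 when isometric
  int n_bound = 0;
  double t = 0.0;
  long n_events = 0, n_strokes = 0;

  // time averages (isometric force, bound count), excluding the transient;
  // for motility, X_t0 records the filament position when the transient ends
  const double t_avg0 = transient_frac * duration_s;
  double int_force = 0.0, int_bound = 0.0, t_accum = 0.0;
  double X_t0 = 0.0;
  bool t0_passed = (t_avg0 <= 0.0);

  std::vector<double> rates(3 * n); // per motor one active transition
  for (;;) {
    // filament equilibrium: mean of zero-force positions of attached motors
    if (!isometric) {
      if (n_bound > 0) {
        double s = 0.0;
        for (int j = 0; j < n; ++j)
          if (state[j] != 0) s += x0[j];
        X = s / n_bound;
      }
    }

    double total = 0.0, total_force = 0.0;
    for (int j = 0; j < n; ++j) {
      double r = 0.0;
      if (state[j] == 0) {
        r = k_ws * act_factor(nc.left[j], nc.right[j], eps, eps_pe);
      } else if (state[j] == 1) {
        double force = k_m * (x0[j] - X);
        total_force += force;
        r = bell_adp_rate(force, kD0, delta_nm, kBT);
      } else {
        total_force += k_m * (x0[j] - X);
        r = kT * atp_uM;
      }
      rates[j] = r;
      total += r;
    }

    double dt_ev = (total > 0.0) ? exp_rand() / total : R_PosInf;
    double t_next = t + dt_ev;
    double seg_end = (t_next < duration_s) ? t_next : duration_s;
    if (!t0_passed && seg_end >= t_avg0) {
      X_t0 = X; // X is constant over (t, seg_end)
      t0_passed = true;
    }
    if (seg_end > t_avg0) {
      double w = seg_end - std::max(t, t_avg0);
      int_force += w * total_force;
      int_bound += w * n_bound;
      t_accum += w;
    }
    if (t_next >= duration_s || !R_finite(t_next)) break;
    t = t_next;

    // pick the transition
    double u = unif_rand() * total, acc = 0.0;
    int j = n - 1;
    for (int i = 0; i < n; ++i) {
      acc += rates[i];
      if (u <= acc) { j = i; break; }
    }

    if (state[j] == 0) {
      state[j] = 1;
      x0[j] = X + d_stroke;
      ++n_bound;
      ++n_strokes;
      update_counts(nc, anchor, j, +1, ell_nm);
    } else if (state[j] == 1) {
      state[j] = 2;
    } else {
      state[j] = 0;
      --n_bound;
      update_counts(nc, anchor, j, -1, ell_nm);
    }
    ++n_events;
    R_CheckUserInterrupt();
  }

  return List::create(
      _["displacement_nm"] = X, _["post_transient_nm"] = X - X_t0,
      _["n_events"] = (double)n_events,
      _["n_strokes"] = (double)n_strokes,
      _["mean_force_pN"] = (t_accum > 0) ? int_force / t_accum : NA_REAL,
      _["mean_bound"] = (t_accum > 0) ? int_bound / t_accum : NA_REAL);
}
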