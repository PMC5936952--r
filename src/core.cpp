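#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Lattice conventions (shared with the R layer):
//  - state/trans_up/dysf are L x L integer matrices, [row, col];
//    rows are transverse (periodic), columns longitudinal (open).
//  - cell clock: 0 resting, 1 excited, 2..tau+1 refractory countdown.
//  - trans_up(r, c) == 1 iff the bond between (r, c) and ((r+1) mod L, c)
//    exists. Longitudinal bonds are implicit and complete along each row.
//  - pacemaker cells are column 0 (C++ indexing), fired when t %% T == 0.
//  - electrode coordinates arrive 0-based: cell (r, c) sits at (x=c, y=r).

static inline double minimg(double d, int L) {
  return d - L * std::round(d / L);
}

// forcings applied to the state at time t, before the synchronous update
static void apply_forcings(IntegerMatrix &state, int L, int t, bool pacing,
                           int T, const IntegerVector &ectopic, int ect_period) {
  if (pacing && T > 0 && (t % T) == 0) {
    for (int r = 0; r < L; ++r)
      if (state(r, 0) == 0) state(r, 0) = 1;
  }
  if (ectopic.size() == 2 && ect_period > 0 && (t % ect_period) == 0) {
    int er = ectopic[0], ec = ectopic[1];
    if (state(er, ec) == 0) state(er, ec) = 1;
  }
}

// one synchronous update step: cur -> nxt
static void advance(const IntegerMatrix &cur, IntegerMatrix &nxt,
                    const IntegerMatrix &trans_up, const IntegerMatrix &dysf,
                    int L, int tau, double eps) {
  for (int c = 0; c < L; ++c) {
    for (int r = 0; r < L; ++r) {
      int s = cur(r, c);
      if (s == 0) {
        bool exc =
          (c > 0     && cur(r, c - 1) == 1) ||
          (c < L - 1 && cur(r, c + 1) == 1) ||
          (trans_up(r, c) && cur((r + 1) % L, c) == 1) ||
          (trans_up((r + L - 1) % L, c) && cur((r + L - 1) % L, c) == 1);
        if (exc && dysf(r, c) && eps > 0.0 && unif_rand() < eps) exc = false;
        nxt(r, c) = exc ? 1 : 0;
      } else if (s >= tau + 1) {
        nxt(r, c) = 0;
      } else {
        nxt(r, c) = s + 1;
      }
    }
  }
}

// [[Rcpp::export(name = ".cmp_run_cpp")]]
IntegerMatrix cmp_run_cpp(IntegerMatrix state, IntegerMatrix trans_up,
                          IntegerMatrix dysf, int tau, double eps,
                          int t0, int nsteps, bool pacing, int T,
                          IntegerVector ectopic, int ect_period) {
  int L = state.nrow();
  IntegerMatrix cur = clone(state), nxt(L, L);
  for (int k = 0; k < nsteps; ++k) {
    apply_forcings(cur, L, t0 + k, pacing, T, ectopic, ect_period);
    advance(cur, nxt, trans_up, dysf, L, tau, eps);
    std::swap(cur, nxt);
  }
  return cur;
}

// run until every column has hosted an excitation, the active-cell count
// has exceeded fib_threshold at least once and (when a monitor cell is
// given) the re-entrant circuit is still re-exciting its monitored cell;
// stops early if activity dies out
// [[Rcpp::export(name = ".cmp_init_cpp")]]
List cmp_init_cpp(IntegerMatrix state, IntegerMatrix trans_up,
                  IntegerMatrix dysf, int tau, double eps,
                  int t0, int max_steps, bool pacing, int T,
                  IntegerVector ectopic, int ect_period,
                  double fib_threshold, IntegerVector monitor,
                  int monitor_window) {
  int L = state.nrow();
  IntegerMatrix cur = clone(state), nxt(L, L);
  std::vector<char> col_seen(L, 0);
  bool fib_seen = false;
  bool can_refire = pacing || ectopic.size() == 2;
  bool use_mon = monitor.size() == 2;
  int last_fire = -1;

  auto scan = [&](const IntegerMatrix &s, int k) {
    int n_exc = 0;
    for (int c = 0; c < L; ++c)
      for (int r = 0; r < L; ++r)
        if (s(r, c) == 1) { ++n_exc; col_seen[c] = 1; }
    if (n_exc > fib_threshold) fib_seen = true;
    if (use_mon && s(monitor[0], monitor[1]) == 1) last_fire = k;
    return n_exc;
  };
  auto done = [&](int k) {
    if (!fib_seen) return false;
    if (use_mon && (last_fire < 0 || k - last_fire > monitor_window))
      return false;
    for (int c = 0; c < L; ++c) if (!col_seen[c]) return false;
    return true;
  };

  int n_exc = scan(cur, 0);
  int k = 0;
  std::string reason = "max_steps";
  for (; k < max_steps; ++k) {
    if (done(k)) { reason = "ok"; break; }
    if (n_exc == 0 && !can_refire) { reason = "extinguished"; break; }
    apply_forcings(cur, L, t0 + k, pacing, T, ectopic, ect_period);
    advance(cur, nxt, trans_up, dysf, L, tau, eps);
    std::swap(cur, nxt);
    n_exc = scan(cur, k + 1);
  }
  if (reason == "max_steps" && done(k)) reason = "ok";
  return List::create(_["state"] = cur, _["t_ready"] = k,
                      _["success"] = (reason == "ok"), _["reason"] = reason);
}

struct WeightList {
  std::vector<int> i, j;
  std::vector<double> w;
};

// unipolar kernel weights for one electrode: current-dipole sum over coupled
// pairs, w = ((r_i - r_j) . (r_m - r_e)) / |r_m - r_e|^3, truncated at cutoff
static WeightList build_weights(const IntegerMatrix &trans_up, int L,
                                double ex, double ey, double h, double cutoff) {
  WeightList wl;
  double c2 = cutoff * cutoff, h2 = h * h;
  int cmin = std::max(0, (int)std::floor(ex - cutoff) - 1);
  int cmax = std::min(L - 1, (int)std::ceil(ex + cutoff) + 1);
  bool all_rows = (2.0 * cutoff + 2.0 >= L);
  int rspan = all_rows ? L : (2 * ((int)std::ceil(cutoff) + 1) + 1);
  int rbase = all_rows ? 0 : (int)std::floor(ey) - ((int)std::ceil(cutoff) + 1);

  for (int c = cmin; c <= cmax; ++c) {
    for (int rr = 0; rr < rspan; ++rr) {
      int r = ((rbase + rr) % L + L) % L;
      // longitudinal bond (r, c) - (r, c + 1)
      if (c < L - 1) {
        double dx = c + 0.5 - ex, dy = minimg(r - ey, L);
        double r2 = dx * dx + dy * dy;
        if (r2 <= c2) {
          wl.i.push_back(r + L * c);
          wl.j.push_back(r + L * (c + 1));
          wl.w.push_back(-dx / std::pow(r2 + h2, 1.5));
        }
      }
      // transverse bond (r, c) - ((r + 1) mod L, c)
      if (trans_up(r, c)) {
        double dx = (double)c - ex, dy = minimg(r + 0.5 - ey, L);
        double r2 = dx * dx + dy * dy;
        if (r2 <= c2) {
          wl.i.push_back(r + L * c);
          wl.j.push_back(((r + 1) % L) + L * c);
          wl.w.push_back(-dy / std::pow(r2 + h2, 1.5));
        }
      }
    }
  }
  return wl;
}

static void potential_field(const IntegerMatrix &state, int L, int tau,
                            std::vector<double> &u) {
  for (int idx = 0; idx < L * L; ++idx) {
    int s = state[idx];
    u[idx] = (s == 0) ? 0.0 : (s == 1 ? 1.0 : 1.0 - (double)(s - 1) / tau);
  }
}

// advance `duration` steps, sampling every electrode after each update
// [[Rcpp::export(name = ".cmp_record_cpp")]]
List cmp_record_cpp(IntegerMatrix state, IntegerMatrix trans_up,
                    IntegerMatrix dysf, int tau, double eps,
                    int t0, int duration, bool pacing, int T,
                    IntegerVector ectopic, int ect_period,
                    NumericVector ex, NumericVector ey,
                    double h, double cutoff) {
  int L = state.nrow(), nE = ex.size();
  std::vector<WeightList> wls(nE);
  for (int e = 0; e < nE; ++e)
    wls[e] = build_weights(trans_up, L, ex[e], ey[e], h, cutoff);

  IntegerMatrix cur = clone(state), nxt(L, L);
  NumericMatrix V(duration, nE);
  std::vector<double> u(L * L);
  for (int k = 0; k < duration; ++k) {
    apply_forcings(cur, L, t0 + k, pacing, T, ectopic, ect_period);
    advance(cur, nxt, trans_up, dysf, L, tau, eps);
    std::swap(cur, nxt);
    potential_field(cur, L, tau, u);
    for (int e = 0; e < nE; ++e) {
      const WeightList &wl = wls[e];
      double phi = 0.0;
      size_t n = wl.w.size();
      for (size_t b = 0; b < n; ++b)
        phi += wl.w[b] * (u[wl.i[b]] - u[wl.j[b]]);
      V(k, e) = phi;
    }
  }
  return List::create(_["voltages"] = V, _["state"] = cur);
}

// single-snapshot electrogram sample (no time stepping)
// [[Rcpp::export(name = ".egm_sample_cpp")]]
double egm_sample_cpp(IntegerMatrix state, IntegerMatrix trans_up, int tau,
                      double ex, double ey, double h, double cutoff) {
  int L = state.nrow();
  WeightList wl = build_weights(trans_up, L, ex, ey, h, cutoff);
  std::vector<double> u(L * L);
  potential_field(state, L, tau, u);
  double phi = 0.0;
  for (size_t b = 0; b < wl.w.size(); ++b)
    phi += wl.w[b] * (u[wl.i[b]] - u[wl.j[b]]);
  return phi;
}

// count of excited cells
// [[Rcpp::export(name = ".cmp_count_active_cpp")]]
int cmp_count_active_cpp(IntegerMatrix state) {
  int n = 0;
  for (int idx = 0; idx < state.size(); ++idx)
    if (state[idx] == 1) ++n;
  return n;
}
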