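#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Counter-based substreams: replicate r of master seed s gets its own
// xoshiro256++ state, seeded through splitmix64 from (s, r).  The generator
// is pinned so that trajectories are bit-reproducible across platforms and
// replicates can be computed in any order.
struct Xoshiro {
  uint64_t s[4];
  Xoshiro(uint64_t seed, uint64_t rep) {
    uint64_t x = seed ^ (0x9E3779B97F4A7C15ULL * (rep + 1));
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  // uniform on (0, 1]; never 0 so -log(u) is finite
  double u01() { return ((next() >> 11) + 1) * (1.0 / 9007199254740992.0); }
  double rexp() { return -std::log(u01()); }
};

// run status codes
enum { RUN_EXTINCT = 0, RUN_TMAX = 1, RUN_ARRIVAL = 2, RUN_CAPPED = 3 };

struct RunOut {
  std::vector<double> grid_state;   // n x G, column = grid point (state just before any event at that instant)
  std::vector<double> ev_times;
  std::vector<double> ev_state;     // n x n_events, state just after each event
  std::vector<double> arrival;      // first time each type is present (NA if never)
  std::vector<double> extinct;      // last time each type was present (NA if never present or still alive)
  std::vector<int>    alive_end;    // type alive when the run stopped
  double t_end, n_events;
  int status;
};

static void run_one(const double* birth, const double* death, const double* mut,
                    const double* init, int n, double t_max,
                    const double* grid, int G,
                    bool record_events, bool stop_on_arrival,
                    double max_events, double max_cells,
                    Xoshiro& rng, RunOut& out) {
  std::vector<double> z(init, init + n);
  out.arrival.assign(n, NA_REAL);
  out.extinct.assign(n, NA_REAL);
  out.alive_end.assign(n, 0);
  out.grid_state.assign(static_cast<size_t>(n) * G, NA_REAL);
  out.ev_times.clear(); out.ev_state.clear();
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    if (z[i] > 0) out.arrival[i] = 0.0;
    total += z[i];
  }
  double t = 0.0, events = 0.0;
  int g = 0;
  int status = RUN_EXTINCT;

  for (;;) {
    double lambda = 0.0;
    for (int i = 0; i < n; ++i) lambda += (birth[i] + death[i] + mut[i]) * z[i];
    if (lambda <= 0.0) { status = RUN_EXTINCT; break; }
    double tnew = t + rng.rexp() / lambda;
    if (R_FINITE(t_max) && tnew >= t_max) {
      // no further event before the horizon
      while (g < G && grid[g] <= t_max) {
        for (int i = 0; i < n; ++i) out.grid_state[(size_t)g * n + i] = z[i];
        ++g;
      }
      t = t_max; status = RUN_TMAX; break;
    }
    // record grid points passed, left-continuously (pre-event state,
    // including a grid point coinciding exactly with the event time)
    while (g < G && grid[g] <= tnew) {
      for (int i = 0; i < n; ++i) out.grid_state[(size_t)g * n + i] = z[i];
      ++g;
    }
    // pick the event proportionally to its propensity
    double u = rng.u01() * lambda;
    int type = -1, kind = -1; // kind 0 birth, 1 death, 2 mutation
    for (int i = 0; i < n && kind < 0; ++i) {
      double a = birth[i] * z[i];
      if (u < a) { type = i; kind = 0; break; }
      u -= a;
      a = death[i] * z[i];
      if (u < a) { type = i; kind = 1; break; }
      u -= a;
      a = mut[i] * z[i];
      if (u < a) { type = i; kind = 2; break; }
      u -= a;
    }
    if (kind < 0) { type = n - 1; kind = 1; } // round-off fallthrough
    t = tnew; events += 1.0;
    if (kind == 0) {
      z[type] += 1.0; total += 1.0;
    } else {
      z[type] -= 1.0; total -= 1.0;
      if (z[type] <= 0.0) out.extinct[type] = t;
      if (kind == 2 && type + 1 < n) {
        if (z[type + 1] <= 0.0 && ISNA(out.arrival[type + 1])) out.arrival[type + 1] = t;
        z[type + 1] += 1.0; total += 1.0;
      }
    }
    if (record_events) {
      out.ev_times.push_back(t);
      for (int i = 0; i < n; ++i) out.ev_state.push_back(z[i]);
    }
    if (stop_on_arrival && z[n - 1] > 0.0) { status = RUN_ARRIVAL; break; }
    if (events >= max_events || total > max_cells) { status = RUN_CAPPED; break; }
  }

  if (status == RUN_EXTINCT) {
    // population frozen at zero (or all-absorbing): remaining grid points
    // keep the final state
    while (g < G) {
      for (int i = 0; i < n; ++i) out.grid_state[(size_t)g * n + i] = z[i];
      ++g;
    }
  }
  for (int i = 0; i < n; ++i) {
    if (z[i] > 0.0) { out.alive_end[i] = 1; out.extinct[i] = NA_REAL; }
  }
  out.t_end = t;
  out.n_events = events;
  out.status = status;
}

// [[Rcpp::export]]
List ssa_run_cpp(NumericVector birth, NumericVector death, NumericVector mutation,
                 NumericVector initial, double t_max, NumericVector grid,
                 bool record_events, bool stop_on_arrival,
                 double max_events, double max_cells, int seed, int rep) {
  int n = birth.size(), G = grid.size();
  Xoshiro rng(static_cast<uint64_t>(static_cast<int64_t>(seed)),
              static_cast<uint64_t>(rep));
  RunOut out;
  run_one(REAL(birth), REAL(death), REAL(mutation), REAL(initial), n, t_max,
          REAL(grid), G, record_events, stop_on_arrival, max_events, max_cells,
          rng, out);
  NumericMatrix gm(n, G);
  std::copy(out.grid_state.begin(), out.grid_state.end(), gm.begin());
  int ne = out.ev_times.size();
  NumericMatrix em(n, ne);
  std::copy(out.ev_state.begin(), out.ev_state.end(), em.begin());
  return List::create(
    _["grid_state"] = gm,
    _["event_times"] = NumericVector(out.ev_times.begin(), out.ev_times.end()),
    _["event_state"] = em,
    _["arrival"] = NumericVector(out.arrival.begin(), out.arrival.end()),
    _["extinct"] = NumericVector(out.extinct.begin(), out.extinct.end()),
    _["alive_end"] = IntegerVector(out.alive_end.begin(), out.alive_end.end()),
    _["t_end"] = out.t_end,
    _["n_events"] = out.n_events,
    _["status"] = out.status);
}

// [[Rcpp::export]]
List ssa_ensemble_cpp(NumericVector birth, NumericVector death, NumericVector mutation,
                      NumericVector initial, NumericVector grid, double t_max,
                      int reps, int seed, double max_events, double max_cells,
                      bool stop_on_arrival, bool keep_counts) {
  int n = birth.size(), G = grid.size();
  IntegerVector alive_any(G), alive_last(G);
  NumericMatrix sum_counts(n, G), sumsq_counts(n, G);
  NumericMatrix arrivals(reps, n), extinctions(reps, n);
  LogicalMatrix censored(reps, n);
  IntegerVector status(reps);
  NumericVector n_events(reps);
  NumericMatrix counts_total(keep_counts ? reps : 0, keep_counts ? G : 0);
  NumericMatrix counts_last(keep_counts ? reps : 0, keep_counts ? G : 0);
  RunOut out;
  for (int r = 0; r < reps; ++r) {
    if (r % 4096 == 0) Rcpp::checkUserInterrupt();
    Xoshiro rng(static_cast<uint64_t>(static_cast<int64_t>(seed)),
                static_cast<uint64_t>(r + 1));
    run_one(REAL(birth), REAL(death), REAL(mutation), REAL(initial), n, t_max,
            REAL(grid), G, false, stop_on_arrival, max_events, max_cells,
            rng, out);
    for (int g = 0; g < G; ++g) {
      double tot = 0.0;
      const double* st = &out.grid_state[(size_t)g * n];
      for (int i = 0; i < n; ++i) {
        double v = st[i];
        tot += v;
        sum_counts(i, g) += v;
        sumsq_counts(i, g) += v * v;
      }
      if (tot > 0.0) ++alive_any[g];
      if (st[n - 1] > 0.0) ++alive_last[g];
      if (keep_counts) { counts_total(r, g) = tot; counts_last(r, g) = st[n - 1]; }
    }
    for (int i = 0; i < n; ++i) {
      arrivals(r, i) = out.arrival[i];
      extinctions(r, i) = out.extinct[i];
      censored(r, i) = out.alive_end[i] == 1;
    }
    status[r] = out.status;
    n_events[r] = out.n_events;
  }
  return List::create(
    _["alive_any"] = alive_any, _["alive_last"] = alive_last,
    _["sum_counts"] = sum_counts, _["sumsq_counts"] = sumsq_counts,
    _["arrivals"] = arrivals, _["extinctions"] = extinctions,
    _["censored"] = censored, _["status"] = status, _["n_events"] = n_events,
    _["counts_total"] = counts_total, _["counts_last"] = counts_last);
}
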