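#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Rate families shared with the R side (see R/reaction.R):
//   1 constant:     k
//   2 linear:       k * x[i]
//   3 hill:         hill(lam, n, K)(x[i])
//   4 hill_const:   hill(lam, n, K)(x[i]) + c
//   5 hill_linear:  hill(lam, n, K)(x[i]) + c * x[j]
//   6 dimer:        gam * x[i] * (x[i] - 1)
// par row layout: (p1, p2, p3, i, p5, j) with i, j 1-based species indices.

static inline double hill_val(double x, double lam, double n, double K) {
  if (n == 0.0) return lam / 2.0;             // continuity convention at n = 0
  if (n > 0.0) {
    if (x <= 0.0) return 0.0;
    double xn = std::pow(x, n), Kn = std::pow(K, n);
    return lam * xn / (Kn + xn);
  }
  double m = -n;                              // repression written without x^n at x = 0
  if (x <= 0.0) return lam;
  double xm = std::pow(x, m), Km = std::pow(K, m);
  return lam * Km / (Km + xm);
}

struct RateTable {
  // memoized hill part per reaction, indexed by integer abundance
  std::vector<double> memo;
  void ensure(int x, double lam, double n, double K) {
    if ((int)memo.size() <= x) {
      int old = memo.size();
      memo.resize(x + 1);
      for (int v = old; v <= x; ++v) memo[v] = hill_val((double)v, lam, n, K);
    }
  }
};

class Propensities {
public:
  int R;
  const IntegerVector type;
  const NumericMatrix par;
  std::vector<RateTable> tabs;
  Propensities(IntegerVector type_, NumericMatrix par_)
    : R(type_.size()), type(type_), par(par_), tabs(type_.size()) {}

  double eval(int k, const std::vector<int>& x) {
    double p1 = par(k, 0), p2 = par(k, 1), p3 = par(k, 2);
    int i = (int)par(k, 3) - 1;
    double p5 = par(k, 4);
    int j = (int)par(k, 5) - 1;
    switch (type[k]) {
    case 1: return p1;
    case 2: return p1 * x[i];
    case 3: {
      tabs[k].ensure(x[i], p1, p2, p3);
      return tabs[k].memo[x[i]];
    }
    case 4: {
      tabs[k].ensure(x[i], p1, p2, p3);
      return tabs[k].memo[x[i]] + p5;
    }
    case 5: {
      tabs[k].ensure(x[i], p1, p2, p3);
      return tabs[k].memo[x[i]] + p5 * x[j];
    }
    case 6: {
      double v = (double)x[i];
      return p1 * v * (v - 1.0);
    }
    default: stop("unknown rate type code");
    }
    return 0.0;
  }
};

// Draw stationary-regime snapshots of the observed pair from one long
// exact (Doob-Gillespie) trajectory.
// [[Rcpp::export]]
List ssa_snapshots_cpp(IntegerVector x0, IntegerMatrix stoich, IntegerVector type,
                       NumericMatrix par, NumericVector speed,
                       double burn_in, double interval, int n_snap,
                       int obs_i, int obs_j) {
  int S = x0.size(), R = stoich.nrow();
  std::vector<int> x(S);
  for (int s = 0; s < S; ++s) x[s] = x0[s];
  Propensities prop(type, par);
  std::vector<double> a(R);
  IntegerMatrix out(n_snap, 2);
  double t = 0.0, t_next = burn_in;
  int rec = 0;
  bool absorbed = false;
  RNGScope scope;
  while (rec < n_snap) {
    double atot = 0.0;
    for (int k = 0; k < R; ++k) {
      a[k] = speed[k] * prop.eval(k, x);
      atot += a[k];
    }
    if (atot <= 0.0) { absorbed = true; break; }
    double dt = ::Rf_rexp(1.0) / atot;
    double t_event = t + dt;
    while (rec < n_snap && t_next <= t_event) {
      out(rec, 0) = x[obs_i - 1];
      out(rec, 1) = x[obs_j - 1];
      ++rec;
      t_next += interval;
    }
    if (rec >= n_snap) break;
    double u = ::unif_rand() * atot, acc = 0.0;
    int k = R - 1;
    for (int kk = 0; kk < R; ++kk) {
      acc += a[kk];
      if (u <= acc) { k = kk; break; }
    }
    for (int s = 0; s < S; ++s) x[s] += stoich(k, s);
    t = t_event;
  }
  if (absorbed) { // absorbing state is stationary: remaining snapshots record it
    while (rec < n_snap) {
      out(rec, 0) = x[obs_i - 1];
      out(rec, 1) = x[obs_j - 1];
      ++rec;
    }
  }
  IntegerVector xfin(S);
  for (int s = 0; s < S; ++s) xfin[s] = x[s];
  return List::create(_["samples"] = out, _["absorbed"] = absorbed,
                      _["t_end"] = t, _["final_state"] = xfin);
}

// Full event-resolved trajectory (states after each event, plus t = 0 row).
// [[Rcpp::export]]
List ssa_trajectory_cpp(IntegerVector x0, IntegerMatrix stoich, IntegerVector type,
                        NumericMatrix par, NumericVector speed,
                        double t_end, double max_events) {
  int S = x0.size(), R = stoich.nrow();
  std::vector<int> x(S);
  for (int s = 0; s < S; ++s) x[s] = x0[s];
  Propensities prop(type, par);
  std::vector<double> a(R);
  std::vector<double> times;
  std::vector<int> states;
  times.push_back(0.0);
  for (int s = 0; s < S; ++s) states.push_back(x[s]);
  double t = 0.0;
  bool absorbed = false, truncated = false;
  RNGScope scope;
  while (true) {
    if ((double)times.size() > max_events) { truncated = true; break; }
    double atot = 0.0;
    for (int k = 0; k < R; ++k) {
      a[k] = speed[k] * prop.eval(k, x);
      atot += a[k];
    }
    if (atot <= 0.0) { absorbed = true; break; }
    double dt = ::Rf_rexp(1.0) / atot;
    if (t + dt > t_end) { t = t_end; break; }
    t += dt;
    double u = ::unif_rand() * atot, acc = 0.0;
    int k = R - 1;
    for (int kk = 0; kk < R; ++kk) {
      acc += a[kk];
      if (u <= acc) { k = kk; break; }
    }
    for (int s = 0; s < S; ++s) x[s] += stoich(k, s);
    times.push_back(t);
    for (int s = 0; s < S; ++s) states.push_back(x[s]);
  }
  int n = times.size();
  NumericVector tv(times.begin(), times.end());
  IntegerMatrix sm(n, S);
  for (int r = 0; r < n; ++r)
    for (int s = 0; s < S; ++s) sm(r, s) = states[(size_t)r * S + s];
  return List::create(_["time"] = tv, _["state"] = sm,
                      _["absorbed"] = absorbed, _["truncated"] = truncated,
                      _["t_end"] = t);
}
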