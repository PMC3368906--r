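#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Discrete-time lifetime simulation of one parasitoid female on the
// cost-scaled longevity-fecundity trade-off.  All stochasticity (the
// natal-patch Bernoulli draw) goes through R's RNG so set.seed() governs
// the whole pipeline.  The R functions init_female()/step_female() mirror
// this arithmetic exactly; test-lifetime.R asserts bit-level agreement.

namespace {

struct EnvPars {
  double g1, g2, g3;
  double n0, alpha;
  int    travel_time;
  double p_natal, cost;
  double max_long, max_egg, max_plast;
  int    bounds_upper;      // 0 = centered on scaled g1, 1 = one-sided
  int    realloc_patch;     // 0 = every step, 1 = only at patch transitions
  int    leave_learned;     // 0 = analytic MVT rate, 1 = learned-mu rule
};

struct Derived {
  double scale, eff_l, eff_e, lo, hi, p0;
  int    t1, t_star;
  double rate_max, mu0;
  bool   stillborn;         // scale <= 0: no budget at all
};

int first_host_time(double n0, double alpha) {
  if (n0 <= 1.0) stop("patch can never yield a host (asymptote below one)");
  double raw = std::ceil(-std::log(1.0 - 1.0 / n0) / alpha);
  int t1 = (int) raw;
  if (t1 < 1) t1 = 1;
  while (t1 > 1 && n0 * (1.0 - std::exp(-alpha * (t1 - 1))) >= 1.0) --t1;
  while (n0 * (1.0 - std::exp(-alpha * t1)) < 1.0) ++t1;
  return t1;
}

int mvt_time(double alpha, double travel_time) {
  // rate(t) <= N(t)/(t+T)  <=>  alpha*e^{-at}(t+T) <= 1 - e^{-at}; n0 cancels
  for (int t = 1; t <= 10000000; ++t) {
    double e = std::exp(-alpha * t);
    if (alpha * e * (t + travel_time) <= 1.0 - e) return t;
  }
  stop("no MVT crossing found (degenerate gain curve)");
}

Derived derive(const EnvPars &ep) {
  Derived d;
  d.scale = 1.0 - ep.cost * ep.g2 / ep.max_plast;
  d.stillborn = (d.scale <= 0.0);
  if (d.stillborn) {
    d.eff_l = d.eff_e = d.lo = d.hi = d.p0 = 0.0;
    d.t1 = 1; d.rate_max = 1.0; d.mu0 = 0.5; d.t_star = 1;
    return d;
  }
  d.eff_l = d.scale * ep.max_long;
  d.eff_e = d.scale * ep.max_egg;
  double w   = ep.g2 * d.scale; if (w > d.eff_l) w = d.eff_l;
  double g1s = ep.g1 * d.scale;
  double lo  = ep.bounds_upper ? g1s : g1s - w / 2.0;
  if (lo < 0.0) lo = 0.0;
  if (lo + w > d.eff_l) lo = d.eff_l - w;
  d.lo = lo; d.hi = lo + w;
  d.p0 = g1s;
  if (d.p0 < d.lo) d.p0 = d.lo;
  if (d.p0 > d.hi) d.p0 = d.hi;
  d.t1 = first_host_time(ep.n0, ep.alpha);
  d.rate_max = 1.0 / d.t1;
  d.mu0 = d.rate_max / 2.0;
  d.t_star = mvt_time(ep.alpha, ep.travel_time);
  return d;
}

struct Female {
  int    time_lived, progeny, phase, travel_rem, patch_clock;
  double rem_life, eggs_rem, acc, mu;
};

const int TRAVEL = 0, FORAGE = 1;

void init_female(Female &f, const EnvPars &ep, const Derived &d) {
  f.time_lived = 0; f.progeny = 0;
  f.rem_life = d.p0;
  f.eggs_rem = d.stillborn ? 0.0 : d.eff_e * (1.0 - d.p0 / d.eff_l);
  f.acc = 0.0; f.mu = d.mu0; f.patch_clock = 0;
  double u = unif_rand();
  if (u < ep.p_natal) { f.phase = FORAGE; f.travel_rem = 0; }
  else                { f.phase = TRAVEL; f.travel_rem = ep.travel_time; }
}

void reallocate(Female &f, const EnvPars &ep, const Derived &d) {
  double frac = f.mu / d.rate_max; if (frac > 1.0) frac = 1.0;
  double target  = d.hi - frac * (d.hi - d.lo);
  double unspent = f.rem_life / d.eff_l + f.eggs_rem / d.eff_e;
  double at = target - f.time_lived;
  if (at < 0.0) at = 0.0;
  double at_max = unspent * d.eff_l;
  if (at > at_max) at = at_max;
  f.rem_life = at;
  f.eggs_rem = (unspent - at / d.eff_l) * d.eff_e;
}

// One time step; returns lambda observed (for traces).
double step_female(Female &f, const EnvPars &ep, const Derived &d) {
  f.time_lived += 1;
  f.rem_life   -= 1.0;
  double lambda = 0.0;
  bool arrived = false;
  if (f.phase == TRAVEL) {
    f.travel_rem -= 1;
    if (f.travel_rem <= 0) {
      f.phase = FORAGE; f.patch_clock = 0; f.acc = 0.0;
      arrived = true;
    }
  } else {
    f.patch_clock += 1;
    double pc = f.patch_clock;
    double dn = ep.n0 * (std::exp(-ep.alpha * (pc - 1.0)) -
                         std::exp(-ep.alpha * pc));
    f.acc += dn;
    double k = std::floor(f.acc);
    double kmax = std::floor(f.eggs_rem);
    bool limited = (k > kmax);
    if (limited) k = kmax;
    if (k > 0.0) {
      f.acc      -= k;
      f.eggs_rem -= k;
      f.progeny  += (int) k;
    }
    if (limited) f.acc = f.acc - std::floor(f.acc); // surplus hosts lost
    lambda = (dn < d.rate_max) ? dn : d.rate_max;
  }
  f.mu = ep.g3 * f.mu + (1.0 - ep.g3) * lambda;
  if (!ep.realloc_patch) reallocate(f, ep, d);
  bool left = false;
  if (f.phase == FORAGE && f.patch_clock >= 1) {
    bool at_threshold;
    if (ep.leave_learned) {
      // leave once the local gain rate falls below the learned estimate
      // of the environment-wide rate
      double pc = f.patch_clock;
      double dn = ep.n0 * (std::exp(-ep.alpha * (pc - 1.0)) -
                           std::exp(-ep.alpha * pc));
      at_threshold = (dn <= f.mu);
    } else {
      // analytic variant: the patch-independent MVT crossing time
      at_threshold = (f.patch_clock >= d.t_star);
    }
    if (at_threshold && f.rem_life >= ep.travel_time) {
      f.phase = TRAVEL; f.travel_rem = ep.travel_time;
      f.patch_clock = 0; f.acc = 0.0;
      left = true;
    }
  }
  if (ep.realloc_patch && (arrived || left)) reallocate(f, ep, d);
  return lambda;
}

EnvPars make_pars(double g1, double g2, double g3, double n0, int travel_time,
                  double p_natal, double cost, double alpha,
                  double max_longevity, double max_eggload,
                  int bounds_upper, int realloc_patch, int leave_learned) {
  EnvPars ep;
  ep.g1 = g1; ep.g2 = g2; ep.g3 = g3;
  ep.n0 = n0; ep.alpha = alpha; ep.travel_time = travel_time;
  ep.p_natal = p_natal; ep.cost = cost;
  ep.max_long = max_longevity; ep.max_egg = max_eggload;
  ep.max_plast = max_longevity;
  ep.bounds_upper = bounds_upper;
  ep.realloc_patch = realloc_patch;
  ep.leave_learned = leave_learned;
  return ep;
}

} // namespace

// [[Rcpp::export]]
List sim_generation_cpp(double g1, double g2, double g3,
                        double n0, int travel_time, double p_natal,
                        double cost, double alpha,
                        double max_longevity, double max_eggload,
                        int bounds_upper, int realloc_patch,
                        int leave_learned, bool trace) {
  EnvPars ep = make_pars(g1, g2, g3, n0, travel_time, p_natal, cost, alpha,
                         max_longevity, max_eggload, bounds_upper,
                         realloc_patch, leave_learned);
  Derived d = derive(ep);
  Female f;
  init_female(f, ep, d);

  std::vector<double> tr_time, tr_phase, tr_pos, tr_mu, tr_eggs, tr_rem,
      tr_prog, tr_lambda;
  if (d.stillborn) {
    f.rem_life = 0.0;
  }
  while (f.rem_life >= 1.0) {
    double lambda = step_female(f, ep, d);
    if (trace) {
      tr_time.push_back(f.time_lived);
      tr_phase.push_back(f.phase);
      tr_pos.push_back(f.time_lived + f.rem_life);
      tr_mu.push_back(f.mu);
      tr_eggs.push_back(f.eggs_rem);
      tr_rem.push_back(f.rem_life);
      tr_prog.push_back(f.progeny);
      tr_lambda.push_back(lambda);
    }
    if (f.time_lived > 100000000) stop("runaway lifetime loop");
  }
  List out = List::create(
      _["progeny"]       = f.progeny,
      _["time_lived"]    = f.time_lived,
      _["rem_life"]      = f.rem_life,
      _["eggs_remaining"] = f.eggs_rem,
      _["eff_longevity"] = d.eff_l,
      _["eff_eggload"]   = d.eff_e,
      _["t1"]            = d.t1,
      _["t_star"]        = d.t_star,
      _["lo"]            = d.lo,
      _["hi"]            = d.hi,
      _["mu"]            = f.mu);
  if (trace) {
    out["trace"] = DataFrame::create(
        _["time"]           = tr_time,
        _["phase"]          = tr_phase,
        _["position"]       = tr_pos,
        _["mu"]             = tr_mu,
        _["eggs_remaining"] = tr_eggs,
        _["rem_life"]       = tr_rem,
        _["progeny"]        = tr_prog,
        _["lambda"]         = tr_lambda);
  }
  return out;
}

// [[Rcpp::export]]
double sim_fitness_cpp(double g1, double g2, double g3,
                       double n0, int travel_time, double p_natal,
                       double cost, double alpha,
                       double max_longevity, double max_eggload,
                       int bounds_upper, int realloc_patch,
                       int leave_learned, int n_generations) {
  EnvPars ep = make_pars(g1, g2, g3, n0, travel_time, p_natal, cost, alpha,
                         max_longevity, max_eggload, bounds_upper,
                         realloc_patch, leave_learned);
  Derived d = derive(ep);
  double total = 0.0;
  for (int g = 0; g < n_generations; ++g) {
    Female f;
    init_female(f, ep, d);
    if (d.stillborn) f.rem_life = 0.0;
    while (f.rem_life >= 1.0) {
      step_female(f, ep, d);
      if (f.time_lived > 100000000) stop("runaway lifetime loop");
    }
    total += f.progeny;
  }
  return total / n_generations;
}
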