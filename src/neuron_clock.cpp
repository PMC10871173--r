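#include <Rcpp.h>
using namespace Rcpp;

// Clock-driven single-neuron integrators for the Izhikevich and
// Hodgkin-Huxley models with alpha-shaped postsynaptic currents.
//
// The alpha current for one event of weight w (peak current) is
//   alpha(t) = (w e / tau) t exp(-t / tau),
// realized as the linear cascade  h' = -h/tau,  I' = -I/tau + h  with the
// event kick h += w e / tau.  Both states admit an exact per-step update,
// so only the voltage equation carries integration error.
//
// Synaptic events arrive either as per-step counts (exc_counts/inh_counts)
// or, when use_rates is true, as Poisson counts sampled each step from
// rate_exc and rate_inh (kHz) using R's RNG.

struct AlphaSyn {
  double h, I, tau, decay, kick;
  void init(double tau_syn, double w, double dt) {
    h = I = 0.0;
    tau = tau_syn;
    decay = std::exp(-dt / tau_syn);
    kick = w * M_E / tau_syn;
  }
  void step(double dt, int k) {
    I = (I + h * dt) * decay;
    h = h * decay + k * kick;
  }
};

static inline int syn_count(bool use_rates, double lam,
                            const IntegerVector &counts, long s) {
  if (use_rates) return (int)R::rpois(lam);
  return s < counts.size() ? counts[(R_xlen_t)s] : 0;
}

// [[Rcpp::export]]
NumericVector cpp_izhikevich(double a, double b, double c, double d,
                             double tau_e, double tau_i,
                             IntegerVector exc_counts, IntegerVector inh_counts,
                             bool use_rates, double rate_exc, double rate_inh,
                             double w_exc, double w_inh, double i_const,
                             double duration, double dt) {
  const long n_steps = (long)std::ceil(duration / dt);
  const double lam_e = rate_exc * dt, lam_i = rate_inh * dt;
  AlphaSyn se, si;
  se.init(tau_e, w_exc, dt);
  si.init(tau_i, w_inh, dt);
  double v = c, u = b * c;
  std::vector<double> spikes;
  for (long s = 0; s < n_steps; ++s) {
    se.step(dt, syn_count(use_rates, lam_e, exc_counts, s));
    si.step(dt, syn_count(use_rates, lam_i, inh_counts, s));
    const double I = i_const + se.I - si.I;
    // two half-steps for v as in the model's original description
    v += 0.5 * dt * (0.04 * v * v + 5.0 * v + 140.0 - u + I);
    v += 0.5 * dt * (0.04 * v * v + 5.0 * v + 140.0 - u + I);
    u += dt * a * (b * v - u);
    if (!R_finite(v) || !R_finite(u))
      stop("Izhikevich state diverged at t = %.3f ms (v = %g, u = %g); reduce dt or input weight",
           s * dt, v, u);
    if (v >= 30.0) {
      spikes.push_back((s + 1) * dt);
      v = c;
      u += d;
    }
  }
  return wrap(spikes);
}

// Standard squid-axon rate functions shifted so rest sits near -65 mV.
static inline double an(double V) {
  double x = V + 55.0;
  return std::abs(x) < 1e-7 ? 0.1 : 0.01 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double bn(double V) { return 0.125 * std::exp(-(V + 65.0) / 80.0); }
static inline double am(double V) {
  double x = V + 40.0;
  return std::abs(x) < 1e-7 ? 1.0 : 0.1 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double bm(double V) { return 4.0 * std::exp(-(V + 65.0) / 18.0); }
static inline double ah(double V) { return 0.07 * std::exp(-(V + 65.0) / 20.0); }
static inline double bh(double V) { return 1.0 / (1.0 + std::exp(-(V + 35.0) / 10.0)); }

// [[Rcpp::export]]
NumericVector cpp_hh(double c_m, double g_na, double g_k, double g_l,
                     double e_na, double e_k, double e_l, double t_ref,
                     double tau_e, double tau_i,
                     IntegerVector exc_counts, IntegerVector inh_counts,
                     bool use_rates, double rate_exc, double rate_inh,
                     double w_exc, double w_inh, double i_const,
                     double duration, double dt) {
  const long n_steps = (long)std::ceil(duration / dt);
  const double lam_e = rate_exc * dt, lam_i = rate_inh * dt;
  AlphaSyn se, si;
  se.init(tau_e, w_exc, dt);
  si.init(tau_i, w_inh, dt);
  double V = -65.0;
  double n = an(V) / (an(V) + bn(V));
  double m = am(V) / (am(V) + bm(V));
  double h = ah(V) / (ah(V) + bh(V));
  double lockout_until = -1.0;
  bool above = false;
  std::vector<double> spikes;
  for (long s = 0; s < n_steps; ++s) {
    const double t = (s + 1) * dt;
    se.step(dt, syn_count(use_rates, lam_e, exc_counts, s));
    si.step(dt, syn_count(use_rates, lam_i, inh_counts, s));
    // exponential Euler for the gating variables
    double tn = 1.0 / (an(V) + bn(V)), ninf = an(V) * tn;
    double tm = 1.0 / (am(V) + bm(V)), minf = am(V) * tm;
    double th = 1.0 / (ah(V) + bh(V)), hinf = ah(V) * th;
    n = ninf + (n - ninf) * std::exp(-dt / tn);
    m = minf + (m - minf) * std::exp(-dt / tm);
    h = hinf + (h - hinf) * std::exp(-dt / th);
    const double I_ion = -g_na * m * m * m * h * (V - e_na)
                         - g_k * n * n * n * n * (V - e_k)
                         - g_l * (V - e_l);
    V += dt * (I_ion + i_const + se.I - si.I) / c_m;
    if (!R_finite(V))
      stop("Hodgkin-Huxley state diverged at t = %.3f ms; reduce dt or input weight", t);
    // spike = upward crossing of 0 mV, with a t_ref detection lockout
    if (V >= 0.0 && !above && t >= lockout_until) {
      spikes.push_back(t);
      lockout_until = t + t_ref;
    }
    above = V >= 0.0;
  }
  return wrap(spikes);
}
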