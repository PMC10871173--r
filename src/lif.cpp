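#include <Rcpp.h>
using namespace Rcpp;

// Leaky integrate-and-fire with delta PSPs.  Units: time ms, voltage mV,
// rates kHz (events per ms).  Between synaptic events the membrane decays
// exponentially toward v_rest, so the event-driven path is exact: no
// discretization error enters beyond floating point.

// [[Rcpp::export]]
NumericVector cpp_lif_event(double tau_m, double v_rest, double v_thresh,
                            double t_ref, NumericVector exc, NumericVector inh,
                            double qe, double qi, double duration) {
  const R_xlen_t ne = exc.size(), ni = inh.size();
  std::vector<double> spikes;
  double v = v_rest, t_cur = 0.0, ref_until = -1.0;
  R_xlen_t ie = 0, ii = 0;
  while (ie < ne || ii < ni) {
    bool is_exc;
    double t;
    if (ii >= ni || (ie < ne && exc[ie] <= inh[ii])) {
      t = exc[ie++]; is_exc = true;
    } else {
      t = inh[ii++]; is_exc = false;
    }
    if (t > duration) break;
    if (t < ref_until) continue;          // state frozen, input discarded
    v = v_rest + (v - v_rest) * std::exp(-(t - t_cur) / tau_m);
    v += is_exc ? qe : -qi;
    t_cur = t;
    if (v >= v_thresh) {
      spikes.push_back(t);
      v = v_rest;
      ref_until = t + t_ref;
      t_cur = ref_until;
    }
  }
  return wrap(spikes);
}

// Clock-driven variant: events are binned onto the dt grid, the decay is
// applied per step with the exact exponential factor, and threshold is
// checked once per step.  Spikes are stamped at the end of their step.

// [[Rcpp::export]]
NumericVector cpp_lif_clock(double tau_m, double v_rest, double v_thresh,
                            double t_ref, NumericVector exc, NumericVector inh,
                            double qe, double qi, double duration, double dt) {
  const long n_steps = (long)std::ceil(duration / dt);
  const double decay = std::exp(-dt / tau_m);
  const long ref_steps = (long)std::lround(t_ref / dt);
  std::vector<double> input((size_t)n_steps, 0.0);
  for (R_xlen_t i = 0; i < exc.size(); ++i) {
    long s = (long)(exc[i] / dt);
    if (s >= 0 && s < n_steps) input[(size_t)s] += qe;
  }
  for (R_xlen_t i = 0; i < inh.size(); ++i) {
    long s = (long)(inh[i] / dt);
    if (s >= 0 && s < n_steps) input[(size_t)s] -= qi;
  }
  std::vector<double> spikes;
  double v = v_rest;
  long ref_count = 0;
  for (long s = 0; s < n_steps; ++s) {
    if (ref_count > 0) { --ref_count; continue; }
    v = v_rest + (v - v_rest) * decay + input[(size_t)s];
    if (v >= v_thresh) {
      spikes.push_back((s + 1) * dt);
      v = v_rest;
      ref_count = ref_steps;
    }
  }
  return wrap(spikes);
}

// Fast transfer-curve point: Poisson excitatory / inhibitory streams are
// generated on the fly (merged stream with exponential waiting times, drawn
// from R's RNG so set.seed() governs reproducibility) and fed through the
// exact event-driven integrator.  Only the spike count is returned.

// Same generator and integrator, but keeping the spike times (used when a
// long measurement must later be truncated to growing time prefixes).

// [[Rcpp::export]]
NumericVector cpp_lif_rate_spikes(double tau_m, double v_rest,
                                  double v_thresh, double t_ref,
                                  double rate_exc, double rate_inh,
                                  double qe, double qi, double duration) {
  const double lambda = rate_exc + rate_inh;
  std::vector<double> spikes;
  if (lambda > 0.0) {
    const double p_exc = rate_exc / lambda;
    double v = v_rest, t = 0.0, t_cur = 0.0, ref_until = -1.0;
    for (;;) {
      t += exp_rand() / lambda;
      if (t > duration) break;
      const bool is_exc = unif_rand() < p_exc;
      if (t < ref_until) continue;
      v = v_rest + (v - v_rest) * std::exp(-(t - t_cur) / tau_m);
      v += is_exc ? qe : -qi;
      t_cur = t;
      if (v >= v_thresh) {
        spikes.push_back(t);
        v = v_rest;
        ref_until = t + t_ref;
        t_cur = ref_until;
      }
    }
  }
  return wrap(spikes);
}

// [[Rcpp::export]]
double cpp_lif_rate_point(double tau_m, double v_rest, double v_thresh,
                          double t_ref, double rate_exc, double rate_inh,
                          double qe, double qi, double duration) {
  const double lambda = rate_exc + rate_inh;
  if (lambda <= 0.0) return 0.0;
  const double p_exc = rate_exc / lambda;
  double v = v_rest, t = 0.0, t_cur = 0.0, ref_until = -1.0;
  double count = 0.0;
  for (;;) {
    t += exp_rand() / lambda;
    if (t > duration) break;
    const bool is_exc = unif_rand() < p_exc;
    if (t < ref_until) continue;
    v = v_rest + (v - v_rest) * std::exp(-(t - t_cur) / tau_m);
    v += is_exc ? qe : -qi;
    t_cur = t;
    if (v >= v_thresh) {
      count += 1.0;
      v = v_rest;
      ref_until = t + t_ref;
      t_cur = ref_until;
    }
  }
  return count;
}
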