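#include <Rcpp.h>
using namespace Rcpp;

// Recurrent-network simulator.  One clock-driven loop serves three neuron
// models (0 = LIF with delta PSPs, 1 = Izhikevich, 2 = Hodgkin-Huxley, the
// latter two with alpha PSCs).  Spike delivery uses a ring buffer over the
// delay horizon holding per-neuron counts of pending excitatory and
// inhibitory arrivals; background Poisson input is sampled per step as a
// population-total count and assigned to uniformly random neurons, which is
// distributionally identical to independent per-neuron streams.
//
// Connectivity: static mode uses a CSR list of out-edges with per-edge
// delays (in steps); annealed mode delivers each spike to a
// Binomial(M-1, N/M) random subset of distinct other neurons with i.i.d.
// uniform delays, matching the static in-degree in expectation while
// destroying temporal correlations.
//
// Times in ms; background rates in kHz per neuron.  Spikes at t >= warmup
// are returned with times relative to the end of the warm-up window.

static inline double an_(double V) {
  double x = V + 55.0;
  return std::abs(x) < 1e-7 ? 0.1 : 0.01 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double bn_(double V) { return 0.125 * std::exp(-(V + 65.0) / 80.0); }
static inline double am_(double V) {
  double x = V + 40.0;
  return std::abs(x) < 1e-7 ? 1.0 : 0.1 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double bm_(double V) { return 4.0 * std::exp(-(V + 65.0) / 18.0); }
static inline double ah_(double V) { return 0.07 * std::exp(-(V + 65.0) / 20.0); }
static inline double bh_(double V) { return 1.0 / (1.0 + std::exp(-(V + 35.0) / 10.0)); }

// [[Rcpp::export]]
List cpp_network(int model_id, NumericVector pars,
                 int M, LogicalVector is_exc,
                 IntegerVector edge_offsets, IntegerVector edge_targets,
                 IntegerVector edge_delays,
                 bool annealed, double p_deliver,
                 int delay_min_steps, int delay_max_steps,
                 double qe, double qi, double w_exc, double w_inh,
                 double eta, double r_bg, double stim_amp, double stim_freq,
                 double warmup, double warmup_amp,
                 double duration, double dt, double max_spikes) {
  const long n_steps = (long)std::ceil((warmup + duration) / dt);
  const int L = delay_max_steps + 2;

  // per-neuron state
  std::vector<double> v((size_t)M), u, he, Ie, hi, Ii, gn, gm, gh;
  std::vector<long> ref((size_t)M, 0);
  std::vector<double> lockout((size_t)M, -1.0);
  std::vector<char> above((size_t)M, 0);

  // model parameters
  double tau_m = 0, v_rest = 0, v_thresh = 0, t_ref = 0, decay = 0;
  double iz_a = 0, iz_b = 0, iz_c = 0, iz_d = 0;
  double c_m = 0, g_na = 0, g_k = 0, g_l = 0, e_na = 0, e_k = 0, e_l = 0;
  double tau_e = 1, tau_i = 1, de = 1, di = 1, kick_e = 0, kick_i = 0;
  long ref_steps = 0;

  if (model_id == 0) {
    tau_m = pars[0]; v_rest = pars[1]; v_thresh = pars[2]; t_ref = pars[3];
    decay = std::exp(-dt / tau_m);
    ref_steps = (long)std::lround(t_ref / dt);
    std::fill(v.begin(), v.end(), v_rest);
  } else {
    tau_e = pars[model_id == 1 ? 4 : 8];
    tau_i = pars[model_id == 1 ? 5 : 9];
    de = std::exp(-dt / tau_e);
    di = std::exp(-dt / tau_i);
    kick_e = w_exc * M_E / tau_e;
    kick_i = w_inh * M_E / tau_i;
    he.assign((size_t)M, 0.0); Ie.assign((size_t)M, 0.0);
    hi.assign((size_t)M, 0.0); Ii.assign((size_t)M, 0.0);
    if (model_id == 1) {
      iz_a = pars[0]; iz_b = pars[1]; iz_c = pars[2]; iz_d = pars[3];
      std::fill(v.begin(), v.end(), iz_c);
      u.assign((size_t)M, iz_b * iz_c);
    } else {
      c_m = pars[0]; g_na = pars[1]; g_k = pars[2]; g_l = pars[3];
      e_na = pars[4]; e_k = pars[5]; e_l = pars[6]; t_ref = pars[7];
      std::fill(v.begin(), v.end(), -65.0);
      double V0 = -65.0;
      gn.assign((size_t)M, an_(V0) / (an_(V0) + bn_(V0)));
      gm.assign((size_t)M, am_(V0) / (am_(V0) + bm_(V0)));
      gh.assign((size_t)M, ah_(V0) / (ah_(V0) + bh_(V0)));
    }
  }

  // delay ring buffers of pending arrival counts
  std::vector<std::vector<float> > cnt_e((size_t)L), cnt_i((size_t)L);
  for (int l = 0; l < L; ++l) {
    cnt_e[(size_t)l].assign((size_t)M, 0.0f);
    cnt_i[(size_t)l].assign((size_t)M, 0.0f);
  }

  std::vector<double> sp_t;
  std::vector<int> sp_id;
  double warmup_spikes = 0.0, total_spikes = 0.0;

  for (long s = 0; s < n_steps; ++s) {
    const double t = s * dt;
    const int slot = (int)(s % L);
    std::vector<float> &ce = cnt_e[(size_t)slot];
    std::vector<float> &ci = cnt_i[(size_t)slot];

    // background input, population-total Poisson counts
    double rb = r_bg;
    if (stim_amp != 0.0)
      rb += stim_amp * std::sin(2.0 * M_PI * stim_freq * t / 1000.0);
    if (rb < 0.0) rb = 0.0;
    double extra = 0.0;
    if (t < warmup && warmup > 0.0)
      extra = warmup_amp * (1.0 - t / warmup);   // linear ramp down to 0
    const double lam_e = M * (eta * rb + extra) * dt;
    const double lam_i = M * (1.0 - eta) * rb * dt;
    long n_e = (long)R::rpois(lam_e), n_i = (long)R::rpois(lam_i);
    for (long k = 0; k < n_e; ++k)
      ce[(size_t)(unif_rand() * M) % (size_t)M] += 1.0f;
    for (long k = 0; k < n_i; ++k)
      ci[(size_t)(unif_rand() * M) % (size_t)M] += 1.0f;

    for (int i = 0; i < M; ++i) {
      bool spiked = false;
      if (model_id == 0) {
        if (ref[(size_t)i] > 0) { --ref[(size_t)i]; continue; }
        double vi = v_rest + (v[(size_t)i] - v_rest) * decay
                    + ce[(size_t)i] * qe - ci[(size_t)i] * qi;
        if (vi >= v_thresh) {
          spiked = true;
          vi = v_rest;
          ref[(size_t)i] = ref_steps;
        }
        v[(size_t)i] = vi;
      } else {
        Ie[(size_t)i] = (Ie[(size_t)i] + he[(size_t)i] * dt) * de;
        he[(size_t)i] = he[(size_t)i] * de + ce[(size_t)i] * kick_e;
        Ii[(size_t)i] = (Ii[(size_t)i] + hi[(size_t)i] * dt) * di;
        hi[(size_t)i] = hi[(size_t)i] * di + ci[(size_t)i] * kick_i;
        const double I = Ie[(size_t)i] - Ii[(size_t)i];
        if (model_id == 1) {
          double vi = v[(size_t)i], ui = u[(size_t)i];
          vi += 0.5 * dt * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + I);
          vi += 0.5 * dt * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + I);
          ui += dt * iz_a * (iz_b * vi - ui);
          if (!R_finite(vi))
            stop("network state diverged (neuron %d, t = %.2f ms)", i + 1, t);
          if (vi >= 30.0) { spiked = true; vi = iz_c; ui += iz_d; }
          v[(size_t)i] = vi; u[(size_t)i] = ui;
        } else {
          double V = v[(size_t)i];
          double tn = 1.0 / (an_(V) + bn_(V)), ninf = an_(V) * tn;
          double tm = 1.0 / (am_(V) + bm_(V)), minf = am_(V) * tm;
          double th = 1.0 / (ah_(V) + bh_(V)), hinf = ah_(V) * th;
          double n2 = ninf + (gn[(size_t)i] - ninf) * std::exp(-dt / tn);
          double m2 = minf + (gm[(size_t)i] - minf) * std::exp(-dt / tm);
          double h2 = hinf + (gh[(size_t)i] - hinf) * std::exp(-dt / th);
          const double I_ion = -g_na * m2 * m2 * m2 * h2 * (V - e_na)
                               - g_k * n2 * n2 * n2 * n2 * (V - e_k)
                               - g_l * (V - e_l);
          V += dt * (I_ion + I) / c_m;
          if (!R_finite(V))
            stop("network state diverged (neuron %d, t = %.2f ms)", i + 1, t);
          if (V >= 0.0 && !above[(size_t)i] && t >= lockout[(size_t)i]) {
            spiked = true;
            lockout[(size_t)i] = t + t_ref;
          }
          above[(size_t)i] = V >= 0.0;
          gn[(size_t)i] = n2; gm[(size_t)i] = m2; gh[(size_t)i] = h2;
          v[(size_t)i] = V;
        }
      }

      if (!spiked) continue;
      total_spikes += 1.0;
      if (total_spikes > max_spikes)
        stop("spike budget exceeded (%.0f spikes): likely runaway activity", max_spikes);
      if (t >= warmup) {
        sp_t.push_back((s + 1) * dt - warmup);
        sp_id.push_back(i + 1);
      } else {
        warmup_spikes += 1.0;
      }
      const bool exc_i = is_exc[i];
      if (annealed) {
        long k = (long)R::rbinom((double)(M - 1), p_deliver);
        for (long j = 0; j < k; ++j) {
          int tgt;
          do {
            tgt = (int)((size_t)(unif_rand() * M) % (size_t)M);
          } while (tgt == i);
          // with k << M duplicate targets are vanishingly rare, so only
          // self-delivery is resampled away
          int dstep = delay_min_steps +
            (int)(unif_rand() * (delay_max_steps - delay_min_steps + 1));
          if (dstep > delay_max_steps) dstep = delay_max_steps;
          int tslot = (int)((s + dstep) % L);
          if (exc_i) cnt_e[(size_t)tslot][(size_t)tgt] += 1.0f;
          else       cnt_i[(size_t)tslot][(size_t)tgt] += 1.0f;
        }
      } else {
        for (int e = edge_offsets[i]; e < edge_offsets[i + 1]; ++e) {
          const int tgt = edge_targets[e];
          const int tslot = (int)((s + edge_delays[e]) % L);
          if (exc_i) cnt_e[(size_t)tslot][(size_t)tgt] += 1.0f;
          else       cnt_i[(size_t)tslot][(size_t)tgt] += 1.0f;
        }
      }
    }

    std::fill(ce.begin(), ce.end(), 0.0f);
    std::fill(ci.begin(), ci.end(), 0.0f);
    if (s % 50000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["times"] = wrap(sp_t), _["ids"] = wrap(sp_id),
                      _["warmup_spikes"] = warmup_spikes);
}
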