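#' Leaky integrate-and-fire parameters
#'
#' Membrane potential decays toward `v_rest` with time constant `tau_m`;
#' each excitatory (inhibitory) synaptic event adds `+qe` (`-qi`) mV
#' instantaneously; crossing `v_thresh` emits a spike, resets the
#' potential to `v_rest`, and freezes the state for `t_ref` ms.
#' Defaults give the common 15 mV threshold distance, 10 ms membrane
#' time constant, and 2 ms refractory period.
#'
#' @param tau_m membrane time constant (ms).
#' @param v_rest resting (and reset) potential (mV).
#' @param v_thresh threshold potential (mV), above `v_rest`.
#' @param t_ref absolute refractory period (ms).
#' @param dt clock-driven integration step (ms); the event-driven path is
#'   exact and ignores it.
#' @return Object of class `lif_params`.
#' @export
lif_params <- function(tau_m = 10, v_rest = -70, v_thresh = -55,
                       t_ref = 2, dt = 0.1) {
  stopifnot(tau_m > 0, v_thresh > v_rest, t_ref >= 0, dt > 0)
  structure(list(tau_m = tau_m, v_rest = v_rest, v_thresh = v_thresh,
                 t_ref = t_ref, dt = dt),
            class = c("lif_params", "neuron_params"))
}

#' Izhikevich neuron parameters
#'
#' The two-variable quadratic model `v' = 0.04 v^2 + 5 v + 140 - u + I`,
#' `u' = a (b v - u)`, with spike at `v >= 30` mV followed by the reset
#' `v <- c`, `u <- u + d`.  Defaults are the canonical regular-spiking
#' set.  Synaptic input enters `I` as alpha-shaped currents; `c_eff` is
#' the nominal capacitance (pF) used to convert a PSP size into a peak
#' current, unity because the model's current term is scaled to directly
#' move `v` in mV/ms.
#'
#' @param a,b,c,d dimensionless Izhikevich parameters.
#' @param tau_syn_exc,tau_syn_inh alpha-synapse time constants (ms).
#' @param c_eff nominal capacitance for the PSC weight conversion (pF).
#' @param dt integration step (ms).
#' @return Object of class `izhikevich_params`.
#' @export
izhikevich_params <- function(a = 0.02, b = 0.2, c = -65, d = 8,
                              tau_syn_exc = 1, tau_syn_inh = 1,
                              c_eff = 1, dt = 0.1) {
  stopifnot(a > 0, b > 0, tau_syn_exc > 0, tau_syn_inh > 0, dt > 0)
  structure(list(a = a, b = b, c = c, d = d,
                 tau_syn_exc = tau_syn_exc, tau_syn_inh = tau_syn_inh,
                 c_eff = c_eff, dt = dt),
            class = c("izhikevich_params", "neuron_params"))
}

#' Hodgkin-Huxley neuron parameters
#'
#' Standard Na/K/leak scheme (squid-axon rate functions shifted so rest
#' sits near -65 mV) driven by alpha-shaped postsynaptic currents with
#' separate excitatory and inhibitory time constants.  A spike is an
#' upward crossing of 0 mV; detection is locked out for `t_ref` ms after
#' each spike while the continuous dynamics run on.  Conductances in nS,
#' capacitance in pF, so currents are in pA.
#'
#' @param c_m membrane capacitance (pF).
#' @param g_na,g_k,g_l peak sodium, potassium, and leak conductances (nS).
#' @param e_na,e_k,e_l reversal potentials (mV).
#' @param t_ref spike-detection lockout (ms).
#' @param tau_syn_exc,tau_syn_inh alpha-synapse time constants (ms).
#' @param dt integration step (ms); the stiff gating dynamics want a
#'   finer step than the other models.
#' @return Object of class `hh_params`.
#' @export
hh_params <- function(c_m = 100, g_na = 12000, g_k = 3600, g_l = 30,
                      e_na = 50, e_k = -77, e_l = -54.402, t_ref = 2,
                      tau_syn_exc = 0.2, tau_syn_inh = 2, dt = 0.025) {
  stopifnot(c_m > 0, g_na >= 0, g_k >= 0, g_l >= 0, t_ref >= 0,
            tau_syn_exc > 0, tau_syn_inh > 0, dt > 0)
  structure(list(c_m = c_m, g_na = g_na, g_k = g_k, g_l = g_l,
                 e_na = e_na, e_k = e_k, e_l = e_l, t_ref = t_ref,
                 tau_syn_exc = tau_syn_exc, tau_syn_inh = tau_syn_inh,
                 dt = dt),
            class = c("hh_params", "neuron_params"))
}

#' Spike train container
#'
#' @param times strictly increasing spike times (ms).
#' @param duration simulated span (ms); all times must lie in
#'   `[0, duration]`.
#' @return Object of class `spike_train`.
#' @export
spike_train <- function(times, duration) {
  times <- as.numeric(times)
  stopifnot(duration > 0)
  if (is.unsorted(times, strictly = TRUE))
    stop("spike times must be strictly increasing")
  if (length(times) && (times[1L] < 0 || times[length(times)] > duration))
    stop("spike times must lie within [0, duration]")
  structure(list(times = times, duration = duration), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train: %d spikes over %.6g ms (%.6g Hz)\n",
              length(x$times), x$duration,
              1000 * length(x$times) / x$duration))
  invisible(x)
}

#' Mean firing rate of a spike train in Hz
#' @param x a [spike_train()].
#' @return Rate in Hz.
#' @export
firing_rate <- function(x) {
  stopifnot(inherits(x, "spike_train"))
  1000 * length(x$times) / x$duration
}

check_streams <- function(exc, inh) {
  if (is.unsorted(exc) || is.unsorted(inh))
    stop("input event streams must be sorted in time")
}

#' Simulate a LIF neuron on explicit input streams
#'
#' Integrates the leaky integrate-and-fire dynamics with delta PSPs on
#' given excitatory and inhibitory event streams.  The `"event"` method
#' applies the exact exponential decay between events and is free of
#' discretization error; the `"clock"` method bins events on the `dt`
#' grid and checks threshold once per step.
#'
#' @param params a [lif_params()].
#' @param exc,inh sorted event times (ms).
#' @param qe,qi PSP magnitudes (mV) for excitatory and inhibitory events.
#' @param duration simulated span (ms).
#' @param method `"event"` (exact) or `"clock"`.
#' @return A [spike_train()].
#' @export
simulate_lif <- function(params, exc, inh, qe, qi, duration,
                         method = c("event", "clock")) {
  stopifnot(inherits(params, "lif_params"), duration > 0, qe >= 0, qi >= 0)
  check_streams(exc, inh)
  method <- match.arg(method)
  times <- if (method == "event") {
    cpp_lif_event(params$tau_m, params$v_rest, params$v_thresh,
                  params$t_ref, as.numeric(exc), as.numeric(inh),
                  qe, qi, duration)
  } else {
    cpp_lif_clock(params$tau_m, params$v_rest, params$v_thresh,
                  params$t_ref, as.numeric(exc), as.numeric(inh),
                  qe, qi, duration, params$dt)
  }
  spike_train(times, duration)
}

bin_counts <- function(times, dt, n_steps) {
  if (!length(times)) return(integer(n_steps))
  tabulate(pmin(floor(times / dt), n_steps - 1) + 1L, nbins = n_steps)
}

#' Simulate an Izhikevich neuron on explicit input streams
#'
#' @param params an [izhikevich_params()].
#' @param exc,inh sorted event times (ms).
#' @param w_exc,w_inh peak alpha-current magnitudes (pA); inhibitory
#'   events contribute with negative sign.
#' @param duration simulated span (ms).
#' @param i_const constant bias current (pA), useful for f-I curves.
#' @return A [spike_train()].
#' @export
simulate_izhikevich <- function(params, exc, inh, w_exc, w_inh, duration,
                                i_const = 0) {
  stopifnot(inherits(params, "izhikevich_params"), duration > 0)
  check_streams(exc, inh)
  n_steps <- ceiling(duration / params$dt)
  times <- cpp_izhikevich(params$a, params$b, params$c, params$d,
                          params$tau_syn_exc, params$tau_syn_inh,
                          bin_counts(exc, params$dt, n_steps),
                          bin_counts(inh, params$dt, n_steps),
                          FALSE, 0, 0, w_exc, w_inh, i_const,
                          duration, params$dt)
  spike_train(times, duration)
}

#' Simulate a Hodgkin-Huxley neuron on explicit input streams
#'
#' @inheritParams simulate_izhikevich
#' @param params an [hh_params()].
#' @return A [spike_train()].
#' @export
simulate_hh <- function(params, exc, inh, w_exc, w_inh, duration,
                        i_const = 0) {
  stopifnot(inherits(params, "hh_params"), duration > 0)
  check_streams(exc, inh)
  n_steps <- ceiling(duration / params$dt)
  times <- cpp_hh(params$c_m, params$g_na, params$g_k, params$g_l,
                  params$e_na, params$e_k, params$e_l, params$t_ref,
                  params$tau_syn_exc, params$tau_syn_inh,
                  bin_counts(exc, params$dt, n_steps),
                  bin_counts(inh, params$dt, n_steps),
                  FALSE, 0, 0, w_exc, w_inh, i_const,
                  duration, params$dt)
  spike_train(times, duration)
}
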