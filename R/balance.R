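#' Balanced excitatory/inhibitory PSP sizes
#'
#' For a population where a fraction `eta` of synaptic input events are
#' excitatory, loose excitatory-inhibitory balance (zero mean synaptic
#' drift for every input rate) fixes the inhibitory postsynaptic potential
#' as a function of the excitatory one.  Parameterizing the pair by a
#' single effective PSP size `q` such that the diffusion coefficient is
#' `D = q^2 R`, the unique balanced pair is
#' `qe = q * sqrt((1 - eta) / eta)` and `qi = q * sqrt(eta / (1 - eta))`.
#'
#' @param q effective PSP size (mV), `q >= 0`.
#' @param eta excitatory fraction of input events, strictly inside (0, 1).
#' @return Named numeric vector `c(qe = , qi = )` in mV.
#' @examples
#' balanced_psp_sizes(1, 0.8)  # qe = 0.5 mV, qi = 2 mV
#' @export
balanced_psp_sizes <- function(q, eta) {
  stopifnot(is.numeric(q), length(q) == 1L, q >= 0)
  if (!is.numeric(eta) || length(eta) != 1L || eta <= 0 || eta >= 1)
    stop("`eta` must lie strictly inside (0, 1) for balanced sizing")
  c(qe = q * sqrt((1 - eta) / eta), qi = q * sqrt(eta / (1 - eta)))
}

#' Drift and diffusion of compound Poisson synaptic input
#'
#' First two moments of the white-noise (diffusion) approximation of a
#' total input rate `R` split into excitatory events of size `qe` and
#' inhibitory events of size `-qi`: drift `mu = eta*R*qe - (1-eta)*R*qi`
#' (mV/ms) and diffusion `D = eta*R*qe^2 + (1-eta)*R*qi^2` (mV^2/ms).
#' For the balanced pair of [balanced_psp_sizes()], `mu` is identically 0
#' and `D = q^2 R`.
#'
#' @param R total input rate (kHz).
#' @param qe,qi excitatory and inhibitory PSP magnitudes (mV).
#' @param eta excitatory fraction in \[0, 1\].
#' @return Named numeric vector `c(mu = , D = )`.
#' @export
drift_diffusion <- function(R, qe, qi, eta) {
  stopifnot(R >= 0, qe >= 0, qi >= 0, eta >= 0, eta <= 1)
  c(mu = eta * R * qe - (1 - eta) * R * qi,
    D = eta * R * qe^2 + (1 - eta) * R * qi^2)
}

#' Input-rate grid uniform in the diffusion coefficient
#'
#' `S` evenly spaced diffusion coefficients on `[0, d_max]` mapped to
#' input rates through `R = D / q^2`, so transfer curves measured at
#' different `q` cover the same noise range.  The first rate is always 0.
#'
#' @param q effective PSP size (mV), strictly positive.
#' @param d_max upper end of the diffusion range (mV^2/ms).
#' @param S number of grid points, at least 2.
#' @return Numeric vector of input rates (kHz), increasing from 0.
#' @examples
#' range(rate_grid(1, 100, 500))  # 0 to 100 kHz
#' @export
rate_grid <- function(q, d_max = 100, S = 500) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0)
    stop("`q` must be a single positive PSP size; the rate R = D/q^2 is undefined at q = 0")
  stopifnot(S >= 2, d_max >= 0)
  seq(0, d_max, length.out = S) / q^2
}

#' Alpha postsynaptic current weight equivalent to a delta PSP
#'
#' Peak current `w` of the alpha kernel `alpha(t) = w * (t/tau_syn) *
#' exp(1 - t/tau_syn)` whose integrated charge equals `c_m * q`, so that a
#' current-based synapse deposits the same total charge as an
#' instantaneous voltage jump of size `q`:  `w = c_m * q / (e * tau_syn)`.
#'
#' @param q equivalent PSP size (mV).
#' @param c_m membrane capacitance (pF).
#' @param tau_syn synaptic time constant (ms), strictly positive.
#' @return Peak current in pA.
#' @examples
#' psc_weight(1, 250, 2)  # 250 / (2 e) ~ 45.98 pA
#' @export
psc_weight <- function(q, c_m, tau_syn) {
  stopifnot(q >= 0, c_m > 0)
  if (!is.numeric(tau_syn) || length(tau_syn) != 1L || tau_syn <= 0)
    stop("`tau_syn` must be > 0; use the delta-PSP path for instantaneous synapses")
  c_m * q / (exp(1) * tau_syn)
}

#' Seeded pair of balanced Poisson event streams
#'
#' Independent homogeneous Poisson realizations at rates `eta * R`
#' (excitatory) and `(1 - eta) * R` (inhibitory) over `[0, duration]`.
#' Event counts are drawn as Poisson variates and event times placed
#' uniformly, which is distributionally exact for a homogeneous process.
#'
#' @param R total input rate (kHz).
#' @param eta excitatory fraction in \[0, 1\] (0 and 1 give an empty
#'   stream on the corresponding side).
#' @param duration span in ms.
#' @param seed optional integer seed; when supplied the function is
#'   deterministic, otherwise it draws from the session RNG stream.
#' @return List with sorted numeric vectors `exc` and `inh` (ms).
#' @export
poisson_streams <- function(R, eta, duration, seed = NULL) {
  stopifnot(R >= 0, eta >= 0, eta <= 1, duration > 0)
  if (!is.null(seed)) set.seed(seed)
  draw <- function(rate) {
    n <- rpois(1L, rate * duration)
    sort(runif(n, 0, duration))
  }
  list(exc = draw(eta * R), inh = draw((1 - eta) * R))
}
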