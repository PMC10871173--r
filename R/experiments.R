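#' Parameter distribution descriptors
#'
#' Small helpers describing how to randomize a neuron parameter:
#' exponential by its mean, normal by mean and standard deviation
#' (resampled while a positivity constraint is violated), or uniform
#' over an interval.  A named list of these forms a distribution spec
#' for [sweep_random_parameters()].
#'
#' @param mean,sd,min,max distribution parameters.
#' @param positive resample normal draws until strictly positive.
#' @return A descriptor of class `param_dist`.
#' @export
dist_exp <- function(mean) {
  stopifnot(mean > 0)
  structure(list(kind = "exp", mean = mean), class = "param_dist")
}

#' @rdname dist_exp
#' @export
dist_norm <- function(mean, sd, positive = TRUE) {
  stopifnot(sd >= 0)
  structure(list(kind = "norm", mean = mean, sd = sd, positive = positive),
            class = "param_dist")
}

#' @rdname dist_exp
#' @export
dist_uniform <- function(min, max) {
  stopifnot(max >= min)
  structure(list(kind = "uniform", min = min, max = max),
            class = "param_dist")
}

draw_param <- function(d) {
  stopifnot(inherits(d, "param_dist"))
  switch(d$kind,
    exp = rexp(1L, 1 / d$mean),
    norm = {
      x <- rnorm(1L, d$mean, d$sd)
      while (isTRUE(d$positive) && x <= 0) x <- rnorm(1L, d$mean, d$sd)
      x
    },
    uniform = runif(1L, d$min, d$max))
}

#' Stock randomization specs for the three neuron models
#'
#' The LIF spec randomizes the refractory period (exponential about its
#' 2 ms default); membrane capacitance does not enter the delta-PSP
#' dynamics and is therefore not varied.  The Izhikevich spec draws
#' each of `a, b, c, d` uniformly over the ranges of the model's
#' original description.  The Hodgkin-Huxley spec randomizes the
#' refractory lockout, the capacitance (normal about 100 pF), and both
#' synaptic time constants (exponential, 1 ms mean).
#'
#' @param model_kind `"lif"`, `"izhikevich"`, or `"hh"`.
#' @return Named list of [dist_exp()]/[dist_norm()]/[dist_uniform()]
#'   descriptors.
#' @export
default_param_distributions <- function(model_kind = c("lif", "izhikevich",
                                                       "hh")) {
  switch(match.arg(model_kind),
    lif = list(t_ref = dist_exp(2)),
    izhikevich = list(a = dist_uniform(0.02, 0.1),
                      b = dist_uniform(0.2, 0.25),
                      c = dist_uniform(-65, -50),
                      d = dist_uniform(2, 8)),
    hh = list(t_ref = dist_exp(2),
              c_m = dist_norm(100, 10),
              tau_syn_exc = dist_exp(1),
              tau_syn_inh = dist_exp(1)))
}

make_model <- function(model_kind, overrides = list()) {
  ctor <- switch(model_kind, lif = lif_params,
                 izhikevich = izhikevich_params, hh = hh_params)
  do.call(ctor, overrides)
}

#' Randomized-parameter generalization sweep
#'
#' Draws `n_draws` random parameterizations of a neuron model from a
#' distribution spec, measures each instance's transfer curve under
#' balanced Poisson input, fits Refractory SoftPlus, and returns the
#' distribution of normalized fit errors together with the
#' default-parameter fit for reference.
#'
#' @param model_kind `"lif"`, `"izhikevich"`, or `"hh"`.
#' @param spec named list of parameter distributions; defaults to
#'   [default_param_distributions()].
#' @param n_draws number of random instances.
#' @param q,eta input model (defaults 1 mV and 0.5).
#' @param S,d_max,duration transfer-curve measurement settings
#'   (`duration` in s).
#' @param seed optional integer seed.
#' @return List with `nrmse` (length `n_draws`), `default_nrmse`, and
#'   `draws` (data frame of the sampled parameter values).
#' @export
sweep_random_parameters <- function(model_kind, spec = NULL, n_draws = 50,
                                    q = 1, eta = 0.5, S = 100,
                                    d_max = 100, duration = 100,
                                    seed = NULL) {
  model_kind <- match.arg(model_kind, c("lif", "izhikevich", "hh"))
  if (is.null(spec)) spec <- default_param_distributions(model_kind)
  stopifnot(n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  default_curve <- measure_transfer_curve(make_model(model_kind), q = q,
                                          eta = eta, S = S, d_max = d_max,
                                          duration = duration)
  default_nrmse <- fit_rsp(default_curve)$nrmse
  draws <- vector("list", n_draws)
  nrmse <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    pars <- lapply(spec, draw_param)
    model <- make_model(model_kind, pars)
    curve <- measure_transfer_curve(model, q = q, eta = eta, S = S,
                                    d_max = d_max, duration = duration)
    nrmse[i] <- fit_rsp(curve)$nrmse
    draws[[i]] <- as.data.frame(pars)
  }
  list(nrmse = nrmse, default_nrmse = default_nrmse,
       draws = do.call(rbind, draws), model_kind = model_kind)
}

# per-point spike times for a transfer measurement (needed to truncate a
# long run to time prefixes)
measure_transfer_spikes <- function(model, q, eta, S, d_max, duration,
                                    seed = NULL) {
  sizes <- balanced_psp_sizes(q, eta)
  grid <- rate_grid(q, d_max, S)
  if (!is.null(seed)) set.seed(seed)
  dur_ms <- duration * 1000
  times <- lapply(grid, function(R) {
    re <- eta * R
    ri <- (1 - eta) * R
    if (inherits(model, "lif_params")) {
      cpp_lif_rate_spikes(model$tau_m, model$v_rest, model$v_thresh,
                          model$t_ref, re, ri, sizes[["qe"]],
                          sizes[["qi"]], dur_ms)
    } else if (inherits(model, "izhikevich_params")) {
      we <- psc_weight(sizes[["qe"]], model$c_eff, model$tau_syn_exc)
      wi <- psc_weight(sizes[["qi"]], model$c_eff, model$tau_syn_inh)
      cpp_izhikevich(model$a, model$b, model$c, model$d,
                     model$tau_syn_exc, model$tau_syn_inh,
                     integer(0), integer(0), TRUE, re, ri, we, wi, 0,
                     dur_ms, model$dt)
    } else {
      we <- psc_weight(sizes[["qe"]], model$c_m, model$tau_syn_exc)
      wi <- psc_weight(sizes[["qi"]], model$c_m, model$tau_syn_inh)
      cpp_hh(model$c_m, model$g_na, model$g_k, model$g_l, model$e_na,
             model$e_k, model$e_l, model$t_ref, model$tau_syn_exc,
             model$tau_syn_inh, integer(0), integer(0), TRUE, re, ri,
             we, wi, 0, dur_ms, model$dt)
    }
  })
  list(grid = grid, times = times)
}

#' Fit-convergence study in the number of rates or the duration
#'
#' Quantifies how the Refractory SoftPlus fit error shrinks with the
#' two axes of simulation effort.  `"vary_S"` runs one measurement at
#' `ref_S` input rates and fits to evenly spaced subsets of sizes
#' `grid`, always scoring against the full reference curve.
#' `"vary_T"` runs one measurement of `S` rates for `max(grid)`
#' seconds, truncates it to each prefix duration in `grid` (so startup
#' transients are shared across durations), fits each truncated curve,
#' and reports both the fitted-curve error and the error of the raw
#' short-time rate estimates against the full-duration curve.
#'
#' @param model a neuron parameter object.
#' @param mode `"vary_S"` or `"vary_T"`.
#' @param grid ascending subset sizes (counts) or prefix durations (s).
#' @param q,eta,d_max input model settings.
#' @param ref_S reference number of rates for `"vary_S"`.
#' @param duration per-point duration (s) for `"vary_S"`.
#' @param S number of rates for `"vary_T"`.
#' @param seed optional integer seed.
#' @return Data frame with columns `value` (the grid), `nrmse`
#'   (fitted-curve error vs the reference), and for `"vary_T"` also
#'   `raw_nrmse` (error of the truncated empirical estimates).
#' @export
convergence_study <- function(model, mode = c("vary_S", "vary_T"), grid,
                              q = 1, eta = 0.5, d_max = 100,
                              ref_S = 500, duration = 100, S = 100,
                              seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(!is.unsorted(grid), all(grid > 0))
  if (mode == "vary_S") {
    stopifnot(all(grid >= 4), all(grid <= ref_S))
    ref <- measure_transfer_curve(model, q = q, eta = eta, S = ref_S,
                                  d_max = d_max, duration = duration,
                                  seed = seed)
    nrmse <- vapply(grid, function(s) {
      idx <- unique(round(seq(1, ref_S, length.out = s)))
      sub <- transfer_curve(ref$R_kHz[idx], ref$rate_Hz[idx], q = q,
                            eta = eta, duration = duration,
                            model = attr(ref, "model"))
      normalized_rms_error(fit_rsp(sub), ref)
    }, numeric(1))
    data.frame(value = grid, nrmse = nrmse)
  } else {
    t_max <- max(grid)
    ms <- measure_transfer_spikes(model, q, eta, S, d_max, t_max, seed)
    ref_rates <- vapply(ms$times, length, numeric(1)) / t_max
    ref <- transfer_curve(ms$grid, ref_rates, q = q, eta = eta,
                          duration = t_max)
    max_ref <- max(ref_rates)
    res <- lapply(grid, function(tt) {
      rates <- vapply(ms$times, function(x) sum(x <= tt * 1000),
                      numeric(1)) / tt
      sub <- transfer_curve(ms$grid, rates, q = q, eta = eta,
                            duration = tt)
      data.frame(value = tt,
                 nrmse = normalized_rms_error(fit_rsp(sub), ref),
                 raw_nrmse = sqrt(mean((rates - ref_rates)^2)) / max_ref)
    })
    do.call(rbind, res)
  }
}
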