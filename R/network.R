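#' Recurrent-network configuration
#'
#' Describes a population of `m_total` neurons, each receiving
#' `n_in` recurrent connections (sampled without replacement, no self
#' connections) plus its own independent background Poisson input pair
#' at rates `eta * r_bg` and `(1 - eta) * r_bg`.  A fraction `eta` of
#' neurons is excitatory, delivering `+qe` to their targets; the rest
#' deliver `-qi` (sizes from [balanced_psp_sizes()]).  Recurrent spikes
#' arrive after an axonal delay drawn uniformly from `delay_range`.
#'
#' `connectivity = "annealed_average"` replaces the fixed wiring by
#' all-to-all probabilistic synapses with per-spike transmission
#' probability `n_in / m_total`, matching the mean input while breaking
#' temporal correlations.
#'
#' @param m_total population size M.
#' @param n_in in-degree N, `0 <= n_in < m_total`.
#' @param q effective PSP size (mV).
#' @param r_bg background input rate per neuron (kHz).
#' @param eta excitatory fraction.
#' @param delay_range recurrent delay interval (ms); minimum at least
#'   one step `dt`.
#' @param connectivity `"static_indegree"` or `"annealed_average"`.
#' @param neuron neuron parameter object ([lif_params()],
#'   [izhikevich_params()], or [hh_params()]).
#' @param dt simulation step (ms); defaults to the neuron's.
#' @param seed optional integer seed used by [build_connectivity()] and
#'   [simulate_network()].
#' @return Object of class `network_config`.
#' @export
network_config <- function(m_total, n_in, q, r_bg, eta = 0.8,
                           delay_range = c(1, 15),
                           connectivity = c("static_indegree",
                                            "annealed_average"),
                           neuron = lif_params(), dt = neuron$dt,
                           seed = NULL) {
  connectivity <- match.arg(connectivity)
  stopifnot(m_total >= 1, n_in >= 0, q > 0, r_bg >= 0,
            eta > 0, eta < 1, length(delay_range) == 2L,
            delay_range[1L] <= delay_range[2L], dt > 0,
            inherits(neuron, "neuron_params"))
  if (n_in >= m_total)
    stop("`n_in` must be smaller than `m_total` (no self or duplicate connections)")
  if (delay_range[1L] < dt)
    stop("minimum delay must be at least one simulation step")
  structure(list(m_total = as.integer(m_total), n_in = as.integer(n_in),
                 q = q, r_bg = r_bg, eta = eta,
                 delay_range = delay_range, connectivity = connectivity,
                 neuron = neuron, dt = dt, seed = seed),
            class = "network_config")
}

#' Build the recurrent wiring of a network configuration
#'
#' Static mode: every neuron draws exactly `n_in` distinct presynaptic
#' partners (never itself) and each edge an i.i.d. uniform delay,
#' returned in compressed out-edge form for the simulator.  Annealed
#' mode returns the per-spike transmission probability instead.
#'
#' @param cfg a [network_config()].
#' @param seed optional seed (defaults to the config's).
#' @return List with `mode`; for static wiring also 0-based CSR fields
#'   `offsets`, `targets`, `delay_steps`, and the matrix `presyn`
#'   (`n_in` rows, one column per neuron) of presynaptic ids; for
#'   annealed wiring the probability `p` and delay bounds in steps.
#' @export
build_connectivity <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "network_config"))
  if (!is.null(seed)) set.seed(seed)
  M <- cfg$m_total
  dmin <- max(1L, as.integer(round(cfg$delay_range[1L] / cfg$dt)))
  dmax <- max(dmin, as.integer(round(cfg$delay_range[2L] / cfg$dt)))
  if (cfg$connectivity == "annealed_average")
    return(list(mode = "annealed_average", p = cfg$n_in / M,
                delay_min_steps = dmin, delay_max_steps = dmax))
  N <- cfg$n_in
  presyn <- vapply(seq_len(M), function(i) {
    s <- sample.int(M - 1L, N)
    s + (s >= i)                      # skip self: map 1..M-1 onto 1..M \ {i}
  }, integer(N))
  presyn <- matrix(presyn, nrow = N)
  src <- as.vector(presyn)            # edge: src -> tgt
  tgt <- rep(seq_len(M), each = N)
  ord <- order(src)
  src <- src[ord]
  tgt <- tgt[ord]
  offsets <- c(0L, cumsum(tabulate(src, nbins = M)))
  delay_steps <- sample(dmin:dmax, length(src), replace = TRUE)
  list(mode = "static_indegree", offsets = offsets, targets = tgt - 1L,
       delay_steps = as.integer(delay_steps), presyn = presyn,
       delay_min_steps = dmin, delay_max_steps = dmax)
}

#' Warm-up protocol for reaching the upper basin of attraction
#'
#' Additional excitatory Poisson drive applied per neuron before
#' recording starts, ramping linearly from `amplitude` down to 0 over
#' `warmup_time`.  Spikes during the warm-up window are excluded from
#' all rate estimates.
#'
#' @param cfg a [network_config()] (supplies the default amplitude
#'   `r_bg`).
#' @param warmup_time warm-up duration (s).
#' @param amplitude initial extra excitatory rate (kHz); `0` disables
#'   the warm-up drive (the window is still discarded).
#' @return Object of class `warmup_protocol`.
#' @export
warmup_protocol <- function(cfg, warmup_time = 1, amplitude = cfg$r_bg) {
  stopifnot(warmup_time > 0, amplitude >= 0)
  structure(list(time_s = warmup_time, amplitude = amplitude),
            class = "warmup_protocol")
}

#' Instantaneous warm-up drive rate
#' @param protocol a [warmup_protocol()].
#' @param t time since simulation start (ms).
#' @return Extra excitatory rate (kHz) at `t`.
#' @export
warmup_rate <- function(protocol, t) {
  stopifnot(inherits(protocol, "warmup_protocol"))
  w <- protocol$time_s * 1000
  ifelse(t < w, protocol$amplitude * (1 - t / w), 0)
}

neuron_pars_vector <- function(neuron) {
  if (inherits(neuron, "lif_params")) {
    list(id = 0L, pars = c(neuron$tau_m, neuron$v_rest, neuron$v_thresh,
                           neuron$t_ref))
  } else if (inherits(neuron, "izhikevich_params")) {
    list(id = 1L, pars = c(neuron$a, neuron$b, neuron$c, neuron$d,
                           neuron$tau_syn_exc, neuron$tau_syn_inh))
  } else {
    list(id = 2L, pars = c(neuron$c_m, neuron$g_na, neuron$g_k, neuron$g_l,
                           neuron$e_na, neuron$e_k, neuron$e_l,
                           neuron$t_ref, neuron$tau_syn_exc,
                           neuron$tau_syn_inh))
  }
}

#' Simulate a recurrent spiking network
#'
#' Clock-driven simulation of the configured population: delta PSPs for
#' LIF neurons, alpha PSCs (weights from [psc_weight()]) for Izhikevich
#' and Hodgkin-Huxley.  Each neuron receives its own background Poisson
#' pair; recurrent spikes are delivered through the configured wiring
#' with per-edge delays.  Spikes inside the warm-up window are
#' discarded; recorded times are relative to the end of warm-up.
#'
#' @param cfg a [network_config()].
#' @param duration recording span (s), after warm-up.
#' @param warmup `NULL` (no warm-up) or a [warmup_protocol()].
#' @param stim optional [stimulus()] modulating the background rate
#'   (kHz) over recording time, e.g. a sinusoid; only the deviation
#'   from `cfg$r_bg` is applied on top of the configured background.
#' @param wiring optional pre-built [build_connectivity()] result to
#'   reuse across runs.
#' @param bin_ms width of the returned population-rate bins (ms).
#' @param seed optional seed (defaults to the config's).
#' @param max_spikes abort threshold on total emitted spikes, guarding
#'   against runaway activity.
#' @param verbose print a one-line run summary.
#' @return Object of class `network_sim`: list with `spikes` (data
#'   frame `neuron_id`, `time_ms`), `trace` (a [binned_rate()]
#'   population trace), `cfg`, `duration` (s), and `warmup_spikes`.
#' @export
simulate_network <- function(cfg, duration, warmup = NULL, stim = NULL,
                             wiring = NULL, bin_ms = 1, seed = cfg$seed,
                             max_spikes = 5e7, verbose = FALSE) {
  stopifnot(inherits(cfg, "network_config"), duration > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(wiring)) wiring <- build_connectivity(cfg, seed = NULL)
  sizes <- balanced_psp_sizes(cfg$q, cfg$eta)
  np <- neuron_pars_vector(cfg$neuron)
  w_exc <- w_inh <- 0
  if (np$id == 1L) {
    w_exc <- psc_weight(sizes[["qe"]], cfg$neuron$c_eff, cfg$neuron$tau_syn_exc)
    w_inh <- psc_weight(sizes[["qi"]], cfg$neuron$c_eff, cfg$neuron$tau_syn_inh)
  } else if (np$id == 2L) {
    w_exc <- psc_weight(sizes[["qe"]], cfg$neuron$c_m, cfg$neuron$tau_syn_exc)
    w_inh <- psc_weight(sizes[["qi"]], cfg$neuron$c_m, cfg$neuron$tau_syn_inh)
  }
  n_exc <- round(cfg$eta * cfg$m_total)
  is_exc <- seq_len(cfg$m_total) <= n_exc
  annealed <- wiring$mode == "annealed_average"
  warmup_ms <- if (is.null(warmup)) 0 else warmup$time_s * 1000
  warmup_amp <- if (is.null(warmup)) 0 else warmup$amplitude
  stim_amp <- 0
  stim_freq <- 1
  if (!is.null(stim)) {
    stopifnot(inherits(stim, "stimulus"))
    if (stim$type != "sinusoid")
      stop("only sinusoidal network stimuli are supported; use `cfg$r_bg` for constants")
    stim_amp <- stim$amplitude
    stim_freq <- stim$frequency
  }
  t0 <- proc.time()[["elapsed"]]
  out <- cpp_network(np$id, np$pars, cfg$m_total, is_exc,
                     if (annealed) integer(1) else wiring$offsets,
                     if (annealed) integer(0) else wiring$targets,
                     if (annealed) integer(0) else wiring$delay_steps,
                     annealed, if (annealed) wiring$p else 0,
                     wiring$delay_min_steps, wiring$delay_max_steps,
                     sizes[["qe"]], sizes[["qi"]], w_exc, w_inh,
                     cfg$eta, cfg$r_bg, stim_amp, stim_freq,
                     warmup_ms, warmup_amp,
                     duration * 1000, cfg$dt, max_spikes)
  spikes <- data.frame(neuron_id = out$ids, time_ms = out$times)
  trace <- binned_rate(spikes, cfg$m_total, duration * 1000, bin_ms)
  if (verbose)
    message(sprintf(
      "network run: M=%d N=%d %s | %.1f s simulated, %d spikes (%.2f Hz), %.1f s wall",
      cfg$m_total, cfg$n_in, wiring$mode, duration, nrow(spikes),
      mean(trace), proc.time()[["elapsed"]] - t0))
  structure(list(spikes = spikes, trace = trace, cfg = cfg,
                 duration = duration, warmup_spikes = out$warmup_spikes),
            class = "network_sim")
}

#' @export
print.network_sim <- function(x, ...) {
  cat(sprintf(
    "Network simulation: M = %d, N = %d (%s), %.3g s recorded\n",
    x$cfg$m_total, x$cfg$n_in, x$cfg$connectivity, x$duration))
  cat(sprintf("  %d spikes, mean population rate %.3f Hz\n",
              nrow(x$spikes), mean(x$trace)))
  invisible(x)
}

#' Binned population firing rate
#'
#' Number of spikes per time bin, divided by the population size and
#' the bin width, giving an instantaneous population rate in Hz.
#'
#' @param spikes data frame with a `time_ms` column (or a numeric
#'   vector of spike times in ms).
#' @param m_total population size M.
#' @param duration_ms recording span (ms).
#' @param bin_ms bin width (ms).
#' @param t0 time of the first bin edge (ms).
#' @return Numeric vector of class `population_trace` with attributes
#'   `bin_ms` and `t0`; length `duration_ms / bin_ms`.
#' @export
binned_rate <- function(spikes, m_total, duration_ms, bin_ms = 1, t0 = 0) {
  stopifnot(bin_ms > 0, m_total >= 1)
  times <- if (is.data.frame(spikes)) spikes$time_ms else as.numeric(spikes)
  n_bins <- ceiling(duration_ms / bin_ms)
  times <- times[times >= t0 & times < t0 + n_bins * bin_ms]
  counts <- tabulate(floor((times - t0) / bin_ms) + 1L, nbins = n_bins)
  structure(1000 * counts / (m_total * bin_ms),
            bin_ms = bin_ms, t0 = t0, class = "population_trace")
}

#' @export
print.population_trace <- function(x, ...) {
  cat(sprintf(
    "Population trace: %d bins of %g ms; mean %.3f Hz, sd %.3f Hz\n",
    length(x), attr(x, "bin_ms"), mean(x), sd(x)))
  invisible(x)
}

#' Fit an Ornstein-Uhlenbeck summary to a population trace
#'
#' Treats the binned population rate as a discretely observed OU
#' process: the `mean` is the time average, `sigma` the stationary
#' standard deviation, and the correlation `timescale` is estimated
#' from the lag-1 autoregression coefficient `rho` as
#' `bin_ms / (1 - rho)` (which matches `-bin / log(rho)` for smooth
#' traces and degrades gracefully to the bin width for white noise).
#'
#' @param trace a [binned_rate()] trace (or plain numeric series).
#' @param discard_ms initial transient to drop (ms).
#' @param bin_ms bin width when `trace` is a bare numeric vector.
#' @return Object of class `ou_fit`: list with `mean`, `sigma`,
#'   `timescale` (`NA` and flagged when the trace is constant), `rho`,
#'   and `n_bins`.
#' @export
fit_ou <- function(trace, discard_ms = 0, bin_ms = attr(trace, "bin_ms")) {
  if (is.null(bin_ms)) bin_ms <- 1
  x <- as.numeric(trace)
  drop <- floor(discard_ms / bin_ms)
  if (drop > 0) x <- x[-seq_len(drop)]
  if (length(x) < 100L)
    stop("need at least 100 bins after the discard window")
  m <- mean(x)
  s <- sd(x)
  if (s == 0) {
    return(structure(list(mean = m, sigma = 0, timescale = NA_real_,
                          rho = NA_real_, n_bins = length(x),
                          degenerate = TRUE), class = "ou_fit"))
  }
  n <- length(x)
  rho <- stats::cor(x[-1L], x[-n])
  timescale <- if (rho < 1) bin_ms / (1 - max(rho, 0)) else NA_real_
  structure(list(mean = m, sigma = s, timescale = timescale, rho = rho,
                 n_bins = n, degenerate = FALSE), class = "ou_fit")
}

#' @export
print.ou_fit <- function(x, ...) {
  cat(sprintf(
    "OU fit: mean %.3f Hz, sigma %.3f Hz, timescale %s ms (%d bins)\n",
    x$mean, x$sigma,
    if (is.na(x$timescale)) "undefined" else sprintf("%.2f", x$timescale),
    x$n_bins))
  invisible(x)
}

#' Finite-size fluctuation experiment across population sizes
#'
#' Repeatedly simulates the configured network at several population
#' sizes and summarizes each run's population trace with [fit_ou()].
#'
#' @param cfg a [network_config()] serving as the template; `m_total`
#'   is replaced by each value of `m_values`.
#' @param m_values population sizes to simulate.
#' @param n_reps independent runs per size.
#' @param duration recording span per run (s).
#' @param settle_s initial span simulated but discarded (s), letting
#'   the population reach equilibrium.
#' @param seed optional base seed; run `j` at size `i` uses
#'   `seed + 1000 * i + j`.
#' @return Data frame with one row per run: `m_total`, `rep`, `mean`,
#'   `sigma`, `timescale`.
#' @export
fluctuation_experiment <- function(cfg, m_values, n_reps = 3,
                                   duration = 2, settle_s = 0.5,
                                   seed = cfg$seed) {
  stopifnot(length(m_values) >= 1)
  rows <- list()
  for (i in seq_along(m_values)) {
    cfg_i <- cfg
    cfg_i$m_total <- as.integer(m_values[i])
    cfg_i$seed <- NULL
    for (j in seq_len(n_reps)) {
      if (!is.null(seed)) set.seed(seed + 1000L * i + j)
      sim <- simulate_network(cfg_i, duration = duration + settle_s,
                              seed = NULL)
      ou <- fit_ou(sim$trace, discard_ms = settle_s * 1000)
      rows[[length(rows) + 1L]] <-
        data.frame(m_total = m_values[i], rep = j, mean = ou$mean,
                   sigma = ou$sigma, timescale = ou$timescale)
    }
  }
  do.call(rbind, rows)
}

#' Inverse-square-root scaling of population-rate fluctuations
#'
#' Least-squares fit of `sigma = k * M^(-1/2)` to per-run fluctuation
#' amplitudes across population sizes, plus the unconstrained log-log
#' slope as a diagnostic of the scaling law.
#'
#' @param df data frame with columns `m_total` and `sigma`, e.g. from
#'   [fluctuation_experiment()]; needs at least 3 distinct sizes.
#' @return List with `k` (coefficient of the inverse-root law),
#'   `loglog_slope`, `r_squared` (of the log-log fit), and `n_runs`.
#' @export
fluctuation_scaling <- function(df) {
  stopifnot(all(c("m_total", "sigma") %in% names(df)))
  if (length(unique(df$m_total)) < 3L)
    stop("need at least 3 distinct population sizes")
  w <- df$m_total^(-0.5)
  k <- sum(df$sigma * w) / sum(w^2)
  ll <- lm(log(sigma) ~ log(m_total), data = df[df$sigma > 0, ])
  list(k = k, loglog_slope = coef(ll)[[2L]],
       r_squared = suppressWarnings(summary(ll)$r.squared),
       n_runs = nrow(df))
}

#' Practical stability of the upper equilibrium
#'
#' Probability that a finite network, warmed up toward the upper fixed
#' point, stays in its basin of attraction for an entire recording.
#' A run "stays" if the trailing `window_ms` moving average of the
#' population rate never falls below the mean-field unstable
#' (watershed) rate.
#'
#' @param cfg a [network_config()] of a bistable condition.
#' @param model the matching [mean_field()] model (used to locate the
#'   unstable fixed point); alternatively pass `r_unstable` directly.
#' @param n_sims number of independent runs.
#' @param duration recording span per run (s).
#' @param warmup a [warmup_protocol()]; default ramps from `r_bg`.
#' @param window_ms trailing-average window (ms).
#' @param r_unstable watershed rate (Hz) overriding `model`.
#' @param seed optional base seed (run `j` uses `seed + j`).
#' @return List with `fraction` of runs that stayed, logical `stayed`,
#'   `r_unstable`, and per-run mean rates `mean_rate`.
#' @export
practical_stability <- function(cfg, model = NULL, n_sims = 10,
                                duration = 2.5,
                                warmup = warmup_protocol(cfg),
                                window_ms = 100, r_unstable = NULL,
                                seed = cfg$seed) {
  if (is.null(r_unstable)) {
    stopifnot(inherits(model, "mean_field"))
    fp <- fixed_points(model)
    un <- fp$rate[fp$stability == "unstable"]
    if (!length(un))
      stop("model has no unstable fixed point: the condition is not bistable")
    r_unstable <- un[1L]
  }
  stayed <- logical(n_sims)
  mean_rate <- numeric(n_sims)
  for (j in seq_len(n_sims)) {
    if (!is.null(seed)) set.seed(seed + j)
    sim <- simulate_network(cfg, duration = duration, warmup = warmup,
                            seed = NULL)
    x <- as.numeric(sim$trace)
    w <- max(1L, round(window_ms / attr(sim$trace, "bin_ms")))
    cs <- cumsum(c(0, x))
    roll <- (cs[(w + 1L):(length(x) + 1L)] - cs[1:(length(x) - w + 1L)]) / w
    stayed[j] <- all(roll > r_unstable)
    mean_rate[j] <- mean(x)
  }
  list(fraction = mean(stayed), stayed = stayed,
       r_unstable = r_unstable, mean_rate = mean_rate)
}
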