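#' Construct a transfer-curve object
#'
#' A sampled single-neuron transfer function: total input rate (kHz)
#' against measured mean firing rate (Hz), together with the input-model
#' metadata needed to fit and reuse it.
#'
#' @param rates_in strictly increasing, non-negative input rates (kHz).
#' @param rates_out non-negative measured firing rates (Hz), same length.
#' @param q effective PSP size (mV).
#' @param eta excitatory input fraction.
#' @param duration per-point simulated time (s).
#' @param seed seed used for the measurement (or `NA`).
#' @param model model name string.
#' @param params the neuron parameter object (stored as a list).
#' @return Object of class `transfer_curve`, a data frame with columns
#'   `R_kHz` and `rate_Hz`.
#' @export
transfer_curve <- function(rates_in, rates_out, q, eta, duration,
                           seed = NA, model = "unknown", params = list()) {
  stopifnot(length(rates_in) == length(rates_out),
            all(rates_in >= 0), all(rates_out >= 0))
  if (is.unsorted(rates_in, strictly = TRUE))
    stop("`rates_in` must be strictly increasing")
  structure(data.frame(R_kHz = rates_in, rate_Hz = rates_out),
            q = q, eta = eta, duration = duration, seed = seed,
            model = model, params = unclass(params),
            class = c("transfer_curve", "data.frame"))
}

#' @export
print.transfer_curve <- function(x, ...) {
  cat(sprintf(
    "Transfer curve: %s neuron, %d points, R in [%.4g, %.4g] kHz\n",
    attr(x, "model"), nrow(x), min(x$R_kHz), max(x$R_kHz)))
  cat(sprintf("  q = %g mV, eta = %g, T = %g s per point, max rate %.2f Hz\n",
              attr(x, "q"), attr(x, "eta"), attr(x, "duration"),
              max(x$rate_Hz)))
  invisible(x)
}

#' @export
plot.transfer_curve <- function(x, ...) {
  plot(x$R_kHz, x$rate_Hz, xlab = "input rate R (kHz)",
       ylab = "firing rate (Hz)",
       main = sprintf("%s transfer curve (q = %g mV)",
                      attr(x, "model"), attr(x, "q")), ...)
}

#' Measure a neuron's transfer curve under balanced Poisson input
#'
#' Simulates the neuron at `S` input rates chosen so the diffusion
#' coefficient `D = q^2 R` is evenly spaced on `[0, d_max]`, each for
#' `duration` seconds with fresh Poisson excitatory/inhibitory streams at
#' rates `eta * R` and `(1 - eta) * R`, PSP sizes from
#' [balanced_psp_sizes()].  For current-based models the PSPs are
#' converted to peak alpha-current weights via [psc_weight()].
#'
#' The LIF `"event"` method generates the merged Poisson stream and
#' integrates exactly, and is the fast path used for long measurements;
#' `"clock"` materializes the streams and bins them on the `dt` grid.
#'
#' @param model a `lif_params`, `izhikevich_params`, or `hh_params`
#'   object.
#' @param q effective PSP size (mV), > 0.
#' @param eta excitatory fraction in (0, 1).
#' @param S number of input rates.
#' @param d_max top of the diffusion range (mV^2/ms); the default 100
#'   drives the stock models to fire in the tens of hertz.
#' @param duration simulated time per point, in seconds.
#' @param seed optional integer seed (one seeding governs all points).
#' @param method LIF integration path, `"event"` or `"clock"`.
#' @return A [transfer_curve()].
#' @export
measure_transfer_curve <- function(model, q = 1, eta = 0.5, S = 500,
                                   d_max = 100, duration = 100,
                                   seed = NULL,
                                   method = c("event", "clock")) {
  stopifnot(inherits(model, "neuron_params"), S >= 2, duration > 0)
  method <- match.arg(method)
  sizes <- balanced_psp_sizes(q, eta)
  grid <- rate_grid(q, d_max, S)
  if (!is.null(seed)) set.seed(seed)
  dur_ms <- duration * 1000
  rates_out <- vapply(grid, function(R) {
    re <- eta * R
    ri <- (1 - eta) * R
    if (inherits(model, "lif_params")) {
      if (method == "event") {
        n <- cpp_lif_rate_point(model$tau_m, model$v_rest, model$v_thresh,
                                model$t_ref, re, ri,
                                sizes[["qe"]], sizes[["qi"]], dur_ms)
      } else {
        st <- poisson_streams(R, eta, dur_ms)
        n <- length(cpp_lif_clock(model$tau_m, model$v_rest,
                                  model$v_thresh, model$t_ref,
                                  st$exc, st$inh, sizes[["qe"]],
                                  sizes[["qi"]], dur_ms, model$dt))
      }
    } else if (inherits(model, "izhikevich_params")) {
      we <- psc_weight(sizes[["qe"]], model$c_eff, model$tau_syn_exc)
      wi <- psc_weight(sizes[["qi"]], model$c_eff, model$tau_syn_inh)
      n <- length(cpp_izhikevich(model$a, model$b, model$c, model$d,
                                 model$tau_syn_exc, model$tau_syn_inh,
                                 integer(0), integer(0), TRUE, re, ri,
                                 we, wi, 0, dur_ms, model$dt))
    } else {
      we <- psc_weight(sizes[["qe"]], model$c_m, model$tau_syn_exc)
      wi <- psc_weight(sizes[["qi"]], model$c_m, model$tau_syn_inh)
      n <- length(cpp_hh(model$c_m, model$g_na, model$g_k, model$g_l,
                         model$e_na, model$e_k, model$e_l, model$t_ref,
                         model$tau_syn_exc, model$tau_syn_inh,
                         integer(0), integer(0), TRUE, re, ri,
                         we, wi, 0, dur_ms, model$dt))
    }
    n / duration
  }, numeric(1))
  transfer_curve(grid, rates_out, q = q, eta = eta, duration = duration,
                 seed = if (is.null(seed)) NA else seed,
                 model = sub("_params$", "", class(model)[1L]),
                 params = model)
}

#' Write / read a transfer curve as annotated CSV
#'
#' Plain CSV with columns `R_kHz, rate_Hz`; measurement metadata is
#' carried in `#`-prefixed header comment lines (the parameter set as a
#' JSON string).
#'
#' @param x a [transfer_curve()].
#' @param path file path.
#' @return `write_transfer_curve` returns `path` invisibly;
#'   `read_transfer_curve` returns the reconstructed [transfer_curve()].
#' @export
write_transfer_curve <- function(x, path) {
  stopifnot(inherits(x, "transfer_curve"))
  hdr <- c(
    sprintf("# model: %s", attr(x, "model")),
    sprintf("# q_mV: %.17g", attr(x, "q")),
    sprintf("# eta: %.17g", attr(x, "eta")),
    sprintf("# duration_s: %.17g", attr(x, "duration")),
    sprintf("# seed: %s", attr(x, "seed")),
    sprintf("# params: %s",
            jsonlite::toJSON(attr(x, "params"), auto_unbox = TRUE,
                             digits = NA)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(x)[c("R_kHz", "rate_Hz")], con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transfer_curve
#' @export
read_transfer_curve <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  field <- function(key) sub(sprintf("^# %s: ", key), "",
                             grep(sprintf("^# %s:", key), hdr, value = TRUE))
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  seed <- suppressWarnings(as.numeric(field("seed")))
  transfer_curve(df$R_kHz, df$rate_Hz,
                 q = as.numeric(field("q_mV")),
                 eta = as.numeric(field("eta")),
                 duration = as.numeric(field("duration_s")),
                 seed = seed, model = field("model"),
                 params = jsonlite::fromJSON(field("params")))
}

#' Write spikes as two-column CSV
#'
#' @param x a [spike_train()] or a data frame with columns `neuron_id`
#'   and `time_ms` (as returned by [simulate_network()]).
#' @param path file path.
#' @param neuron_id id to stamp on a single spike train.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(x, path, neuron_id = 1L) {
  df <- if (inherits(x, "spike_train")) {
    data.frame(neuron_id = neuron_id, time_ms = x$times)
  } else {
    stopifnot(all(c("neuron_id", "time_ms") %in% names(x)))
    x[c("neuron_id", "time_ms")]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
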