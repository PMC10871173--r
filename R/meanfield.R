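#' Mean-field model of a recurrently connected population
#'
#' Combines a fitted (or given) Refractory SoftPlus transfer function
#' `F` with the wiring statistics of a homogeneous random network: each
#' neuron receives background Poisson input at total rate `r_bg` (kHz)
#' plus spikes from `n_recurrent` other neurons firing at the population
#' rate `r` (Hz), for an effective input rate
#' `R_eff = r_bg + n_recurrent * r / 1000` (kHz).  Population equilibria
#' are the roots of the consistency condition `F(R_eff) = r`.
#'
#' @param params an [rsp_params()] vector or a fitted [fit_rsp()] object
#'   (in which case `q` defaults to the fit's).
#' @param n_recurrent in-degree N (number of recurrent inputs per
#'   neuron), non-negative.
#' @param r_bg total background input rate per neuron (kHz).
#' @param q effective PSP size (mV).
#' @return Object of class `mean_field`.
#' @seealso [fixed_points()], [find_bifurcation()],
#'   [integrate_dynamics()], [recurrent_fraction()]
#' @export
mean_field <- function(params, n_recurrent, r_bg,
                       q = if (inherits(params, "rsp_fit")) params$q else NULL) {
  p <- as_rsp(params)
  if (is.null(q)) stop("`q` is required when `params` is a bare parameter set")
  stopifnot(n_recurrent >= 0, r_bg >= 0, q > 0)
  structure(list(params = p, q = q, n_recurrent = n_recurrent, r_bg = r_bg),
            class = "mean_field")
}

#' @export
print.mean_field <- function(x, ...) {
  cat(sprintf(
    "Mean-field model: N = %g recurrent inputs, R_bg = %g kHz, q = %g mV\n",
    x$n_recurrent, x$r_bg, x$q))
  fp <- fixed_points(x)
  cat(sprintf("  %d fixed point(s): %s\n", nrow(fp),
              paste(sprintf("%.3g Hz (%s)", fp$rate, fp$stability),
                    collapse = ", ")))
  invisible(x)
}

# effective input rate (kHz) at population rate r (Hz)
r_eff <- function(r, model) model$r_bg + model$n_recurrent * r / 1000

mf_F <- function(R, model) refractory_softplus(R, model$params, model$q)

# slope of the feedback map r -> F(R_eff(r)); dimensionless gain
mf_gain <- function(r, model) {
  if (model$n_recurrent == 0) return(rep(0, length(r)))
  R <- r_eff(r, model)
  model$n_recurrent / 1000 *
    refractory_softplus_deriv(pmax(R, 1e-12), model$params, model$q)
}

#' Residual of the mean-field consistency condition
#'
#' `F(R_bg + N r / 1000) - r` in Hz; its zeros are the population's
#' equilibrium firing rates.
#'
#' @param r candidate population rate(s), Hz, non-negative.
#' @param model a [mean_field()] model.
#' @return Residual in Hz, same shape as `r`.
#' @export
consistency_residual <- function(r, model) {
  stopifnot(inherits(model, "mean_field"), all(r >= 0))
  mf_F(r_eff(r, model), model) - r
}

rate_ceiling <- function(model) {
  t_ref <- model$params[["t_ref"]]
  if (t_ref > 1e-6) 1000 / t_ref
  else 2 * mf_F(r_eff(2000, model), model) + 100
}

#' Equilibrium firing rates of a mean-field model
#'
#' Finds all roots of [consistency_residual()] on `[0, r_max]` by a
#' dense bracketing scan followed by bisection, and classifies each by
#' the feedback gain `N F'(R_eff) / 1000`: gain below 1 is stable,
#' above 1 unstable.  For this model family the count is 1, 2 (at a
#' tangency), or 3.
#'
#' @param model a [mean_field()] model.
#' @param r_max top of the search interval (Hz); defaults to 1.2 times
#'   the refractory rate ceiling.
#' @param n_scan number of scan points for bracketing.
#' @param tol bisection tolerance (Hz).
#' @return Data frame with columns `rate` (Hz), `gain`, and `stability`
#'   (`"stable"` or `"unstable"`), ordered by rate.
#' @export
fixed_points <- function(model, r_max = NULL, n_scan = 2000, tol = 1e-6) {
  stopifnot(inherits(model, "mean_field"))
  if (is.null(r_max)) r_max <- 1.2 * rate_ceiling(model)
  grid <- seq(0, r_max, length.out = n_scan)
  res <- consistency_residual(grid, model)
  roots <- numeric(0)
  sgn <- sign(res)
  for (i in seq_len(n_scan - 1L)) {
    if (sgn[i] == 0) next
    if (sgn[i] * sgn[i + 1L] < 0) {
      roots <- c(roots, uniroot(function(r) consistency_residual(r, model),
                                c(grid[i], grid[i + 1L]),
                                tol = tol)$root)
    }
  }
  roots <- c(roots, grid[which(res == 0)])
  roots <- sort(unique(roots))
  gain <- if (length(roots)) mf_gain(roots, model) else numeric(0)
  data.frame(rate = roots, gain = gain,
             stability = ifelse(gain < 1, "stable", "unstable"))
}

#' Locate the saddle-node bifurcation in the in-degree N
#'
#' Scans integer in-degrees for the smallest `N` at which the
#' consistency condition gains an upper pair of fixed points, then
#' refines the tangency continuously by solving `F(u) = r` together
#' with the tangency condition `(u - R_bg) F'(u) = F(u)` for the
#' effective input rate `u` at which the consistency curve touches the
#' identity line.
#'
#' In-degree is an integer in any actual network, so the bifurcation is
#' reported primarily at integer resolution: `n_critical` is the
#' smallest in-degree at which the bistable pair exists, and `r_half`
#' is the rate of the member of that newly created pair whose feedback
#' gain is nearest 1 — the operational "half-stable" point of the
#' bifurcation diagram.  The continuous tangency `(n_continuous,
#' r_tangent)` is also returned; note that because the pair separates
#' as the square root of `N - n_continuous`, the tangency rate itself
#' is a hypersensitive quantity, moving by several Hz for sub-unit
#' changes in the tangency in-degree.
#'
#' @param model a [mean_field()] model; its `n_recurrent` is ignored
#'   and scanned over `n_range`.
#' @param n_range integer interval to scan; the family must be
#'   monostable at its lower end.
#' @return Object of class `bifurcation`: a list with `monostable`
#'   (logical), and when a bifurcation exists `n_critical` (smallest
#'   integer N with multiple fixed points), `r_half` (Hz, see above),
#'   `n_continuous` (real tangency N), and `r_tangent` (Hz, rate at
#'   the continuous tangency).
#' @export
find_bifurcation <- function(model, n_range = c(0, 200)) {
  stopifnot(inherits(model, "mean_field"), length(n_range) == 2L)
  n_lo <- ceiling(n_range[1L])
  n_hi <- floor(n_range[2L])
  at_n <- function(N) {
    m <- model
    m$n_recurrent <- N
    m
  }
  count <- function(N) nrow(fixed_points(at_n(N)))
  if (count(n_lo) > 1L)
    stop("family is not monostable at the lower end of `n_range`")

  # coarse upward scan, then integer bisection for the smallest
  # multi-stable N
  step <- max(1L, floor((n_hi - n_lo) / 40))
  found <- NA_integer_
  for (N in seq(n_lo, n_hi, by = step)) {
    if (count(N) > 1L) { found <- N; break }
  }
  if (is.na(found) && count(n_hi) > 1L) found <- n_hi
  if (is.na(found))
    return(structure(list(monostable = TRUE, n_range = c(n_lo, n_hi)),
                     class = "bifurcation"))
  lo <- max(n_lo, found - step)
  hi <- found
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (count(mid) > 1L) hi <- mid else lo <- mid
  }
  n_critical <- hi

  # the operational half-stable point: among the pair created at the
  # first bistable integer N, the fixed point with gain nearest 1
  fp_crit <- fixed_points(at_n(n_critical))
  pair <- fp_crit[-1L, , drop = FALSE]         # drop the low-rate branch
  r_half <- pair$rate[which.min(abs(pair$gain - 1))]

  # continuous tangency: root of phi(u) = (u - R_bg) F'(u) - F(u) whose
  # implied N is smallest (the pair-creating tangency)
  Fd <- function(u) refractory_softplus_deriv(u, model$params, model$q)
  Fu <- function(u) mf_F(u, model)
  phi <- function(u) (u - model$r_bg) * Fd(u) - Fu(u)
  u_max <- model$r_bg + n_hi * rate_ceiling(model) / 1000
  ug <- seq(model$r_bg + 1e-9, u_max, length.out = 4000)
  pv <- phi(ug)
  n_cont <- r_tan <- NA_real_
  best_n <- Inf
  for (i in seq_len(length(ug) - 1L)) {
    if (sign(pv[i]) * sign(pv[i + 1L]) < 0) {
      u0 <- uniroot(phi, c(ug[i], ug[i + 1L]), tol = 1e-10)$root
      Ni <- 1000 * (u0 - model$r_bg) / Fu(u0)
      if (Ni < best_n && Ni >= n_lo - 1 && Ni <= n_hi + 1) {
        best_n <- Ni
        n_cont <- Ni
        r_tan <- Fu(u0)
      }
    }
  }
  if (!is.finite(best_n)) {
    # fall back to the near-tangent pair at the first bistable N
    fp <- fixed_points(at_n(n_critical))
    new_pair <- tail(fp$rate, 2L)
    r_tan <- exp(mean(log(pmax(new_pair, 1e-12))))
    n_cont <- NA_real_
  }
  structure(list(monostable = FALSE, n_critical = n_critical,
                 r_half = r_half, n_continuous = n_cont,
                 r_tangent = r_tan, n_range = c(n_lo, n_hi)),
            class = "bifurcation")
}

#' @export
print.bifurcation <- function(x, ...) {
  if (x$monostable) {
    cat(sprintf("Monostable throughout N in [%d, %d]\n",
                x$n_range[1L], x$n_range[2L]))
  } else {
    cat(sprintf(
      "Saddle-node bifurcation: first bistable at integer N = %d (half-stable point %.2f Hz)\n",
      x$n_critical, x$r_half))
    cat(sprintf("  continuous tangency at N = %.3f, rate %.2f Hz\n",
                x$n_continuous, x$r_tangent))
  }
  invisible(x)
}

#' Time-varying background stimulus specification
#'
#' Background input rate `R_bg(t)` (kHz) as a constant, a step, or a
#' sinusoid `base + amplitude * sin(2 pi frequency t)`.
#'
#' @param type one of `"constant"`, `"step"`, `"sinusoid"`.
#' @param base baseline rate (kHz).
#' @param amplitude step height or sine amplitude (kHz).
#' @param frequency sine frequency (Hz).
#' @param t_on step onset (ms).
#' @return Object of class `stimulus`.
#' @export
stimulus <- function(type = c("constant", "step", "sinusoid"), base,
                     amplitude = 0, frequency = 1, t_on = 0) {
  type <- match.arg(type)
  stopifnot(base >= 0)
  structure(list(type = type, base = base, amplitude = amplitude,
                 frequency = frequency, t_on = t_on), class = "stimulus")
}

stim_eval <- function(stim, t) {
  v <- switch(stim$type,
    constant = rep(stim$base, length(t)),
    step = stim$base + stim$amplitude * (t >= stim$t_on),
    sinusoid = stim$base +
      stim$amplitude * sin(2 * pi * stim$frequency * t / 1000))
  pmax(v, 0)
}

#' Integrate first-order mean-field rate dynamics
#'
#' Explicit fixed-step RK4 integration of
#' `T dr/dt = F(N r / 1000 + R_bg(t)) - r`, the first-order relaxation
#' of the population rate toward its transfer-function value with
#' characteristic timescale `T` (ms).  Under a constant stimulus the
#' stationary points coincide with [fixed_points()].
#'
#' @param model a [mean_field()] model.
#' @param r0 initial rate (Hz), non-negative.
#' @param horizon integration span (ms).
#' @param stim a [stimulus()]; defaults to the model's constant `r_bg`.
#' @param timescale dynamics timescale `T` (ms); 1 ms suits
#'   stimulus-following runs.
#' @param step integration step (ms); default `min(timescale / 10,
#'   0.1)`.  Must be smaller than `timescale`.
#' @return Data frame (`t_ms`, `rate_Hz`, `R_bg_kHz`) of class
#'   `rate_trajectory`.
#' @export
integrate_dynamics <- function(model, r0, horizon,
                               stim = stimulus("constant", model$r_bg),
                               timescale = 1, step = NULL) {
  stopifnot(inherits(model, "mean_field"), r0 >= 0, horizon > 0,
            timescale > 0, inherits(stim, "stimulus"))
  if (is.null(step)) step <- min(timescale / 10, 0.1)
  if (step >= timescale)
    stop("integration `step` must be smaller than the dynamics timescale")
  n <- ceiling(horizon / step)
  t_out <- seq(0, by = step, length.out = n + 1L)
  rb <- stim_eval(stim, t_out)
  rb_half <- stim_eval(stim, t_out + step / 2)
  rate <- numeric(n + 1L)
  rate[1L] <- r0
  deriv <- function(r, R_bg) {
    (mf_F(R_bg + model$n_recurrent * max(r, 0) / 1000, model) - r) / timescale
  }
  for (i in seq_len(n)) {
    r <- rate[i]
    k1 <- deriv(r, rb[i])
    k2 <- deriv(r + step / 2 * k1, rb_half[i])
    k3 <- deriv(r + step / 2 * k2, rb_half[i])
    k4 <- deriv(r + step * k3, rb[i + 1L])
    rate[i + 1L] <- max(r + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
  }
  structure(data.frame(t_ms = t_out, rate_Hz = rate, R_bg_kHz = rb),
            class = c("rate_trajectory", "data.frame"))
}

#' @export
plot.rate_trajectory <- function(x, ...) {
  plot(x$t_ms, x$rate_Hz, type = "l", xlab = "time (ms)",
       ylab = "population rate (Hz)", ...)
}

#' Recurrent fraction of the synaptic input at a fixed point
#'
#' Fraction `N r / (1000 R_bg + N r)` of a neuron's total input rate
#' that arrives from the rest of the network rather than the
#' background, at population rate `r`.
#'
#' @param model a [mean_field()] model.
#' @param fp a fixed-point rate in Hz (numeric), or a row of
#'   [fixed_points()] output.
#' @return Fraction in \[0, 1\].
#' @export
recurrent_fraction <- function(model, fp) {
  stopifnot(inherits(model, "mean_field"))
  r <- if (is.data.frame(fp)) fp$rate else as.numeric(fp)
  stopifnot(all(r >= 0))
  rec <- model$n_recurrent * r / 1000
  tot <- model$r_bg + rec
  ifelse(tot > 0, rec / tot, 0)
}
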