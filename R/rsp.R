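#' Numerically stable SoftPlus
#'
#' `softplus(x; beta) = log(1 + exp(beta * x)) / beta`, a smooth ramp
#' that converges to `max(x, 0)` as `beta` grows.  Above `beta * x =
#' cutoff` the ramp value `x` is returned exactly; at the default cutoff
#' of 20 the relative error of that switch is about 1e-10.
#'
#' @param x input (any numeric vector).
#' @param beta sharpness, > 0.
#' @param cutoff value of `beta * x` beyond which the linear branch is
#'   used.
#' @return Numeric vector the shape of `x`.
#' @export
softplus <- function(x, beta = 1, cutoff = 20) {
  stopifnot(beta > 0)
  bx <- beta * x
  out <- numeric(length(x))
  hi <- bx > cutoff
  out[hi] <- x[hi]
  out[!hi] <- log1p(exp(bx[!hi])) / beta
  out
}

#' Refractory SoftPlus parameter set
#'
#' The fitted quadruple of the Refractory SoftPlus transfer function.
#' `alpha` converts the SoftPlus output into an instantaneous rate
#' (1/ms per mV ms^-1/2), `beta` is the SoftPlus sharpness, `sigma0`
#' shifts the input `q * sqrt(R)` (mV ms^-1/2), and `t_ref` (ms) is the
#' refractory period imposing the rate ceiling `1000 / t_ref` Hz.
#'
#' @param alpha,beta,sigma0,t_ref see description; `alpha, beta > 0`,
#'   `t_ref >= 0`.
#' @return Named numeric vector of class `rsp_params`.
#' @export
rsp_params <- function(alpha, beta, sigma0, t_ref) {
  stopifnot(alpha > 0, beta > 0, t_ref >= 0)
  structure(c(alpha = alpha, beta = beta, sigma0 = sigma0, t_ref = t_ref),
            class = "rsp_params")
}

#' Refractory SoftPlus transfer function
#'
#' Firing rate of a neuron under balanced Poisson input at total rate
#' `R`, modeled by passing `q * sqrt(R)` (the square root of the
#' diffusion coefficient) through a shifted, scaled SoftPlus and adding
#' a refractory period to the resulting interspike interval:
#' `rate = 1 / (t_ref + 1 / (alpha * softplus(q * sqrt(R) - sigma0; beta)))`,
#' returned in Hz.  Strictly increasing in `R` and bounded above by
#' `1000 / t_ref` Hz.
#'
#' @param R total input rate (kHz), non-negative vector.
#' @param params an [rsp_params()] (or a fitted [fit_rsp()] object).
#' @param q effective PSP size (mV); a known constant of the input
#'   model, not a fitted parameter.
#' @return Firing rates in Hz.
#' @export
refractory_softplus <- function(R, params, q) {
  p <- as_rsp(params)
  stopifnot(all(R >= 0), q > 0)
  s <- softplus(q * sqrt(R) - p[["sigma0"]], p[["beta"]])
  1000 / (p[["t_ref"]] + 1 / (p[["alpha"]] * s))
}

#' Derivative of the Refractory SoftPlus transfer function
#'
#' Closed-form `dF/dR` in Hz per kHz, used for fixed-point stability and
#' tangency (saddle-node) conditions.  Undefined at `R = 0`, where the
#' square-root input has infinite slope.
#'
#' @inheritParams refractory_softplus
#' @return Derivative values in Hz/kHz.
#' @export
refractory_softplus_deriv <- function(R, params, q) {
  p <- as_rsp(params)
  stopifnot(all(R > 0))
  x <- q * sqrt(R) - p[["sigma0"]]
  s <- softplus(x, p[["beta"]])
  f <- 1 / (p[["t_ref"]] + 1 / (p[["alpha"]] * s))  # rate per ms
  dsdR <- stats::plogis(p[["beta"]] * x) * q / (2 * sqrt(R))
  1000 * f^2 * dsdR / (p[["alpha"]] * s^2)
}

as_rsp <- function(params) {
  if (inherits(params, "rsp_fit")) return(params$coefficients)
  if (inherits(params, "rsp_params")) return(params)
  if (is.numeric(params) &&
      all(c("alpha", "beta", "sigma0", "t_ref") %in% names(params)))
    return(params)
  stop("`params` must be an rsp_params vector or a fitted rsp_fit object")
}

rsp_predict <- function(par, x) {
  # par on the optimizer scale, x = q * sqrt(R); rate in Hz
  s <- softplus(x - par[["sigma0"]], par[["beta"]])
  1000 / (par[["t_ref"]] + 1 / (par[["alpha"]] * s))
}

#' Fit the Refractory SoftPlus transfer function to a measured curve
#'
#' Nonlinear least squares (Levenberg-Marquardt with box constraints
#' `alpha, beta > 0`, `t_ref >= 0`) of the four Refractory SoftPlus
#' parameters to a [transfer_curve()], with the PSP size `q` taken from
#' the curve as a known constant.  Residuals are unweighted and taken on
#' the Hz scale.  Initial values follow the shape of the curve (ceiling
#' for `t_ref`, upper-third slope for `alpha`, 1%-of-max crossing for
#' `sigma0`); on failure to converge, up to `restarts` jittered restarts
#' are attempted and the best solution kept.
#'
#' @param curve a [transfer_curve()] (at least 4 points), or a data
#'   frame with columns `R_kHz` and `rate_Hz` plus a `q` argument.
#' @param q effective PSP size (mV); defaults to the curve attribute.
#' @param restarts number of jittered restarts allowed on
#'   non-convergence.
#' @return Object of class `rsp_fit` with components `coefficients`
#'   (an [rsp_params()]), `nrmse` (RMS residual / max observed rate),
#'   `n_points`, `converged`, `q`, `eta`, `model`, and `curve`.
#'   Standard methods ([coef()], [predict()], [fitted()],
#'   [residuals()], [summary()], [plot()], [simulate()]) apply.
#' @seealso [refractory_softplus()], [normalized_rms_error()],
#'   [mean_field()]
#' @export
fit_rsp <- function(curve, q = attr(curve, "q"), restarts = 3) {
  stopifnot(is.data.frame(curve),
            all(c("R_kHz", "rate_Hz") %in% names(curve)))
  if (nrow(curve) < 4L)
    stop("need at least 4 curve points to fit 4 parameters")
  if (is.null(q)) stop("`q` is required when the curve carries no attribute")
  R <- curve$R_kHz
  y <- curve$rate_Hz
  x <- q * sqrt(R)
  out <- list(n_points = length(y), q = q,
              eta = attr(curve, "eta"), model = attr(curve, "model"),
              curve = curve)
  if (max(y) <= 0) {
    out$coefficients <- rsp_params(1e-6, 1, max(x), 1)
    out$nrmse <- 0
    out$converged <- FALSE
    class(out) <- "rsp_fit"
    return(out)
  }

  init <- local({
    t_ref0 <- min(1000 / max(y), 10)
    i0 <- which(y > 0.01 * max(y))[1L]
    sigma00 <- x[max(i0, 1L)]
    upper <- x >= quantile(x, 2 / 3)
    sl <- if (sum(upper) >= 2)
      coef(lm(y[upper] ~ x[upper]))[[2L]] else max(y) / max(x)
    alpha0 <- max(sl, 1e-3) / 1000   # Hz/x to ms^-1/x
    c(alpha = alpha0, beta = 1, sigma0 = sigma00, t_ref = t_ref0)
  })

  lower <- c(alpha = 1e-10, beta = 1e-10, sigma0 = -Inf, t_ref = 0)
  do_fit <- function(par0) {
    minpack.lm::nls.lm(
      par = pmax(par0, c(1e-9, 1e-9, -Inf, 0)),
      lower = lower,
      fn = function(p) rsp_predict(p, x) - y,
      control = minpack.lm::nls.lm.control(maxiter = 500))
  }

  # a Levenberg-Marquardt run can report convergence from a degenerate
  # basin (e.g. beta collapsing to its bound, predicting a constant), so
  # always try a small deterministic family of starts and keep the best;
  # add jittered restarts while the best fit still looks poor
  starts <- list(init,
                 replace(init, "beta", 5),
                 replace(init, "beta", 0.2))
  best <- NULL
  for (par0 in starts) {
    fit <- tryCatch(do_fit(par0), error = function(e) NULL)
    if (!is.null(fit) && all(is.finite(unlist(fit$par))) &&
        (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  ok <- function(f) !is.null(f) &&
    sqrt(f$deviance / length(y)) / max(y) < 0.05 && f$info %in% 1:4
  for (k in seq_len(restarts)) {
    if (ok(best)) break
    par0 <- init * exp(rnorm(4, 0, 0.4))
    par0[["sigma0"]] <- init[["sigma0"]] + rnorm(1, 0, 0.2 * max(x))
    fit <- tryCatch(do_fit(par0), error = function(e) NULL)
    if (!is.null(fit) && all(is.finite(unlist(fit$par))) &&
        (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best))
    stop("Refractory SoftPlus fit failed to produce finite parameters")

  p <- unlist(best$par)
  out$coefficients <- rsp_params(p[["alpha"]], p[["beta"]],
                                 p[["sigma0"]], p[["t_ref"]])
  out$nrmse <- sqrt(best$deviance / length(y)) / max(y)
  out$converged <- best$info %in% 1:4
  class(out) <- "rsp_fit"
  out
}

#' @export
coef.rsp_fit <- function(object, ...) object$coefficients

#' @export
print.rsp_fit <- function(x, ...) {
  p <- x$coefficients
  cat(sprintf("Refractory SoftPlus fit (%s neuron, %d points, q = %g mV)\n",
              x$model %||% "?", x$n_points, x$q))
  cat(sprintf("  alpha  = %.5g  1/ms per mV ms^-1/2\n", p[["alpha"]]))
  cat(sprintf("  beta   = %.5g  per mV ms^-1/2\n", p[["beta"]]))
  cat(sprintf("  sigma0 = %.5g  mV ms^-1/2\n", p[["sigma0"]]))
  cat(sprintf("  t_ref  = %.5g  ms  (rate ceiling %.1f Hz)\n",
              p[["t_ref"]], 1000 / p[["t_ref"]]))
  cat(sprintf("  NRMSE  = %.4g%s\n", x$nrmse,
              if (isTRUE(x$converged)) "" else "  [did not converge]"))
  invisible(x)
}

#' @export
summary.rsp_fit <- function(object, ...) {
  res <- residuals(object)
  structure(list(fit = object, resid_summary = summary(res),
                 max_rate = max(object$curve$rate_Hz)),
            class = "summary.rsp_fit")
}

#' @export
print.summary.rsp_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  max observed rate %.2f Hz; residuals (Hz):\n", x$max_rate))
  print(x$resid_summary)
  invisible(x)
}

#' @export
predict.rsp_fit <- function(object, newdata = NULL, ...) {
  R <- if (is.null(newdata)) object$curve$R_kHz
       else if (is.data.frame(newdata)) newdata$R_kHz
       else as.numeric(newdata)
  refractory_softplus(R, object$coefficients, object$q)
}

#' @export
fitted.rsp_fit <- function(object, ...) predict(object)

#' @export
residuals.rsp_fit <- function(object, ...)
  object$curve$rate_Hz - fitted(object)

#' @export
plot.rsp_fit <- function(x, ...) {
  plot(x$curve$R_kHz, x$curve$rate_Hz, xlab = "input rate R (kHz)",
       ylab = "firing rate (Hz)", main = "Refractory SoftPlus fit", ...)
  Rg <- seq(min(x$curve$R_kHz), max(x$curve$R_kHz), length.out = 400)
  lines(Rg, refractory_softplus(Rg, x$coefficients, x$q), col = 2, lwd = 2)
  invisible(x)
}

#' Simulate transfer curves from a fitted Refractory SoftPlus model
#'
#' Parametric resampling: per-point spike counts are drawn as Poisson
#' variates with mean `rate * duration` and converted back to rates,
#' emulating a fresh measurement of the fitted transfer function.
#'
#' @param object an `rsp_fit`.
#' @param nsim number of curves.
#' @param seed optional seed.
#' @param duration per-point duration (s) controlling counting noise.
#' @param ... unused.
#' @return A list of [transfer_curve()]s (length `nsim`).
#' @export
simulate.rsp_fit <- function(object, nsim = 1, seed = NULL,
                             duration = attr(object$curve, "duration") %||% 100,
                             ...) {
  if (is.na(duration)) duration <- 100
  if (!is.null(seed)) set.seed(seed)
  R <- object$curve$R_kHz
  mu <- predict(object) * duration
  lapply(seq_len(nsim), function(i)
    transfer_curve(R, rpois(length(mu), mu) / duration, q = object$q,
                   eta = object$eta, duration = duration,
                   model = paste0(object$model %||% "rsp", "-simulated")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a Refractory SoftPlus fit as JSON
#'
#' Writes the fitted quadruple plus fit metadata as a flat JSON object:
#' `{alpha, beta, sigma0, t_ref_ms, nrmse, n_points, model, q_mV, eta}`.
#'
#' @param fit an [fit_rsp()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "rsp_fit"))
  p <- fit$coefficients
  obj <- list(alpha = p[["alpha"]], beta = p[["beta"]],
              sigma0 = p[["sigma0"]], t_ref_ms = p[["t_ref"]],
              nrmse = fit$nrmse, n_points = fit$n_points,
              model = fit$model %||% NA, q_mV = fit$q,
              eta = fit$eta %||% NA)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Normalized RMS error of a transfer-function fit
#'
#' RMS of (predicted - observed) over the curve, divided by the maximum
#' observed rate.  Dimensionless; invariant to jointly rescaling rates
#' and predictions.
#'
#' @param object an [rsp_fit()], [rsp_params()], or baseline fit.
#' @param curve a [transfer_curve()] (or data frame with `R_kHz`,
#'   `rate_Hz`) to evaluate against; it need not be the curve the
#'   parameters were fitted to.
#' @param q PSP size (mV), defaulting to the curve's attribute.
#' @return Fraction (not percent).
#' @export
normalized_rms_error <- function(object, curve, q = attr(curve, "q")) {
  stopifnot(all(c("R_kHz", "rate_Hz") %in% names(curve)))
  if (max(curve$rate_Hz) <= 0)
    stop("cannot normalize against an all-zero curve")
  pred <- if (inherits(object, c("rsp_fit", "baseline_fit"))) {
    predict(object, curve$R_kHz)
  } else {
    refractory_softplus(curve$R_kHz, object, q)
  }
  sqrt(mean((pred - curve$rate_Hz)^2)) / max(curve$rate_Hz)
}
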