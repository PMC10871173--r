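#' Baseline transfer-function fits: scaled sigmoid and ReLU
#'
#' Comparison fitters used to benchmark Refractory SoftPlus.  Both are
#' univariate functions of `sqrt(D) = q * sqrt(R)` with scale and shift
#' parameters, fitted by the same Levenberg-Marquardt least squares as
#' [fit_rsp()]:
#' * `"sigmoid"`: `rate = a * (1 + tanh((x - c) / b)) / 2` (saturating);
#' * `"relu"`: `rate = a * max(x - c, 0)` (unbounded ramp).
#'
#' @param curve a [transfer_curve()] with at least as many points as
#'   parameters.
#' @param kind which baseline to fit.
#' @param q PSP size (mV), defaulting to the curve attribute.
#' @return Object of class `baseline_fit` with `coefficients`, `nrmse`,
#'   `kind`, and `q`; supports [coef()] and [predict()].
#' @export
fit_baseline <- function(curve, kind = c("sigmoid", "relu"),
                         q = attr(curve, "q")) {
  kind <- match.arg(kind)
  stopifnot(all(c("R_kHz", "rate_Hz") %in% names(curve)), nrow(curve) >= 4)
  x <- q * sqrt(curve$R_kHz)
  y <- curve$rate_Hz
  if (max(y) <= 0) stop("all-zero curve: nothing to fit")
  pred <- function(p, x) {
    if (kind == "sigmoid") p[["a"]] * (1 + tanh((x - p[["c"]]) / p[["b"]])) / 2
    else p[["a"]] * pmax(x - p[["c"]], 0)
  }
  par0 <- if (kind == "sigmoid") {
    c(a = max(y), b = diff(range(x)) / 4,
      c = x[which.min(abs(y - max(y) / 2))])
  } else {
    upper <- x >= stats::quantile(x, 0.5)
    sl <- coef(lm(y[upper] ~ x[upper]))[[2L]]
    c(a = max(sl, 1e-6), c = x[which(y > 0.01 * max(y))[1L]])
  }
  lower <- if (kind == "sigmoid") c(a = 1e-9, b = 1e-9, c = -Inf)
           else c(a = 1e-9, c = -Inf)
  fit <- minpack.lm::nls.lm(par = par0, lower = lower,
                            fn = function(p) pred(p, x) - y,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  structure(list(coefficients = unlist(fit$par),
                 nrmse = sqrt(fit$deviance / length(y)) / max(y),
                 kind = kind, q = q, curve = curve),
            class = "baseline_fit")
}

#' @export
coef.baseline_fit <- function(object, ...) object$coefficients

#' @export
predict.baseline_fit <- function(object, newdata = NULL, ...) {
  R <- if (is.null(newdata)) object$curve$R_kHz
       else if (is.data.frame(newdata)) newdata$R_kHz
       else as.numeric(newdata)
  x <- object$q * sqrt(R)
  p <- object$coefficients
  if (object$kind == "sigmoid")
    p[["a"]] * (1 + tanh((x - p[["c"]]) / p[["b"]])) / 2
  else p[["a"]] * pmax(x - p[["c"]], 0)
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf("Baseline %s fit: %s; NRMSE = %.4g\n", x$kind,
              paste(sprintf("%s = %.4g", names(x$coefficients),
                            x$coefficients), collapse = ", "),
              x$nrmse))
  invisible(x)
}
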