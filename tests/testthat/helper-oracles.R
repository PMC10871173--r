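# Independent oracles used by the tests; deliberately simple and separate
# from the package's own numerical paths.

# Diffusion-limit (Ornstein-Uhlenbeck) mean first-passage firing rate of the
# LIF neuron under zero-drift white noise with diffusion coefficient D
# (mV^2/ms): the classical quadrature formula, evaluated with stats::integrate.
siegert_rate <- function(params, D) {
  stopifnot(D > 0)
  erf <- function(u) 2 * pnorm(u * sqrt(2)) - 1
  b <- (params$v_thresh - params$v_rest) / sqrt(D * params$tau_m)
  I <- stats::integrate(function(u) exp(u^2) * (1 + erf(u)), 0, b,
                        rel.tol = 1e-10)$value
  1000 / (params$t_ref + params$tau_m * sqrt(pi) * I)  # Hz
}

# Dense-scan root finder for the consistency condition, at 0.01 Hz
# resolution: the brute-force counterpart of fixed_points().
brute_fixed_points <- function(model, r_max = 600, dr = 0.01) {
  r <- seq(0, r_max, by = dr)
  res <- consistency_residual(r, model)
  i <- which(diff(sign(res)) != 0)
  (r[i] + r[i + 1]) / 2
}

# Exact discrete simulation of an OU process observed at bin spacing dt:
# AR(1) with coefficient exp(-dt/tau) and the matching stationary sd.
simulate_ou <- function(n, mean, sigma, tau, dt = 1) {
  rho <- exp(-dt / tau)
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sigma)
  innov_sd <- sigma * sqrt(1 - rho^2)
  for (i in 2:n) x[i] <- rho * x[i - 1] + rnorm(1, 0, innov_sd)
  x + mean
}

# Shared LIF reference transfer curve (measured once per test run).
lif_fixture_env <- new.env()
lif_fixture_curve <- function() {
  if (is.null(lif_fixture_env$curve)) {
    lif_fixture_env$curve <- measure_transfer_curve(
      lif_params(), q = 1, eta = 0.8, S = 60, d_max = 100,
      duration = 20, seed = 424242)
  }
  lif_fixture_env$curve
}
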