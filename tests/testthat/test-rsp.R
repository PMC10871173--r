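test_that("softplus closed forms and the stability cutoff hold", {
  for (beta in c(0.5, 1, 4)) {
    expect_equal(softplus(0, beta), log(2) / beta)
  }
  expect_equal(softplus(-50, 1), exp(-50), tolerance = 1e-6)
  # relative error at the cutoff point beta*x = 20
  expect_equal(log1p(exp(20)) / 20 - 1, 1.03e-10, tolerance = 0.01)
  # linear branch above the cutoff is exact
  expect_identical(softplus(30, 1), 30)
  expect_equal(softplus(10, 2), 10 + log1p(exp(-20)) / 2, tolerance = 1e-12)
})

test_that("refractory softplus has the stated closed forms and limits", {
  p <- rsp_params(alpha = 0.02, beta = 1.5, sigma0 = 3, t_ref = 2)
  # at the offset point q*sqrt(R) = sigma0
  R0 <- (3 / 2)^2  # q = 2
  expect_equal(refractory_softplus(R0, p, 2),
               1000 / (2 + 1.5 / (0.02 * log(2))))
  # refractory ceiling
  expect_equal(refractory_softplus(1e12, p, 2), 1000 / 2, tolerance = 1e-4)
  # ReLU asymptote at t_ref = 0
  p0 <- rsp_params(alpha = 0.02, beta = 1.5, sigma0 = 3, t_ref = 0)
  x <- 40  # q*sqrt(R) >> sigma0
  expect_equal(refractory_softplus((x / 2)^2, p0, 2),
               1000 * 0.02 * (x - 3), tolerance = 1e-6)
})

test_that("fitted transfer functions are increasing and ceiling-bounded", {
  set.seed(2)
  for (i in 1:10) {
    p <- rsp_params(alpha = runif(1, 0.005, 0.05), beta = runif(1, 0.3, 5),
                    sigma0 = runif(1, 0, 5), t_ref = runif(1, 0.5, 4))
    R <- seq(0, 200, length.out = 2000)
    y <- refractory_softplus(R, p, 1)
    expect_true(all(diff(y) > 0))
    expect_true(all(y < 1000 / p[["t_ref"]]))
    expect_true(all(y > 0))
  }
})

test_that("noiseless parameter recovery is essentially exact", {
  p0 <- rsp_params(0.011, 2.4, 3.4, 2.1)
  R <- rate_grid(5, 100, 80)
  cur <- transfer_curve(R, refractory_softplus(R, p0, 5), q = 5, eta = 0.8,
                        duration = NA)
  f <- fit_rsp(cur)
  expect_true(f$converged)
  expect_lt(max(abs(coef(f) - p0) / p0), 1e-4)
  expect_lt(f$nrmse, 1e-8)
})

test_that("the refractory period is identifiable under mild rate noise", {
  p1 <- rsp_params(0.011, 2.6, 2.65, 1.8)
  R <- rate_grid(1, 100, 500)
  y <- refractory_softplus(R, p1, 1)
  set.seed(5)
  for (i in 1:4) {
    yn <- pmax(y + rnorm(length(y), 0, 0.02 * max(y)), 0)
    f <- fit_rsp(transfer_curve(R, yn, q = 1, eta = 0.5, duration = NA))
    expect_lt(abs(coef(f)[["t_ref"]] - 1.8), 0.5)
  }
})

test_that("fit handles degenerate and undersized curves as specified", {
  R <- rate_grid(1, 100, 10)
  zero <- transfer_curve(R, rep(0, 10), q = 1, eta = 0.5, duration = NA)
  f <- fit_rsp(zero)
  expect_false(f$converged)
  expect_error(fit_rsp(transfer_curve(c(0, 1, 2), c(0, 1, 2), q = 1,
                                      eta = 0.5, duration = NA)),
               "4")
})

test_that("normalized RMS error matches its definition and guards zeros", {
  p <- rsp_params(0.02, 1.5, 3, 2)
  R <- rate_grid(2, 50, 30)
  y <- refractory_softplus(R, p, 2)
  cur <- transfer_curve(R, y, q = 2, eta = 0.5, duration = NA)
  expect_equal(normalized_rms_error(p, cur), 0)
  yn <- pmax(y + seq(-2, 2, length.out = 30), 0)
  curn <- transfer_curve(R, yn, q = 2, eta = 0.5, duration = NA)
  manual <- sqrt(mean((y - yn)^2)) / max(yn)
  expect_equal(normalized_rms_error(p, curn), manual)
  expect_error(
    normalized_rms_error(p, transfer_curve(R, rep(0, 30), q = 2,
                                           eta = 0.5, duration = NA)),
    "zero")
})

test_that("fit quality on a measured LIF curve beats the baselines", {
  cur <- lif_fixture_curve()
  f <- fit_rsp(cur)
  relu <- fit_baseline(cur, "relu")
  expect_lte(f$nrmse, relu$nrmse)
  # a sigmoid fitted to the left half saturates and undershoots the top
  half <- transfer_curve(cur$R_kHz[1:30], cur$rate_Hz[1:30], q = 1,
                         eta = 0.8, duration = attr(cur, "duration"))
  sig <- fit_baseline(half, "sigmoid")
  top <- nrow(cur)
  expect_lt(predict(sig, cur$R_kHz[top]), 0.9 * cur$rate_Hz[top])
  expect_gt(normalized_rms_error(sig, cur), normalized_rms_error(f, cur))
})

test_that("ReLU baseline recovers a noiseless ramp exactly", {
  R <- rate_grid(1, 100, 50)
  x <- sqrt(R)
  y <- 8 * pmax(x - 2, 0)
  cur <- transfer_curve(R, y, q = 1, eta = 0.5, duration = NA)
  b <- fit_baseline(cur, "relu")
  expect_equal(unname(coef(b)), c(8, 2), tolerance = 1e-6)
  expect_lt(b$nrmse, 1e-8)
})

test_that("simulated curves from a fit behave like fresh measurements", {
  cur <- lif_fixture_curve()
  f <- fit_rsp(cur)
  sims <- simulate(f, nsim = 2, seed = 99, duration = 50)
  expect_length(sims, 2)
  expect_equal(sims[[1]]$R_kHz, cur$R_kHz)
  # counting noise scale: residuals vs fit are Poisson-sized
  resid <- sims[[1]]$rate_Hz - predict(f)
  expect_lt(max(abs(resid) / sqrt(pmax(predict(f), 5) / 50)), 5)
})
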