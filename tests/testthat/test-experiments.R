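test_that("distribution descriptors draw as specified", {
  set.seed(1)
  e <- replicate(4000, rsoftplus:::draw_param(dist_exp(2)))
  expect_equal(mean(e), 2, tolerance = 0.15)
  n <- replicate(4000, rsoftplus:::draw_param(dist_norm(1, 2)))
  expect_true(all(n > 0))                      # positivity resampling
  u <- replicate(2000, rsoftplus:::draw_param(dist_uniform(0.02, 0.1)))
  expect_true(all(u >= 0.02 & u <= 0.1))
  # stock specs follow the randomization table
  liff <- default_param_distributions("lif")
  expect_named(liff, "t_ref")
  expect_equal(liff$t_ref$mean, 2)
  izh <- default_param_distributions("izhikevich")
  expect_setequal(names(izh), c("a", "b", "c", "d"))
})

test_that("a point-mass sweep reproduces the default-parameter fit", {
  spec <- list(t_ref = dist_uniform(2, 2))
  sw <- sweep_random_parameters("lif", spec, n_draws = 1, S = 30,
                                duration = 10, seed = 42)
  expect_equal(sw$draws$t_ref, 2)
  # same parameters, independent noise: comparable fit error
  expect_lt(abs(sw$nrmse[1] - sw$default_nrmse),
            3 * max(sw$default_nrmse, 0.01))
})

test_that("randomized LIF parameters keep the default fit unexceptional", {
  sw <- sweep_random_parameters("lif", n_draws = 12, S = 40,
                                duration = 10, seed = 7)
  expect_length(sw$nrmse, 12)
  expect_true(all(sw$nrmse < 0.15))
  band <- quantile(sw$nrmse, c(0.05, 0.95))
  expect_gte(sw$default_nrmse, band[[1]] - 0.02)
  expect_lte(sw$default_nrmse, band[[2]] + 0.02)
})

test_that("fit error converges in the number of sampled rates", {
  cs <- convergence_study(lif_params(), "vary_S", c(5, 20, 100, 400),
                          q = 1, eta = 0.5, ref_S = 400, duration = 40,
                          seed = 31)
  expect_lt(cs$nrmse[1], 0.06)          # already a few percent at S = 5
  expect_lte(cs$nrmse[4], cs$nrmse[1] * 1.5 + 1e-3)
  # plateau: S = 100 within 20% of the densest fit
  expect_lt(abs(cs$nrmse[3] - cs$nrmse[4]), 0.2 * cs$nrmse[4] + 1e-4)
})

test_that("short-duration fits reject counting noise", {
  cs <- convergence_study(lif_params(), "vary_T", c(2, 8, 30), q = 1,
                          eta = 0.5, S = 60, seed = 13)
  # the fitted curve is more accurate than the raw estimates it came from
  expect_lt(cs$nrmse[1], cs$raw_nrmse[1])
  expect_lte(cs$nrmse[3], cs$nrmse[1] * 1.5 + 1e-3)
})

test_that("experiments are reproducible from their seeds", {
  a <- sweep_random_parameters("lif", n_draws = 2, S = 20, duration = 5,
                               seed = 99)
  b <- sweep_random_parameters("lif", n_draws = 2, S = 20, duration = 5,
                               seed = 99)
  expect_identical(a$nrmse, b$nrmse)
  expect_identical(a$draws, b$draws)
})
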