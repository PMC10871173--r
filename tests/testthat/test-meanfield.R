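# synthetic parameter sets shaped like measured LIF fits
p_bistable <- rsp_params(0.011, 2.37, 3.45, 2.1)   # q = 5 mV regime
p_mono <- rsp_params(0.011, 2.6, 2.65, 1.8)        # q = 3 mV, strong noise

test_that("the consistency residual has its stated trivial structure", {
  m0 <- mean_field(p_mono, 0, 10, q = 3)
  F0 <- refractory_softplus(10, p_mono, 3)
  expect_equal(consistency_residual(F0, m0), 0)
  expect_equal(consistency_residual(0, m0), F0)
  expect_gt(consistency_residual(0, mean_field(p_bistable, 55, 0.1, q = 5)), 0)
})

test_that("N = 0 yields exactly one stable point at F(R_bg)", {
  m0 <- mean_field(p_mono, 0, 10, q = 3)
  fp <- fixed_points(m0)
  expect_equal(nrow(fp), 1)
  expect_equal(fp$stability, "stable")
  expect_equal(fp$rate, refractory_softplus(10, p_mono, 3),
               tolerance = 1e-6)
  expect_equal(fp$gain, 0)
})

test_that("root finding agrees with a dense 0.01 Hz scan oracle", {
  models <- list(mean_field(p_bistable, 45, 0.1, q = 5),
                 mean_field(p_bistable, 55, 0.1, q = 5),
                 mean_field(p_bistable, 80, 0.1, q = 5),
                 mean_field(p_mono, 60, 10, q = 3))
  for (m in models) {
    fp <- fixed_points(m)
    oracle <- brute_fixed_points(m)
    expect_equal(nrow(fp), length(oracle))
    expect_true(all(abs(fp$rate - oracle) < 0.01))
    # residual vanishes at every reported fixed point
    expect_true(all(abs(consistency_residual(fp$rate, m)) < 1e-4))
    # stability alternates along increasing rate
    if (nrow(fp) > 1)
      expect_true(all(fp$stability[-1] != head(fp$stability, -1)))
  }
})

test_that("bifurcation scan finds the first bistable in-degree", {
  m <- mean_field(p_bistable, 0, 0.1, q = 5)
  b <- find_bifurcation(m, c(0, 120))
  expect_false(b$monostable)
  # brute-force smallest integer N with multiple fixed points
  counts <- vapply(seq(40, b$n_critical + 2), function(N)
    nrow(fixed_points(mean_field(p_bistable, N, 0.1, q = 5))), numeric(1))
  first <- seq(40, b$n_critical + 2)[which(counts > 1)[1]]
  expect_equal(b$n_critical, first)
  expect_lt(b$n_continuous, b$n_critical + 1e-9)
  expect_gt(b$n_continuous, b$n_critical - 1.5)
  # the half-stable representative lies between the pair born at N_crit
  fpc <- fixed_points(mean_field(p_bistable, b$n_critical, 0.1, q = 5))
  expect_true(b$r_half %in% fpc$rate)

  mono <- find_bifurcation(mean_field(p_mono, 0, 10, q = 3), c(0, 90))
  expect_true(mono$monostable)
})

test_that("critical N decreases weakly with synaptic strength", {
  ncrit <- vapply(c(4, 5, 6), function(q) {
    m <- mean_field(p_bistable, 0, 0.1, q = q)
    find_bifurcation(m, c(0, 250))$n_critical
  }, numeric(1))
  expect_true(all(diff(ncrit) <= 0))
})

test_that("the ReLU-limit tangency matches its closed form", {
  # t_ref = 0, near-infinite beta: F(u) = 1000 a (q sqrt(u) - s0) above
  # threshold, and the tangency system reduces to a quadratic in N with
  # roots N = 6.202, 25.798 for a = 0.01, s0 = 2, q = 5, R_bg = 0.1 --
  # only the larger root lies above the background rate.
  rp <- rsp_params(alpha = 0.01, beta = 500, sigma0 = 2, t_ref = 0)
  b <- find_bifurcation(mean_field(rp, 0, 0.1, q = 5), c(0, 60))
  expect_equal(b$n_continuous, (32 + sqrt(1024 - 640)) / 2, tolerance = 1e-3)
  expect_equal(b$r_tangent, 1.25 * b$n_continuous - 20, tolerance = 1e-2)
})

test_that("rate dynamics relax to fixed points at the linearized speed", {
  m <- mean_field(p_bistable, 55, 0.1, q = 5)
  fp <- fixed_points(m)
  stable_hi <- max(fp$rate[fp$stability == "stable"])
  gain_hi <- fp$gain[fp$rate == stable_hi]
  traj <- integrate_dynamics(m, r0 = stable_hi + 5, horizon = 150,
                             timescale = 2)
  expect_equal(tail(traj$rate_Hz, 1), stable_hi, tolerance = 1e-4)
  # perturbation decays with effective timescale T / (1 - gain)
  dev <- abs(traj$rate_Hz - stable_hi)
  keep <- dev > 1e-3 & traj$t_ms < 20
  slope <- coef(lm(log(dev[keep]) ~ traj$t_ms[keep]))[[2]]
  expect_equal(-1 / slope, 2 / (1 - gain_hi), tolerance = 0.1)

  # starting exactly on the unstable point stays there (within drift)
  r_un <- fp$rate[fp$stability == "unstable"]
  traj_un <- integrate_dynamics(m, r0 = r_un, horizon = 20, timescale = 2)
  expect_lt(abs(tail(traj_un$rate_Hz, 1) - r_un), 0.5)

  expect_error(integrate_dynamics(m, 1, 10, timescale = 1, step = 2),
               "step")
})

test_that("sinusoidal background drive produces an oscillatory response", {
  m <- mean_field(p_mono, 50, 10, q = 3)
  stim <- stimulus("sinusoid", base = 10, amplitude = 5, frequency = 1)
  fp <- fixed_points(m)$rate[1]
  traj <- integrate_dynamics(m, r0 = fp, horizon = 3000, stim = stim,
                             timescale = 1, step = 0.1)
  late <- traj[traj$t_ms > 1000, ]
  # oscillates about the fixed point with period 1000 ms
  expect_gt(diff(range(late$rate_Hz)), 5)
  expect_gt(cor(late$rate_Hz,
                refractory_softplus(late$R_bg_kHz +
                                      m$n_recurrent * late$rate_Hz / 1000,
                                    p_mono, 3)),
            0.99)
})

test_that("recurrent input fractions follow the fixed-point algebra", {
  m0 <- mean_field(p_mono, 0, 10, q = 3)
  expect_equal(recurrent_fraction(m0, 20), 0)
  m <- mean_field(p_mono, 40, 10, q = 3)
  r <- fixed_points(m)$rate[1]
  expect_equal(recurrent_fraction(m, r),
               (40 * r / 1000) / (10 + 40 * r / 1000))
})
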