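test_that("static connectivity has exact in-degree and valid delays", {
  cfg <- network_config(m_total = 100, n_in = 75, q = 1, r_bg = 1,
                        seed = 3)
  w <- build_connectivity(cfg)
  expect_equal(dim(w$presyn), c(75, 100))
  for (i in c(1, 50, 100)) {
    pres <- w$presyn[, i]
    expect_length(unique(pres), 75)
    expect_false(i %in% pres)
    expect_true(all(pres >= 1 & pres <= 100))
  }
  expect_equal(sum(w$offsets[101] ), 100 * 75)
  expect_true(all(w$delay_steps >= w$delay_min_steps &
                    w$delay_steps <= w$delay_max_steps))
  w2 <- build_connectivity(cfg)
  expect_identical(w, w2)            # same seed, same wiring
  expect_error(network_config(m_total = 10, n_in = 10, q = 1, r_bg = 1),
               "n_in")
})

test_that("network simulations are reproducible and respect refractoriness", {
  cfg <- network_config(m_total = 200, n_in = 20, q = 3, r_bg = 10,
                        eta = 0.8, seed = 5)
  a <- simulate_network(cfg, duration = 1)
  b <- simulate_network(cfg, duration = 1)
  expect_identical(a$spikes, b$spikes)
  expect_gt(nrow(a$spikes), 100)
  for (id in unique(a$spikes$neuron_id)[1:20]) {
    isi <- diff(a$spikes$time_ms[a$spikes$neuron_id == id])
    if (length(isi)) expect_true(all(isi >= cfg$neuron$t_ref - 1e-9))
  }
})

test_that("an uncoupled network reproduces single-neuron statistics", {
  cfg <- network_config(m_total = 100, n_in = 0, q = 3, r_bg = 10,
                        eta = 0.8, seed = 6)
  sim <- simulate_network(cfg, duration = 2)
  net_isi <- unlist(lapply(split(sim$spikes$time_ms, sim$spikes$neuron_id),
                           diff))
  # standalone clock-driven neuron at the same input statistics
  s <- balanced_psp_sizes(3, 0.8)
  st <- poisson_streams(10, 0.8, 60e3, seed = 61)
  solo <- simulate_lif(lif_params(), st$exc, st$inh, s[["qe"]], s[["qi"]],
                       60e3, method = "clock")
  ks <- suppressWarnings(ks.test(net_isi, diff(solo$times)))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(sim$trace) - firing_rate(solo)) / firing_rate(solo),
            0.1)
})

test_that("annealed connectivity matches the static mean input rate", {
  base <- list(m_total = 2000, n_in = 60, q = 3, r_bg = 10, eta = 0.8)
  rates <- vapply(c("static_indegree", "annealed_average"), function(conn) {
    cfg <- do.call(network_config, c(base, list(connectivity = conn,
                                                seed = 17)))
    mean(simulate_network(cfg, duration = 1.5)$trace)
  }, numeric(1))
  expect_gt(min(rates), 10)
  expect_lt(abs(diff(rates)) / mean(rates), 0.25)
})

test_that("binned rates have the stated unit arithmetic", {
  expect_equal(as.numeric(binned_rate(numeric(0), 100, 10)), rep(0, 10))
  one_bin <- binned_rate(data.frame(time_ms = rep(2.5, 100)), 100, 10)
  expect_equal(as.numeric(one_bin), c(0, 0, 1000, rep(0, 7)))
  set.seed(4)
  times <- runif(5000, 0, 1000)
  tr <- binned_rate(times, 250, 1000)
  expect_equal(sum(tr) * 250 * 1e-3, 5000)   # spike conservation
})

test_that("OU fits recover synthetic parameters", {
  set.seed(9)
  x <- simulate_ou(2000, mean = 50, sigma = 4, tau = 10)
  ou <- fit_ou(x)
  expect_equal(ou$mean, 50, tolerance = 0.1)
  expect_equal(ou$sigma, 4, tolerance = 0.1)
  # timescale needs more bins for the same precision: the lag-1
  # regression has se(rho) ~ sqrt((1-rho^2)/n), which maps to ~7% on tau
  set.seed(10)
  xl <- simulate_ou(8000, mean = 50, sigma = 4, tau = 20)
  expect_equal(fit_ou(xl)$timescale, 20, tolerance = 0.1)

  set.seed(11)
  white <- rnorm(2000, 30, 3)
  expect_equal(fit_ou(white)$timescale, 1, tolerance = 0.25)

  const <- fit_ou(rep(5, 500))
  expect_equal(const$sigma, 0)
  expect_true(const$degenerate)
  expect_true(is.na(const$timescale))
})

test_that("fluctuation scaling recovers an exact inverse-root law", {
  M <- rep(c(100, 1000, 10000), each = 4)
  df <- data.frame(m_total = M, sigma = 30 * M^(-0.5))
  fs <- fluctuation_scaling(df)
  expect_equal(fs$k, 30, tolerance = 1e-10)
  expect_equal(fs$loglog_slope, -0.5, tolerance = 1e-10)
  expect_error(fluctuation_scaling(data.frame(m_total = c(1, 2),
                                              sigma = c(1, 2))),
               "3 distinct")
})

test_that("warm-up ramps linearly and can be disabled", {
  cfg <- network_config(m_total = 50, n_in = 5, q = 1, r_bg = 2, seed = 1)
  wp <- warmup_protocol(cfg, warmup_time = 1, amplitude = 2)
  expect_equal(warmup_rate(wp, 500), 1)      # half-way, half amplitude
  expect_equal(warmup_rate(wp, 0), 2)
  expect_equal(warmup_rate(wp, 1500), 0)     # after the window
  wp0 <- warmup_protocol(cfg, warmup_time = 1, amplitude = 0)
  expect_equal(warmup_rate(wp0, 300), 0)
})

test_that("practical stability demands a bistable model", {
  cfg <- network_config(m_total = 100, n_in = 10, q = 3, r_bg = 10,
                        eta = 0.8, seed = 2)
  mono <- mean_field(rsp_params(0.011, 2.6, 2.65, 1.8), 10, 10, q = 3)
  expect_error(practical_stability(cfg, mono, n_sims = 1), "unstable")
})
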