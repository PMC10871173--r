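test_that("LIF responds correctly to trivial inputs", {
  p <- lif_params()
  expect_length(simulate_lif(p, numeric(0), numeric(0), 1, 1, 1000)$times, 0)
  # one suprathreshold kick (20 mV > 15 mV threshold distance)
  st <- simulate_lif(p, 5, numeric(0), 20, 1, 100)
  expect_equal(st$times, 5)
  # subthreshold kick does nothing
  expect_length(simulate_lif(p, 5, numeric(0), 10, 1, 100)$times, 0)
  expect_error(simulate_lif(p, c(3, 1), numeric(0), 1, 1, 10), "sorted")
})

test_that("clock-driven LIF converges to the exact event-driven path", {
  p <- lif_params()
  s <- balanced_psp_sizes(1, 0.8)
  st <- poisson_streams(20, 0.8, 20e3, seed = 8)
  ev <- simulate_lif(p, st$exc, st$inh, s[["qe"]], s[["qi"]], 20e3)
  n_coarse <- length(simulate_lif(lif_params(dt = 0.1), st$exc, st$inh,
                                  s[["qe"]], s[["qi"]], 20e3, "clock")$times)
  n_fine <- length(simulate_lif(lif_params(dt = 0.01), st$exc, st$inh,
                                s[["qe"]], s[["qi"]], 20e3, "clock")$times)
  n_ev <- length(ev$times)
  expect_lt(abs(n_fine - n_ev), abs(n_coarse - n_ev))
  expect_lt(abs(n_fine - n_ev) / n_ev, 0.02)
})

test_that("no interspike interval ever violates the refractory period", {
  s <- balanced_psp_sizes(2, 0.8)
  st <- poisson_streams(30, 0.8, 10e3, seed = 12)
  for (method in c("event", "clock")) {
    sp <- simulate_lif(lif_params(t_ref = 3), st$exc, st$inh,
                       s[["qe"]], s[["qi"]], 10e3, method)
    expect_gte(length(sp$times), 10)
    expect_true(all(diff(sp$times) >= 3 - 1e-9))
  }
  hp <- hh_params(t_ref = 4)
  we <- psc_weight(1, hp$c_m, hp$tau_syn_exc)
  wi <- psc_weight(1, hp$c_m, hp$tau_syn_inh)
  st2 <- poisson_streams(60, 0.5, 3e3, seed = 13)
  sp2 <- simulate_hh(hp, st2$exc, st2$inh, we, wi, 3e3)
  expect_gte(length(sp2$times), 5)
  expect_true(all(diff(sp2$times) >= 4 - 1e-9))
})

test_that("LIF at small PSPs matches the diffusion-limit quadrature rate", {
  p <- lif_params()
  s <- balanced_psp_sizes(0.1, 0.5)
  set.seed(1)
  for (D in c(20, 50, 100)) {
    R <- D / 0.1^2
    st <- measure_transfer_curve(p, q = 0.1, eta = 0.5, S = 2, d_max = D,
                                 duration = 20)
    rate <- st$rate_Hz[2]
    se <- sqrt(rate * 20) / 20   # Poisson-scale Monte-Carlo error
    expect_lt(abs(rate - siegert_rate(p, D)), 3 * se + 1e-9)
  }
})

test_that("Izhikevich integrates correctly and reports blow-ups", {
  p <- izhikevich_params()
  expect_length(simulate_izhikevich(p, numeric(0), numeric(0), 0, 0,
                                    2000)$times, 0)
  # constant suprathreshold current: regular spiking, rate increasing in
  # I, agreeing with a fine-step reference integration of the same ODE
  rates <- vapply(c(6, 10, 14), function(I) {
    coarse <- firing_rate(simulate_izhikevich(p, numeric(0), numeric(0),
                                              0, 0, 3000, i_const = I))
    fine <- firing_rate(simulate_izhikevich(izhikevich_params(dt = 0.005),
                                            numeric(0), numeric(0), 0, 0,
                                            3000, i_const = I))
    expect_lt(abs(coarse - fine) / fine, 0.05)
    coarse
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
  expect_error(simulate_izhikevich(p, 1, numeric(0), 1e9, 0, 50),
               "diverged")
})

test_that("Hodgkin-Huxley fires tonically under strong current", {
  p <- hh_params()
  expect_length(simulate_hh(p, numeric(0), numeric(0), 0, 0, 1000)$times, 0)
  st <- simulate_hh(p, numeric(0), numeric(0), 0, 0, 2000, i_const = 2000)
  rate <- firing_rate(st)
  expect_gt(rate, 20)
  expect_lt(rate, 1000 / p$t_ref)
  isi <- diff(st$times)
  expect_lt(sd(isi) / mean(isi), 0.05)  # tonic regularity
})

test_that("transfer curves start at zero, stay monotone, and average noise", {
  cur <- lif_fixture_curve()
  expect_equal(cur$rate_Hz[1], 0)
  expect_gt(max(cur$rate_Hz), 10)   # tens of hertz at the top of the grid
  expect_lt(max(cur$rate_Hz), 150)
  # monotone non-decreasing up to sampling noise: isotonic residual small
  iso <- isoreg(cur$R_kHz, cur$rate_Hz)
  se <- sqrt(pmax(cur$rate_Hz, 1) / attr(cur, "duration"))
  expect_true(all(abs(iso$yf - cur$rate_Hz) <= 3 * se))
})

test_that("doubling the duration shrinks the per-point standard error", {
  p <- lif_params()
  set.seed(21)
  rates <- function(dur) replicate(40, {
    measure_transfer_curve(p, q = 1, eta = 0.5, S = 2, d_max = 50,
                           duration = dur)$rate_Hz[2]
  })
  ratio <- sd(rates(1)) / sd(rates(4))
  # expect about sqrt(4) = 2; 3-sigma band for 40 replicates
  expect_gt(ratio, 1.25)
  expect_lt(ratio, 3.2)
})
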