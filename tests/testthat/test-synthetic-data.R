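test_that("trace simulation is seed-deterministic with additive noise only", {
  p <- if_study_params()
  obs <- observation_model(n_points = 400)
  a <- simulate_trace(p, 1e-6, 1e-6, obs, seed = 42, trace_length = 10)
  b <- simulate_trace(p, 1e-6, 1e-6, obs, seed = 42, trace_length = 10)
  expect_identical(a$signal, b$signal)
  expect_identical(a$times, b$times)

  c2 <- simulate_trace(p, 1e-6, 1e-6, obs, seed = 43, trace_length = 10)
  expect_false(identical(a$signal, c2$signal))
  # the seed only affects the noise: noiseless parts are identical
  obs0 <- observation_model(n_points = 400, noise_sigma = 0)
  base1 <- simulate_trace(p, 1e-6, 1e-6, obs0, seed = 42, trace_length = 10)
  base2 <- simulate_trace(p, 1e-6, 1e-6, obs0, seed = 43, trace_length = 10)
  expect_identical(base1$signal, base2$signal)
  expect_lt(sd(a$signal - base1$signal), 2 * a$provenance$noise_sigma)
})

test_that("noiseless induced-fit traces increase monotonically", {
  obs0 <- observation_model(n_points = 500, noise_sigma = 0)
  tr <- simulate_trace(if_study_params(), 2e-6, 1e-6, obs0, seed = 1,
                       trace_length = 20)
  expect_true(all(diff(tr$signal) > -1e-9 * diff(range(tr$signal))))
  expect_true(all(diff(tr$times) > 0))
  expect_equal(tr$times[1], obs0$dead_time)
})

test_that("a negligible conformational branch gives two-state binding kinetics", {
  # k_e = 0 and k_r ~ 0: single-exponential binding with rate
  # k_plus (L_eq + R_eq) + k_minus
  p <- mechanism_params("IF", 2e6, 1.5, k_e = 0, k_r = 1e-12)
  L0 <- 1e-5; P0 <- 5e-7   # ligand excess keeps the binding step pseudo-linear
  eq <- equilibrium_delta(L0, P0, overall_kd(p))
  rate_true <- p$k_plus * (eq$L_free_eq + (P0 - eq$RL_total_eq)) + p$k_minus
  obs0 <- observation_model(n_points = 1500, noise_sigma = 0)
  tr <- simulate_trace(p, L0, P0, obs0, seed = 1, trace_length = 6 / rate_true)
  f <- fit_exponentials(tr, 1L, fit_start = 1 / rate_true, seed = 2)
  expect_rel_equal(f$rates[1], rate_true, 0.02)
})

test_that("the default experiment reproduces the replicate design", {
  d <- default_design(seed = 7)
  expect_equal(sum(d$conditions$replicates), 55L)
  expect_equal(nrow(d$conditions), 10L)
  expect_equal(sort(d$conditions$L0) * 1e6,
               c(0.5, 0.75, 1, 1.5, 2, 2.5, 3.75, 5, 10, 15),
               tolerance = 1e-12)
  expect_true(all(d$conditions$trace_length[d$conditions$L0 >= 5e-6] == 5))

  obs <- observation_model(n_points = 30)
  traces <- simulate_experiment(if_study_params(),
                                experiment_design(c(1e-6, 2e-6), c(2, 1),
                                                  5, seed = 3), obs)
  expect_length(traces, 3L)
  # singleton design
  single <- simulate_experiment(if_study_params(),
                                experiment_design(1e-6, 1, 5, seed = 3), obs)
  expect_length(single, 1L)
})

test_that("rate datasets reduce to the closed forms at zero noise", {
  p <- if_study_params()
  ds <- simulate_rate_dataset(p, default_design(), rate_noise = 0, seed = 1)
  expect_s3_class(ds, "rate_dataset")
  expect_equal(nrow(ds), 10L)
  for (i in seq_len(nrow(ds))) {
    r <- relaxation_rates(p, ds$L0[i], 1e-6)
    expect_equal(ds$k1[i], r$k1, tolerance = 1e-12)
    if (!is.na(ds$k2[i])) expect_equal(ds$k2[i], r$k2, tolerance = 1e-12)
  }
  # high-concentration rows carry no slow rate
  expect_true(all(is.na(ds$k2[ds$L0 >= 5e-6 * (1 - 1e-9)])))
  expect_true(all(!is.na(ds$k2[ds$L0 < 5e-6 * (1 - 1e-9)])))
  expect_false(is.unsorted(ds$L0))

  empty <- simulate_rate_dataset(p, experiment_design(numeric(0), integer(0),
                                                      numeric(0), seed = 1))
  expect_equal(nrow(empty), 0L)
})

test_that("saturation-transfer curves follow the exchange closed form", {
  # no exchange: on-resonance stays at the unsaturated intensity
  cv <- simulate_std_curve(0, 1, I0 = 2, noise_sigma = 0, seed = 1)
  expect_equal(cv$on_intensity, rep(2, 10), tolerance = 1e-12)

  # long-time plateau R_S / (k_SI + R_S)
  cv <- simulate_std_curve(3, 1, I0 = 1, sat_times = c(0.1, 1, 10, 50),
                           noise_sigma = 0, seed = 1)
  expect_equal(cv$on_intensity[4], 0.25, tolerance = 1e-9)

  # the ODE mode integrates to the closed form
  ts <- seq(0.05, 1, length.out = 10)
  a <- simulate_std_curve(1.23, 2, 1, ts, noise_sigma = 0, seed = 1)
  b <- simulate_std_curve(1.23, 2, 1, ts, noise_sigma = 0, seed = 1,
                          mode = "ode")
  expect_lt(max(abs(a$on_intensity - b$on_intensity)), 1e-9)

  # determinism
  x <- simulate_std_curve(1, 1, 1, noise_sigma = 0.02, seed = 9)
  y <- simulate_std_curve(1, 1, 1, noise_sigma = 0.02, seed = 9)
  expect_identical(x$on_intensity, y$on_intensity)
  expect_identical(x$off_intensity, y$off_intensity)
})

test_that("trace-level fits recover well-separated rates within 5 percent", {
  # round trip at low noise (1% of dynamic range), moderate problem size
  p <- mechanism_params("IF", 2e5, 3, k_e = 0.5, k_r = 1.5)
  rr <- relaxation_rates(p, 2e-5, 5e-7)
  expect_gt(rr$k1 / rr$k2, 3)
  obs <- observation_model(n_points = 1000, noise_sigma = NA)
  errs <- t(vapply(1:12, function(i) {
    tr <- simulate_trace(p, 2e-5, 5e-7, obs, seed = 100 + i,
                         trace_length = 6 / rr$k2)
    f <- fit_exponentials(tr, 2L, fit_start = 1 / rr$k1, seed = i,
                          control = list(n_pop = 25L, n_gen = 80L))
    c(abs(f$rates[1] - rr$k1) / rr$k1, abs(f$rates[2] - rr$k2) / rr$k2)
  }, numeric(2)))
  expect_lt(median(errs[, 1]), 0.05)
  expect_lt(median(errs[, 2]), 0.05)
})
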