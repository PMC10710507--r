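make_biexp_trace <- function(baseline, a1, a2, r1, r2, sigma = 0, seed = 1,
                             n = 800, t_max = 20) {
  t <- seq(0.0015, t_max, length.out = n)
  y <- baseline + a1 * exp(-r1 * t) + a2 * exp(-r2 * t)
  if (sigma > 0) y <- y + withr::with_seed(seed, rnorm(n, 0, sigma))
  list(times = t, signal = y, L0 = 1e-6, P0 = 1e-6)
}

test_that("noiseless double exponentials are recovered to a tenth of a percent", {
  tr <- make_biexp_trace(1.2, -0.25, -0.4, 1.1253, 0.71892)
  f <- fit_exponentials(tr, 2L, seed = 4)
  expect_true(f$converged)
  expect_rel_equal(f$rates[1], 1.1253, 1e-3)
  expect_rel_equal(f$rates[2], 0.71892, 1e-3)
  expect_rel_equal(f$baseline, 1.2, 1e-3)
  expect_true(all(diff(f$rates) <= 0))
})

test_that("model selection prefers the parsimonious truth", {
  # double-exponential truth, rate ratio 3, 1% noise: chooses 2
  tr2 <- make_biexp_trace(1, -0.3, -0.3, 1.5, 0.5, sigma = 0.006, seed = 21)
  sel2 <- compare_exponential_models(tr2, seed = 5,
                                     control = list(n_pop = 25L, n_gen = 80L))
  expect_equal(sel2$chosen, 2L)
  expect_gt(sel2$delta_aic, 0)
  expect_true(sel2$reliable)

  # single-exponential truth fitted with two components: AIC prefers one
  tr1 <- make_biexp_trace(1, -0.5, 0, 0.8, 0.1, sigma = 0.004, seed = 22)
  sel1 <- compare_exponential_models(tr1, seed = 5,
                                     control = list(n_pop = 25L, n_gen = 80L))
  expect_equal(sel1$chosen, 1L)

  # pure noise around a constant: majority of seeds choose 1
  chosen <- vapply(1:9, function(i) {
    trn <- make_biexp_trace(1, 0, 0, 1, 0.1, sigma = 0.01, seed = 30 + i,
                            n = 300)
    compare_exponential_models(trn, seed = i,
                               control = list(n_pop = 20L, n_gen = 50L))$chosen
  }, integer(1))
  expect_gt(sum(chosen == 1L), 4)

  # the tie rule is parsimony: chosen follows strictly-lower AIC only
  expect_equal(sel1$chosen,
               if (sel1$fit2$aic < sel1$fit1$aic) 2L else 1L)
})

test_that("AIC bookkeeping is consistent with least squares", {
  tr <- make_biexp_trace(1, -0.3, -0.2, 2, 0.4, sigma = 0.005, seed = 3)
  f1 <- fit_exponentials(tr, 1L, seed = 6)
  f2 <- fit_exponentials(tr, 2L, seed = 6)
  # adding a component never increases the residual sum of squares
  expect_lte(f2$rss, f1$rss * (1 + 1e-10))
  # AIC follows n log(RSS/n) + 2 (p+1)
  expect_equal(f1$aic, f1$n_points * log(f1$rss / f1$n_points) + 2 * 4)
  expect_equal(f2$aic, f2$n_points * log(f2$rss / f2$n_points) + 2 * 6)
})

test_that("fits are invariant to affine rescaling of the signal", {
  tr <- make_biexp_trace(1, -0.3, -0.2, 2, 0.4, sigma = 0.004, seed = 8)
  f <- fit_exponentials(tr, 2L, seed = 9)
  tr_scaled <- tr
  tr_scaled$signal <- 5 + 40 * tr$signal
  g <- fit_exponentials(tr_scaled, 2L, seed = 9)
  expect_equal(g$rates, f$rates, tolerance = 1e-3)
  expect_equal(g$amplitudes, 40 * f$amplitudes, tolerance = 1e-2)
  expect_equal(g$baseline, 5 + 40 * f$baseline, tolerance = 1e-2)
})

test_that("replicate aggregation applies the error and window rules", {
  # identical replicate fits collapse to zero-width intervals
  fits <- data.frame(trace_id = rep(1:3, each = 3),
                     L0 = 1e-6, window = rep(c(5, 10, 20), 3),
                     n_components = 2L, k1 = 2, k2 = 0.5, converged = TRUE)
  ds <- aggregate_rates(fits)
  expect_equal(ds$k1_ci95, 0)
  expect_equal(ds$k2_ci95, 0)
  expect_equal(ds$n_traces, 3L)

  # high-concentration rows: single-exponential fits, no slow rate
  fits_hi <- rbind(fits,
                   data.frame(trace_id = 4:6, L0 = 1e-5, window = 0.5,
                              n_components = 1L, k1 = c(9, 10, 11),
                              k2 = NA_real_, converged = TRUE))
  ds_hi <- aggregate_rates(fits_hi)
  expect_equal(nrow(ds_hi), 2L)
  expect_true(is.na(ds_hi$k2[ds_hi$L0 == 1e-5]))
  expect_equal(ds_hi$k1[ds_hi$L0 == 1e-5], 10)
  expect_rel_equal(ds_hi$k1_ci95[ds_hi$L0 == 1e-5],
                   1.96 * sd(c(9, 10, 11)) / sqrt(3), 1e-9)

  # slow-rate error comes from the window spread
  fits_w <- fits
  fits_w$k2 <- rep(c(0.48, 0.5, 0.52), 3)  # varies by window, not trace
  ds_w <- aggregate_rates(fits_w)
  expect_rel_equal(ds_w$k2_ci95, 1.96 * sd(c(0.48, 0.5, 0.52)), 1e-9)

  # a single trace cannot give a confidence interval
  expect_warning(aggregate_rates(fits[fits$trace_id == 1, ]), "single trace")
})

test_that("experiment-level fits bracket the generating rates", {
  p <- if_study_params()
  # concentrations where the slow rate completes several relaxation times
  # within the 10-s analysis window (k2 ~ 0.5-0.8 /s here)
  design <- experiment_design(L0 = c(2e-6, 2.5e-6, 3.75e-6), replicates = 3,
                              trace_length = 20, P0 = 1e-6, seed = 17)
  obs <- observation_model(n_points = 700)
  traces <- simulate_experiment(p, design, obs)
  fits <- fit_experiment(traces, windows = c(5, 10, 20), seed = 23,
                         control = list(n_pop = 20L, n_gen = 60L))
  ds <- aggregate_rates(fits)
  expect_equal(nrow(ds), 3L)
  expect_true(all(ds$k1 > ds$k2, na.rm = TRUE))
  expect_true(all(ds$k1_ci95 >= 0))
  truth1 <- vapply(ds$L0, function(L) relaxation_rates(p, L, 1e-6)$k1,
                   numeric(1))
  truth2 <- vapply(ds$L0, function(L) relaxation_rates(p, L, 1e-6)$k2,
                   numeric(1))
  # full-trace fits at these depletion conditions carry the settling
  # transient, which biases the fast rate upward; the slow rate is tight
  expect_true(all(abs(ds$k1 - truth1) / truth1 < 0.5))
  expect_true(all(abs(ds$k2 - truth2) / truth2 < 0.1))
  # concentration ordering of the fast rate survives the bias
  expect_false(is.unsorted(ds$k1))
})
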