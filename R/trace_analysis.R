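#' Seeded differential-evolution minimiser
#'
#' Compact rand/1/bin differential evolution over box constraints, used as
#' the global stage of the exponential trace fits. Deterministic given the
#' seed. A list of candidate starting points can be injected into the
#' initial population.
#'
#' @param fn Objective taking a numeric vector, returning a scalar.
#' @param lower,upper Box constraints.
#' @param seed Integer seed.
#' @param n_pop Population size.
#' @param n_gen Number of generations.
#' @param f_weight Differential weight.
#' @param cr Crossover probability.
#' @param init Optional list of numeric vectors seeded into the population.
#' @return List with `par` and `value`.
#' @keywords internal
de_optim <- function(fn, lower, upper, seed = 1L, n_pop = 40L, n_gen = 150L,
                     f_weight = 0.8, cr = 0.9, init = list()) {
  d <- length(lower)
  withr::with_seed(seed, {
    pop <- matrix(stats::runif(n_pop * d, lower, upper),
                  nrow = n_pop, ncol = d, byrow = TRUE)
    for (i in seq_along(init)) {
      if (i <= n_pop) pop[i, ] <- pmin(pmax(init[[i]], lower), upper)
    }
    val <- apply(pop, 1, fn)
    for (g in seq_len(n_gen)) {
      idx <- vapply(seq_len(n_pop), function(i) {
        sample(setdiff(seq_len(n_pop), i), 3L)
      }, integer(3))
      mut <- pop[idx[1, ], ] + f_weight * (pop[idx[2, ], ] - pop[idx[3, ], ])
      cross <- matrix(stats::runif(n_pop * d) < cr, n_pop, d)
      jrand <- cbind(seq_len(n_pop), sample.int(d, n_pop, replace = TRUE))
      cross[jrand] <- TRUE
      trial <- ifelse(cross, mut, pop)
      trial <- pmin(pmax(trial, matrix(lower, n_pop, d, byrow = TRUE)),
                    matrix(upper, n_pop, d, byrow = TRUE))
      tval <- apply(trial, 1, fn)
      better <- tval < val
      pop[better, ] <- trial[better, , drop = FALSE]
      val[better] <- tval[better]
    }
    best <- which.min(val)
    list(par = pop[best, ], value = val[best])
  })
}

exp_model_eval <- function(theta, t, n_components) {
  baseline <- theta[1]
  amps <- theta[1 + seq_len(n_components)]
  rates <- exp(theta[1 + n_components + seq_len(n_components)])
  y <- rep(baseline, length(t))
  for (i in seq_len(n_components)) y <- y + amps[i] * exp(-rates[i] * t)
  y
}

# Rough exponential start: baseline from the trace tail, overall rate from
# the time to cover 2/3 of the signal change.
heuristic_exp_start <- function(t, y, n_components) {
  baseline <- mean(utils::tail(y, max(3L, length(y) %/% 20L)))
  a0 <- y[1] - baseline
  span <- max(t) - min(t)
  frac <- abs(y - baseline) <= abs(a0) / 3
  t63 <- if (any(frac)) t[which(frac)[1]] - min(t) else span / 3
  r <- 1 / max(t63, span / 1e3)
  if (n_components == 1) {
    c(baseline, a0, log(r))
  } else {
    c(baseline, a0 / 2, a0 / 2, log(min(r * 3, 1e3)), log(max(r / 3, 1e-3)))
  }
}

# Exponential-peeling start for two components: log-linear regression of
# the tail residual gives the slow mode; peeling it off and regressing the
# early residual gives the fast mode. Clean traces give near-exact starts.
peeling_exp_start <- function(t, y) {
  n <- length(y)
  baseline <- mean(utils::tail(y, max(3L, n %/% 20L)))
  slow_idx <- seq(from = n %/% 3L, to = max(n %/% 3L + 2L, n - n %/% 10L))
  res <- y[slow_idx] - baseline
  sgn <- sign(stats::median(res))
  ok <- sgn * res > 0
  if (sum(ok) < 5) return(NULL)
  fit_s <- stats::lm.fit(cbind(1, t[slow_idx][ok]), log(sgn * res[ok]))
  r_slow <- -fit_s$coefficients[2]
  a_slow <- sgn * exp(fit_s$coefficients[1])
  if (!is.finite(r_slow) || r_slow <= 0) return(NULL)
  fast_idx <- seq_len(max(10L, n %/% 5L))
  res_f <- y[fast_idx] - baseline - a_slow * exp(-r_slow * t[fast_idx])
  sgn_f <- sign(stats::median(res_f))
  ok_f <- sgn_f * res_f > 0
  if (sum(ok_f) < 5) return(NULL)
  fit_f <- stats::lm.fit(cbind(1, t[fast_idx][ok_f]), log(sgn_f * res_f[ok_f]))
  r_fast <- -fit_f$coefficients[2]
  a_fast <- sgn_f * exp(fit_f$coefficients[1])
  if (!is.finite(r_fast) || r_fast <= 0) return(NULL)
  cl <- function(r) log(min(max(r, 1.0001e-3), 0.9999e3))
  unname(c(baseline, a_fast, a_slow, cl(r_fast), cl(r_slow)))
}

#' Fit a sum of exponentials to a stopped-flow trace
#'
#' Minimises the residual sum of squares of
#' `signal ~ baseline + sum_i amplitude_i * exp(-rate_i * t)` over the fit
#' window using a seeded differential-evolution global search followed by
#' Levenberg-Marquardt polishing. Rates are bounded in \[1e-3, 1e3\] /s and
#' baseline/amplitudes within 3 signal ranges of the data, so the fit is
#' invariant to affine rescaling of the signal. AIC uses the least-squares
#' convention `n log(RSS/n) + 2 (p + 1)` with the residual variance counted
#' as a parameter; only within-dataset orderings and differences of AIC are
#' meaningful.
#'
#' @param trace A `stopped_flow_trace` (or any list with `times`, `signal`).
#' @param n_components 1 or 2.
#' @param fit_window Upper time limit (s, from mixing) of data used; `NULL`
#'   for the whole trace.
#' @param fit_start Lower time limit (s); points before it are dropped.
#'   Useful for restricting the fit to the final relaxation, which is what
#'   the near-equilibrium rate expressions describe.
#' @param seed Integer seed for the global search.
#' @param control List overriding differential-evolution settings
#'   (`n_pop`, `n_gen`).
#' @return An `exponential_fit` list: `n_components`, `baseline`,
#'   `amplitudes`, `rates` (sorted descending), `rss`, `n_points`, `aic`,
#'   `fit_window`, `converged`, `warnings`.
#' @export
fit_exponentials <- function(trace, n_components = 2L, fit_window = NULL,
                             fit_start = 0, seed = 1L, control = list()) {
  stopifnot(n_components %in% c(1L, 2L))
  t <- trace$times
  y <- trace$signal
  keep <- t >= fit_start & (if (is.null(fit_window)) TRUE else t <= fit_window)
  t <- t[keep]; y <- y[keep]
  p <- 2L * n_components + 1L
  if (length(t) < 10L * p) {
    stop("need at least ", 10L * p, " points inside the fit window; have ",
         length(t))
  }
  rng <- diff(range(y))
  if (rng == 0) rng <- max(abs(y), 1)
  lower <- c(min(y) - 3 * rng, rep(-3 * rng, n_components),
             rep(log(1e-3), n_components))
  upper <- c(max(y) + 3 * rng, rep(3 * rng, n_components),
             rep(log(1e3), n_components))
  obj <- function(theta) {
    r <- y - exp_model_eval(theta, t, n_components)
    sum(r * r)
  }
  inits <- list(heuristic_exp_start(t, y, n_components))
  if (n_components == 2L) {
    peel <- peeling_exp_start(t, y)
    if (!is.null(peel)) inits <- c(inits, list(peel))
  }
  ctl <- utils::modifyList(list(n_pop = 40L, n_gen = 150L), control)
  de <- de_optim(obj, lower, upper, seed = seed,
                 n_pop = ctl$n_pop, n_gen = ctl$n_gen, init = inits)
  theta <- de$par
  rss <- de$value
  converged <- TRUE
  polish_from <- function(start) {
    tryCatch({
      st <- as.list(stats::setNames(pmin(pmax(start, lower), upper),
                                    paste0("th", seq_along(start))))
      form <- stats::as.formula(paste(
        "y ~ exp_model_eval(c(", paste(names(st), collapse = ","),
        "), t, ", n_components, ")"))
      fit <- minpack.lm::nlsLM(form, data = list(y = y, t = t), start = st,
                               lower = lower, upper = upper,
                               control = minpack.lm::nls.lm.control(maxiter = 200))
      list(par = stats::coef(fit), rss = sum(stats::resid(fit)^2))
    }, error = function(e) NULL)
  }
  polishes <- Filter(function(p) !is.null(p) && is.finite(p$rss),
                     lapply(c(list(theta), inits), polish_from))
  if (length(polishes)) {
    bestp <- polishes[[which.min(vapply(polishes, `[[`, numeric(1), "rss"))]]
    if (bestp$rss <= rss) {
      theta <- as.numeric(bestp$par)
      rss <- bestp$rss
    }
  } else {
    converged <- is.finite(rss)
  }
  amps <- theta[1 + seq_len(n_components)]
  rates <- exp(theta[1 + n_components + seq_len(n_components)])
  ord <- order(rates, decreasing = TRUE)
  rates <- rates[ord]; amps <- amps[ord]
  warnings <- character(0)
  if (n_components == 2L && rates[1] / rates[2] < 1.05) {
    warnings <- c(warnings, "degenerate rates: ratio of fitted rates < 1.05")
  }
  n <- length(y)
  aic <- n * log(rss / n) + 2 * (p + 1)
  structure(list(n_components = n_components, baseline = theta[1],
                 amplitudes = amps, rates = rates, rss = rss, n_points = n,
                 aic = aic,
                 fit_window = if (is.null(fit_window)) max(t) else fit_window,
                 converged = converged, warnings = warnings),
            class = "exponential_fit")
}

#' Select between single- and double-exponential trace models by AIC
#'
#' Runs both fits and chooses the model with the lower AIC; exact ties
#' resolve to the single exponential (parsimony).
#'
#' @inheritParams fit_exponentials
#' @return List: `chosen` (1 or 2), `delta_aic` = AIC(single) - AIC(double)
#'   (positive favours the double exponential), `fit1`, `fit2`, `reliable`
#'   (both fits converged).
#' @export
compare_exponential_models <- function(trace, fit_window = NULL, seed = 1L,
                                       control = list()) {
  fit1 <- fit_exponentials(trace, 1L, fit_window = fit_window, seed = seed,
                           control = control)
  fit2 <- fit_exponentials(trace, 2L, fit_window = fit_window, seed = seed,
                           control = control)
  chosen <- if (fit2$aic < fit1$aic) 2L else 1L
  list(chosen = chosen, delta_aic = fit1$aic - fit2$aic,
       fit1 = fit1, fit2 = fit2,
       reliable = fit1$converged && fit2$converged)
}

#' Fit every trace of an experiment across the analysis windows
#'
#' Below the high-concentration threshold each trace is fitted
#' double-exponentially in each window of `windows`; at or above it a
#' single-exponential fit in `short_window` determines the fast rate only
#' (the slow rate cannot be measured reliably there). Per-trace fit seeds
#' derive deterministically from `seed`.
#'
#' @param traces List of `stopped_flow_trace` objects.
#' @param windows Double-exponential fit windows (s).
#' @param short_window Single-exponential window (s) for high
#'   concentrations.
#' @param high_conc_threshold Ligand concentration (molar) at and above
#'   which the single-exponential rule applies.
#' @param seed Integer seed.
#' @param control Passed to [fit_exponentials()].
#' @return Data frame with one row per (trace, window): `trace_id`, `L0`,
#'   `window`, `n_components`, `k1`, `k2`, `converged`.
#' @export
fit_experiment <- function(traces, windows = c(5, 10, 20), short_window = 0.5,
                           high_conc_threshold = 5e-6, seed = 1L,
                           control = list()) {
  seeds <- withr::with_seed(seed,
                            sample.int(.Machine$integer.max, length(traces)))
  rows <- list()
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    if (tr$L0 >= high_conc_threshold * (1 - 1e-9)) {
      f <- fit_exponentials(tr, 1L, fit_window = short_window,
                            fit_start = 0, seed = seeds[i], control = control)
      rows[[length(rows) + 1L]] <-
        data.frame(trace_id = i, L0 = tr$L0, window = short_window,
                   n_components = 1L, k1 = f$rates[1], k2 = NA_real_,
                   converged = f$converged)
    } else {
      use <- windows[windows <= max(tr$times) * 1.001]
      for (w in use) {
        f <- fit_exponentials(tr, 2L, fit_window = w, seed = seeds[i],
                              control = control)
        rows[[length(rows) + 1L]] <-
          data.frame(trace_id = i, L0 = tr$L0, window = w,
                     n_components = 2L, k1 = f$rates[1], k2 = f$rates[2],
                     converged = f$converged)
      }
    }
  }
  do.call(rbind, rows)
}

#' Aggregate replicate exponential fits into a rate dataset
#'
#' Applies the replicate-averaging and error rules of the trace analysis:
#' the fast rate is the mean of per-trace values in the `k1_window` fit
#' (95% interval 1.96 x standard error over traces); the slow rate is the
#' mean of per-trace values in the same window, with its 95% interval taken
#' as 1.96 x the standard deviation of the per-window trace averages over
#' `k2_windows`, because window choice dominates replicate scatter for the
#' slow rate. Rows whose fits are single-exponential (high-concentration
#' rule) report the fast rate only, averaged over the short-window fits.
#'
#' @param fits Data frame from [fit_experiment()].
#' @param k1_window Window (s) whose fits define both mean rates.
#' @param k2_windows Windows (s) whose averages define the slow-rate error.
#' @return A `rate_dataset` data.frame (columns `L0`, `k1`, `k1_ci95`,
#'   `k2`, `k2_ci95`, `n_traces`), sorted by `L0`.
#' @export
aggregate_rates <- function(fits, k1_window = 10, k2_windows = c(5, 10, 20)) {
  stopifnot(nrow(fits) >= 1)
  out <- lapply(split(fits, fits$L0), function(g) {
    single <- all(g$n_components == 1L)
    if (single) {
      n <- nrow(g)
      if (n == 1L) warning("single trace at L0 = ", g$L0[1] * 1e6,
                           " uM: no confidence interval")
      data.frame(L0 = g$L0[1], k1 = mean(g$k1),
                 k1_ci95 = if (n > 1) 1.96 * stats::sd(g$k1) / sqrt(n) else NA_real_,
                 k2 = NA_real_, k2_ci95 = NA_real_, n_traces = n)
    } else {
      avail <- intersect(k2_windows, unique(g$window))
      w1 <- if (k1_window %in% avail) k1_window else max(avail)
      gk <- g[g$window == w1, ]
      n <- nrow(gk)
      if (n == 1L) warning("single trace at L0 = ", g$L0[1] * 1e6,
                           " uM: no confidence interval")
      window_means <- vapply(avail, function(w) mean(g$k2[g$window == w]),
                             numeric(1))
      data.frame(L0 = g$L0[1], k1 = mean(gk$k1),
                 k1_ci95 = if (n > 1) 1.96 * stats::sd(gk$k1) / sqrt(n) else NA_real_,
                 k2 = mean(gk$k2),
                 k2_ci95 = if (length(window_means) > 1)
                   1.96 * stats::sd(window_means) else NA_real_,
                 n_traces = n)
    }
  })
  ds <- do.call(rbind, out)
  ds <- ds[order(ds$L0), , drop = FALSE]
  rownames(ds) <- NULL
  class(ds) <- c("rate_dataset", "data.frame")
  ds
}
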