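#' Observation model for simulated stopped-flow traces
#'
#' Describes how species concentrations map to the recorded fluorescence
#' signal and how the instrument samples and corrupts it. The signal at
#' time t is `background + sum(coefficient_s * [s](t))` with per-species
#' coefficients expressed per micromolar of species, plus i.i.d. additive
#' Gaussian noise. Bound-species coefficients exceed unbound ones by
#' default, reflecting the increase in intrinsic Trp fluorescence of the
#' receptor on ligand binding; the ligand itself is dark.
#'
#' @param background Signal offset (arbitrary fluorescence units).
#' @param coef_unbound Signal per micromolar of unbound receptor species.
#' @param coef_bound Signal per micromolar of bound receptor species.
#' @param coef_ligand Signal per micromolar of free ligand (default dark).
#' @param noise_sigma Additive Gaussian noise s.d. in signal units, or `NA`
#'   (default) for 0.5% of the noiseless dynamic range of each trace.
#' @param dead_time Unobserved interval after mixing (s).
#' @param n_points Number of samples spanning a trace.
#' @param sample_interval Time between samples (s), or `NA` to derive it
#'   from `n_points` and the trace length.
#' @return An object of class `observation_model`.
#' @export
observation_model <- function(background = 0, coef_unbound = 1.0,
                              coef_bound = 1.3, coef_ligand = 0,
                              noise_sigma = NA, dead_time = 1.5e-3,
                              n_points = 2000, sample_interval = NA) {
  stopifnot(dead_time >= 0, n_points >= 2,
            is.na(noise_sigma) || noise_sigma >= 0,
            is.na(sample_interval) || sample_interval > 0)
  structure(list(background = background, coef_unbound = coef_unbound,
                 coef_bound = coef_bound, coef_ligand = coef_ligand,
                 noise_sigma = noise_sigma, dead_time = dead_time,
                 n_points = n_points, sample_interval = sample_interval),
            class = "observation_model")
}

species_coefficients <- function(model, obs) {
  if (model == "IF") {
    c(R1 = obs$coef_unbound, L = obs$coef_ligand,
      R1L = obs$coef_bound, R2L = obs$coef_bound)
  } else {
    c(R1 = obs$coef_unbound, R2 = obs$coef_unbound,
      L = obs$coef_ligand, R2L = obs$coef_bound)
  }
}

# Initial state right after mixing: unbound receptor at its apo
# conformational equilibrium, all ligand free, no complex. For IF the apo
# receptor has a single conformation R1; for CS the unbound pool is
# pre-equilibrated R1:R2 = k_r:k_e.
initial_state <- function(params, L0, P0) {
  if (params$model == "IF") {
    c(R1 = P0, L = L0, R1L = 0, R2L = 0)
  } else {
    ker <- params$k_e + params$k_r
    c(R1 = P0 * params$k_r / ker, R2 = P0 * params$k_e / ker,
      L = L0, R2L = 0)
  }
}

#' Simulate a stopped-flow fluorescence trace
#'
#' Integrates the mass-action rate equations of the scheme from the
#' post-mixing initial state (unbound receptor in its apo conformational
#' equilibrium, all ligand free), converts concentrations to a fluorescence
#' signal via the observation model, and adds seeded Gaussian noise.
#' Sampling starts at the instrument dead time.
#'
#' @param params A [mechanism_params()] object.
#' @param L0,P0 Total ligand / receptor concentration after mixing (molar).
#' @param obs An [observation_model()].
#' @param seed Integer seed; traces are reproducible bit-for-bit given it.
#' @param trace_length Total recorded time (s).
#' @return An object of class `stopped_flow_trace`: list with `times`,
#'   `signal`, `L0`, `P0` and a `provenance` list (model, true parameters,
#'   seed, realised noise s.d.).
#' @export
simulate_trace <- function(params, L0, P0, obs = observation_model(),
                           seed = 1L, trace_length = 20) {
  stopifnot(inherits(params, "mechanism_params"),
            inherits(obs, "observation_model"),
            trace_length > obs$dead_time)
  dt <- if (is.na(obs$sample_interval)) {
    (trace_length - obs$dead_time) / (obs$n_points - 1)
  } else obs$sample_interval
  sample_times <- seq(obs$dead_time, trace_length, by = dt)
  ode_times <- if (sample_times[1] > 0) c(0, sample_times) else sample_times
  y0 <- initial_state(params, L0, P0)
  sol <- deSolve::ode(
    y = y0, times = ode_times,
    func = function(t, y, p) list(mass_action_derivatives(y, p)),
    parms = params, rtol = 1e-9, atol = 1e-15 * max(P0, L0, 1e-9))
  if (attr(sol, "istate")[1] < 0) {
    stop(sprintf("ODE integration failed for %s scheme at L0 = %g M (reached t = %g s)",
                 params$model, L0, max(sol[, "time"])))
  }
  sol <- sol[sol[, "time"] %in% sample_times, , drop = FALSE]
  coefs <- species_coefficients(params$model, obs)
  conc_uM <- sol[, names(coefs), drop = FALSE] * 1e6
  noiseless <- obs$background + as.numeric(conc_uM %*% coefs)
  sigma <- if (is.na(obs$noise_sigma)) {
    0.005 * diff(range(noiseless))
  } else obs$noise_sigma
  noise <- if (sigma > 0) {
    withr::with_seed(seed, stats::rnorm(length(noiseless), 0, sigma))
  } else rep(0, length(noiseless))
  structure(list(times = sol[, "time"], signal = noiseless + noise,
                 L0 = L0, P0 = P0,
                 provenance = list(model = params$model, params = params,
                                   seed = seed, noise_sigma = sigma)),
            class = "stopped_flow_trace")
}

#' Replicate/concentration design of a stopped-flow experiment
#'
#' @param L0 Total ligand concentrations after mixing (molar), distinct.
#' @param replicates Trace count per concentration (>= 1).
#' @param trace_length Recorded length per concentration (s).
#' @param P0 Total receptor concentration after mixing (molar).
#' @param seed Integer master seed; per-trace seeds are derived from it.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(L0, replicates, trace_length, P0 = 1e-6,
                              seed = 1L) {
  if (length(replicates) == 1L) replicates <- rep(replicates, length(L0))
  stopifnot(length(L0) == length(replicates),
            length(trace_length) %in% c(1L, length(L0)),
            all(replicates >= 1), anyDuplicated(L0) == 0, P0 > 0)
  structure(list(conditions = data.frame(L0 = L0,
                                         replicates = as.integer(replicates),
                                         trace_length = trace_length),
                 P0 = P0, seed = as.integer(seed)),
            class = "experiment_design")
}

#' Default stopped-flow design: ten ligand concentrations, 55 traces
#'
#' The replicate/concentration table of the study this package models:
#' 12 traces at 0.5 uM ligand; 6 at 0.75, 2 and 3.75 uM; 5 at 1 and 2.5 uM;
#' 4 at 1.5, 10 and 15 uM; 3 at 5 uM, with 20-s traces below 5 uM and
#' shorter 5-s traces at 5 uM and above, at 1 uM receptor after mixing.
#'
#' @inheritParams experiment_design
#' @return An [experiment_design()].
#' @export
default_design <- function(P0 = 1e-6, seed = 1L) {
  L0_uM <- c(0.5, 0.75, 1, 1.5, 2, 2.5, 3.75, 5, 10, 15)
  reps <- c(12, 6, 5, 4, 6, 5, 6, 3, 4, 4)
  len <- ifelse(L0_uM >= 5, 5, 20)
  experiment_design(L0 = L0_uM * 1e-6, replicates = reps,
                    trace_length = len, P0 = P0, seed = seed)
}

#' Simulate a full stopped-flow experiment
#'
#' One [simulate_trace()] per replicate of each design condition, with
#' per-trace seeds drawn deterministically from the design seed.
#'
#' @param params A [mechanism_params()] object.
#' @param design An [experiment_design()]; defaults to [default_design()].
#' @param obs An [observation_model()].
#' @return List of `stopped_flow_trace` objects.
#' @export
simulate_experiment <- function(params, design = default_design(),
                                obs = observation_model()) {
  stopifnot(inherits(design, "experiment_design"))
  cond <- design$conditions
  n_tot <- sum(cond$replicates)
  seeds <- withr::with_seed(design$seed,
                            sample.int(.Machine$integer.max, n_tot))
  out <- vector("list", n_tot)
  k <- 0L
  for (i in seq_len(nrow(cond))) {
    for (j in seq_len(cond$replicates[i])) {
      k <- k + 1L
      out[[k]] <- simulate_trace(params, L0 = cond$L0[i], P0 = design$P0,
                                 obs = obs, seed = seeds[k],
                                 trace_length = cond$trace_length[i])
    }
  }
  out
}

#' Simulate a rate dataset directly from the closed-form rates
#'
#' Fast path for Monte-Carlo studies of mechanism inference: bypasses the
#' trace level by perturbing the closed-form relaxation rates with relative
#' Gaussian noise per replicate and aggregating replicates exactly as the
#' trace pipeline would (mean and 1.96 x standard-error 95% intervals).
#' The slow rate is omitted at concentrations where double-exponential
#' fitting is unreliable (at or above `high_conc_threshold`).
#'
#' @param params A [mechanism_params()] object (generating truth).
#' @param design An [experiment_design()].
#' @param rate_noise Relative s.d. of per-replicate rate perturbations.
#' @param seed Integer seed.
#' @param K_D If non-`NULL`, replaces `params$k_plus` by the value implied
#'   by this overall dissociation constant via [k_plus_from_kd()].
#' @param high_conc_threshold Ligand concentration (molar) at and above
#'   which only the fast rate is reported.
#' @return A `rate_dataset` data.frame with columns `L0`, `k1`, `k1_ci95`,
#'   `k2`, `k2_ci95`, `n_traces`, sorted by `L0`.
#' @export
simulate_rate_dataset <- function(params, design = default_design(),
                                  rate_noise = 0.05, seed = 1L, K_D = NULL,
                                  high_conc_threshold = 5e-6) {
  stopifnot(inherits(params, "mechanism_params"),
            inherits(design, "experiment_design"), rate_noise >= 0)
  if (!is.null(K_D)) {
    params <- mechanism_params(params$model,
                               k_plus_from_kd(K_D, params$k_minus,
                                              params$k_e, params$k_r,
                                              params$model),
                               params$k_minus, params$k_e, params$k_r)
  }
  cond <- design$conditions
  if (nrow(cond) == 0) return(empty_rate_dataset())
  rows <- withr::with_seed(seed, lapply(seq_len(nrow(cond)), function(i) {
    n <- cond$replicates[i]
    rr <- relaxation_rates(params, cond$L0[i], design$P0)
    k1s <- rr$k1 * (1 + rate_noise * stats::rnorm(n))
    k2s <- rr$k2 * (1 + rate_noise * stats::rnorm(n))
    se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
    drop_k2 <- cond$L0[i] >= high_conc_threshold * (1 - 1e-9)
    data.frame(L0 = cond$L0[i], k1 = mean(k1s), k1_ci95 = 1.96 * se(k1s),
               k2 = if (drop_k2) NA_real_ else mean(k2s),
               k2_ci95 = if (drop_k2) NA_real_ else 1.96 * se(k2s),
               n_traces = n)
  }))
  ds <- do.call(rbind, rows)
  ds <- ds[order(ds$L0), , drop = FALSE]
  rownames(ds) <- NULL
  class(ds) <- c("rate_dataset", "data.frame")
  ds
}

empty_rate_dataset <- function() {
  ds <- data.frame(L0 = numeric(0), k1 = numeric(0), k1_ci95 = numeric(0),
                   k2 = numeric(0), k2_ci95 = numeric(0),
                   n_traces = integer(0))
  class(ds) <- c("rate_dataset", "data.frame")
  ds
}

#' Simulate a saturation-transfer decay curve
#'
#' Generates on-resonance intensities of a monitored spin exchanging with a
#' saturated partner, following the Bloch-McConnell solution
#' \deqn{I_S(t) = I_S(0)\left(\frac{k_{SI}}{k_{SI}+R_S} e^{-t (R_S+k_{SI})}
#'       + \frac{R_S}{k_{SI}+R_S}\right)}
#' plus Gaussian noise; the off-resonance channel is the unsaturated
#' intensity plus independent noise (no transfer). An alternative ODE mode
#' integrates `dM_S/dt = -R_S (M_S - I0) - k_SI M_S`, whose solution under
#' ideal saturation is the closed form.
#'
#' @param k_SI Exchange rate constant from the monitored spin S to the
#'   saturated spin I (/s).
#' @param R_S Longitudinal relaxation rate of S (/s).
#' @param I0 Unsaturated intensity of S (arbitrary units).
#' @param sat_times Saturation times (s), default ten points on 0.05-1 s.
#' @param noise_sigma Absolute noise s.d. (intensity units).
#' @param seed Integer seed.
#' @param mode `"closed_form"` (default) or `"ode"`.
#' @return An object of class `std_curve` (see [build_std_curve()]); its
#'   `corrected` series is not yet computed.
#' @export
simulate_std_curve <- function(k_SI, R_S, I0 = 1,
                               sat_times = seq(0.05, 1, length.out = 10),
                               noise_sigma = 0.01 * I0, seed = 1L,
                               mode = c("closed_form", "ode")) {
  mode <- match.arg(mode)
  stopifnot(k_SI >= 0, R_S > 0, I0 > 0, all(sat_times >= 0),
            noise_sigma >= 0)
  ideal <- if (mode == "closed_form") {
    std_transfer_curve(sat_times, k_SI, R_S, I0)
  } else {
    sol <- deSolve::ode(
      y = c(M = I0), times = sort(unique(c(0, sat_times))),
      func = function(t, y, p) list(-R_S * (y - I0) - k_SI * y),
      parms = NULL, rtol = 1e-12, atol = 1e-12 * I0)
    sol[match(sat_times, sol[, "time"]), "M"]
  }
  noise <- withr::with_seed(seed,
                            matrix(stats::rnorm(2 * length(sat_times), 0,
                                                noise_sigma), ncol = 2))
  structure(list(sat_times = sat_times,
                 on_intensity = ideal + noise[, 1],
                 off_intensity = I0 + noise[, 2],
                 reference_intensity = I0, corrected = NULL,
                 dialect = NULL,
                 provenance = list(k_SI = k_SI, R_S = R_S, I0 = I0,
                                   seed = seed, noise_sigma = noise_sigma,
                                   mode = mode)),
            class = "std_curve")
}

# Bloch-McConnell closed form for a monitored spin exchanging with a
# fully saturated partner.
std_transfer_curve <- function(t, k_SI, R_S, I0) {
  tot <- k_SI + R_S
  I0 * (k_SI / tot * exp(-t * tot) + R_S / tot)
}
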