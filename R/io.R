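#' Write a stopped-flow trace as delimited text
#'
#' Format: comment header lines `# key=value` carrying metadata (`model`,
#' `L0_uM`, `P0_uM`, `seed`, `noise_sigma`, `dead_time_s`), then a
#' `time_s,signal` column header and comma-separated rows. Concentrations
#' in headers are micromolar (after mixing); numbers are written at full
#' double precision so traces round-trip exactly.
#'
#' @param trace A `stopped_flow_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  prov <- trace$provenance
  hdr <- c(model = if (is.null(prov$model)) "unknown" else prov$model,
           L0_uM = format(trace$L0 * 1e6, digits = 17),
           P0_uM = format(trace$P0 * 1e6, digits = 17),
           seed = if (is.null(prov$seed)) "NA" else format(prov$seed),
           noise_sigma = if (is.null(prov$noise_sigma)) "NA"
                         else format(prov$noise_sigma, digits = 17),
           dead_time_s = format(trace$times[1], digits = 17))
  lines <- c(sprintf("# %s=%s", names(hdr), hdr), "time_s,signal",
             sprintf("%.17g,%.17g", trace$times, trace$signal))
  writeLines(lines, path)
  invisible(path)
}

parse_header <- function(lines, path) {
  hdr_lines <- grep("^#", lines)
  kv <- list()
  for (i in hdr_lines) {
    m <- regmatches(lines[i], regexec("^#\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*)$",
                                      lines[i]))[[1]]
    if (length(m) != 3) {
      stop(sprintf("%s:%d: malformed header line '%s'", path, i, lines[i]))
    }
    kv[[m[2]]] <- m[3]
  }
  kv
}

#' Read stopped-flow traces from delimited-text files
#'
#' Parses files written in the [write_trace()] format. `paths` may be file
#' paths or a single glob pattern (expanded with [Sys.glob()]).
#'
#' @param paths Character vector of file paths, or one glob pattern.
#' @return List of `stopped_flow_trace` objects, each with a `source_file`
#'   element.
#' @export
read_traces <- function(paths) {
  if (length(paths) == 1 && !file.exists(paths)) paths <- Sys.glob(paths)
  if (length(paths) == 0) stop("no trace files found")
  lapply(paths, function(path) {
    lines <- readLines(path)
    kv <- parse_header(lines, path)
    for (fld in c("L0_uM", "P0_uM")) {
      if (is.null(kv[[fld]]) || is.na(suppressWarnings(as.numeric(kv[[fld]])))) {
        stop(sprintf("%s: missing or non-numeric required header field '%s'",
                     path, fld))
      }
    }
    body <- lines[!grepl("^#", lines)]
    if (length(body) < 2 || body[1] != "time_s,signal") {
      stop(sprintf("%s: expected 'time_s,signal' column header", path))
    }
    dat <- utils::read.csv(text = body, header = TRUE)
    if (any(diff(dat$time_s) <= 0)) {
      bad <- which(diff(dat$time_s) <= 0)[1]
      stop(sprintf("%s:%d: times not strictly increasing", path,
                   length(lines) - length(body) + 2 + bad))
    }
    structure(list(times = dat$time_s, signal = dat$signal,
                   L0 = as.numeric(kv$L0_uM) * 1e-6,
                   P0 = as.numeric(kv$P0_uM) * 1e-6,
                   provenance = list(
                     model = kv$model,
                     seed = suppressWarnings(as.integer(kv$seed)),
                     noise_sigma = suppressWarnings(as.numeric(kv$noise_sigma))),
                   source_file = path),
              class = "stopped_flow_trace")
  })
}

#' Write / read a rate dataset as delimited text
#'
#' Column header `L0_uM,k1_per_s,k1_ci95,k2_per_s,k2_ci95,n_traces`;
#' fields for an absent slow rate are left empty. Concentrations are
#' micromolar in the file, molar in the object.
#'
#' @param data A `rate_dataset`.
#' @param path File path.
#' @return `path` invisibly (write); a `rate_dataset` (read).
#' @export
write_rate_table <- function(data, path) {
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  lines <- c("L0_uM,k1_per_s,k1_ci95,k2_per_s,k2_ci95,n_traces",
             sprintf("%s,%s,%s,%s,%s,%d", fmt(data$L0 * 1e6), fmt(data$k1),
                     fmt(data$k1_ci95), fmt(data$k2), fmt(data$k2_ci95),
                     data$n_traces))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_rate_table
#' @export
read_rate_table <- function(path) {
  dat <- utils::read.csv(path, header = TRUE)
  need <- c("L0_uM", "k1_per_s", "k1_ci95", "k2_per_s", "k2_ci95", "n_traces")
  if (!all(need %in% names(dat))) {
    stop(path, ": expected columns ", paste(need, collapse = ","))
  }
  ds <- data.frame(L0 = dat$L0_uM * 1e-6, k1 = dat$k1_per_s,
                   k1_ci95 = dat$k1_ci95, k2 = dat$k2_per_s,
                   k2_ci95 = dat$k2_ci95, n_traces = as.integer(dat$n_traces))
  ds <- ds[order(ds$L0), , drop = FALSE]
  rownames(ds) <- NULL
  class(ds) <- c("rate_dataset", "data.frame")
  ds
}

#' Write / read a saturation-transfer curve as delimited text
#'
#' Comment header `# key=value` lines carrying `reference_intensity` (and
#' generator provenance where known), then columns
#' `sat_time_s,on_intensity,off_intensity`.
#'
#' @param curve An `std_curve`.
#' @param path File path.
#' @return `path` invisibly (write); an `std_curve` (read), uncorrected.
#' @export
write_std_curve <- function(curve, path) {
  stopifnot(inherits(curve, "std_curve"))
  hdr <- c(reference_intensity = format(curve$reference_intensity,
                                        digits = 17))
  prov <- curve$provenance
  if (!is.null(prov)) {
    hdr <- c(hdr, k_SI_true = format(prov$k_SI, digits = 17),
             R_S_true = format(prov$R_S, digits = 17),
             seed = format(prov$seed))
  }
  lines <- c(sprintf("# %s=%s", names(hdr), hdr),
             "sat_time_s,on_intensity,off_intensity",
             sprintf("%.17g,%.17g,%.17g", curve$sat_times,
                     curve$on_intensity, curve$off_intensity))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_std_curve
#' @export
read_std_curve <- function(path) {
  lines <- readLines(path)
  kv <- parse_header(lines, path)
  if (is.null(kv$reference_intensity)) {
    stop(path, ": missing required header field 'reference_intensity'")
  }
  body <- lines[!grepl("^#", lines)]
  dat <- utils::read.csv(text = body, header = TRUE)
  structure(list(sat_times = dat$sat_time_s, on_intensity = dat$on_intensity,
                 off_intensity = dat$off_intensity,
                 reference_intensity = as.numeric(kv$reference_intensity),
                 corrected = NULL, dialect = NULL, provenance = NULL,
                 source_file = path),
            class = "std_curve")
}

#' Pipeline configuration
#'
#' Collects every tunable of the trace-to-verdict pipeline. Can be read
#' from a YAML file with [read_pipeline_config()]; any value given here
#' overrides the file. Concentrations are molar.
#'
#' @param K_D Fixed overall dissociation constant (molar).
#' @param P0 Total receptor concentration after mixing (molar).
#' @param fit_windows Double-exponential fit windows (s).
#' @param short_window Single-exponential window (s) for high
#'   concentrations.
#' @param k1_window Window (s) defining the reported mean rates.
#' @param high_conc_threshold Concentration (molar) at and above which only
#'   the fast rate is fitted.
#' @param plausibility_threshold Maximum plausible unbound active-state
#'   probability for the conformational-selection fit.
#' @param std_dialect Correction dialect for saturation-transfer curves.
#' @param seed Integer seed used for every stochastic stage.
#' @param n_starts Multi-start count of the mechanism fits.
#' @param trace_fit_control Control list for [fit_exponentials()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(K_D = 6e-9, P0 = 1e-6,
                            fit_windows = c(5, 10, 20), short_window = 0.5,
                            k1_window = 10, high_conc_threshold = 5e-6,
                            plausibility_threshold = 0.1,
                            std_dialect = "difference", seed = 1L,
                            n_starts = 32L, trace_fit_control = list()) {
  stopifnot(K_D > 0, P0 > 0, high_conc_threshold > 0,
            plausibility_threshold > 0)
  structure(list(K_D = K_D, P0 = P0, fit_windows = fit_windows,
                 short_window = short_window, k1_window = k1_window,
                 high_conc_threshold = high_conc_threshold,
                 plausibility_threshold = plausibility_threshold,
                 std_dialect = std_dialect, seed = as.integer(seed),
                 n_starts = as.integer(n_starts),
                 trace_fit_control = trace_fit_control,
                 aic_convention = "n*log(RSS/n)+2(p+1) traces; chi2+2p mechanisms"),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with any subset of the configuration fields.
#' @param ... Overrides applied after reading the file.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  vals <- utils::modifyList(vals, list(...))
  do.call(pipeline_config, vals)
}

#' Run the full trace-to-verdict pipeline
#'
#' Orchestrates the complete analysis: stopped-flow traces are fitted with
#' single/double exponentials across the configured windows, aggregated
#' into a rate dataset, and the induced-fit and conformational-selection
#' schemes are fitted jointly and compared by AIC. If saturation-transfer
#' curves are supplied, they are corrected and fitted, and the
#' conformational exchange rates are tabulated against the induced-fit
#' `(k_e, k_r)` estimates — the cross-experiment consistency check. The
#' report echoes the configuration and is reproducible from it.
#'
#' @param config A [pipeline_config()].
#' @param traces List of `stopped_flow_trace` objects (or `NULL` when
#'   `rate_table` is given).
#' @param rate_table A precomputed `rate_dataset`; skips the trace stage.
#' @param std_curves Optional named list of `std_curve` objects; names
#'   label the fits. By convention supply `k12` (monitoring S1 while
#'   saturating S2) and `k21` (the reverse) to obtain the exchange summary.
#' @return A `run_report` list with per-stage summaries, the mechanism
#'   verdict, parameter tables with standard errors, the
#'   stopped-flow-vs-saturation-transfer rate comparison, and the config
#'   echo.
#' @export
run_pipeline <- function(config = pipeline_config(), traces = NULL,
                         rate_table = NULL, std_curves = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(package_version = as.character(utils::packageVersion("relaxkin")),
                 config = unclass(config))
  if (is.null(rate_table)) {
    if (is.null(traces)) stop("supply either traces or a rate_table")
    fits <- fit_experiment(traces, windows = config$fit_windows,
                           short_window = config$short_window,
                           high_conc_threshold = config$high_conc_threshold,
                           seed = config$seed,
                           control = config$trace_fit_control)
    rate_table <- aggregate_rates(fits, k1_window = config$k1_window,
                                  k2_windows = config$fit_windows)
    report$trace_stage <- list(n_traces = length(traces),
                               n_fits = nrow(fits),
                               n_unconverged = sum(!fits$converged))
  } else {
    report$trace_stage <- list(skipped = TRUE)
  }
  report$rate_table <- as.data.frame(rate_table)
  cmp <- compare_mechanisms(rate_table, K_D = config$K_D, P0 = config$P0,
                            plausibility_threshold = config$plausibility_threshold,
                            seed = config$seed, n_starts = config$n_starts)
  report$mechanism <- list(
    verdict = cmp$verdict,
    delta_aic = as.list(cmp$delta_aic),
    unbound_active_probability = as.list(cmp$unbound_active_probability),
    fits = lapply(cmp$fits, function(f) {
      list(model = f$model, constrained = f$constrained, k_e = f$k_e,
           k_r = f$k_r, k_minus = f$k_minus, se = as.list(f$se),
           k_plus_implied = f$k_plus_implied, K_D_fixed = f$K_D_fixed,
           chi_square = f$chi_square, aic = f$aic, converged = f$converged)
    }))
  if (!is.null(std_curves)) {
    std_fits <- lapply(std_curves, function(cv) {
      fit_std(build_std_curve(cv, dialect = config$std_dialect),
              seed = config$seed)
    })
    report$std <- lapply(std_fits, function(f) {
      list(k_SI = f$k_SI, R_S = f$R_S, I0 = f$I0, rss = f$rss,
           converged = f$converged, dialect = f$dialect)
    })
    if (all(c("k12", "k21") %in% names(std_fits))) {
      ex <- two_state_exchange(std_fits$k12$k_SI, std_fits$k21$k_SI)
      fif <- cmp$fits$IF
      report$exchange_vs_mechanism <- list(
        std_k12 = ex$k12, std_k21 = ex$k21,
        std_p1 = ex$p1, std_p2 = ex$p2,
        if_k_r = fif$k_r, if_k_e = fif$k_e,
        ratio_k12_over_k_r = ex$k12 / fif$k_r,
        ratio_k21_over_k_e = ex$k21 / fif$k_e)
    }
  }
  class(report) <- "run_report"
  report
}

#' Serialise a run report to JSON
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", dataframe = "columns")
  invisible(path)
}
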