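# Pipeline orchestration: run the full analysis per peptide x condition x
# trajectory, apply e/h averaging with half-difference errors, and emit
# result tables with provenance metadata.

#' Average paired e/h trajectory values
#'
#' Trajectories started from extended ("e") and helical ("h")
#' configurations are averaged, with half their absolute difference taken
#' as the uncertainty.
#'
#' @param value_e,value_h values from the e and h trajectories (same unit).
#' @return an `AveragedResult`: list with `mean` and `error`.
#' @export
average_eh <- function(value_e, value_h) {
  if (!is.numeric(value_e) || !is.numeric(value_h))
    stop("average_eh: inputs must be numeric")
  structure(list(mean = (value_e + value_h) / 2,
                 error = abs(value_e - value_h) / 2),
            class = "AveragedResult")
}

# Default analysis settings; every value can be overridden via the config.
.default_settings <- function() {
  list(temperature = 300, cutoff = 0.36, delta = 0.15, delta_alt = 0.34,
       dwell_mode = "per_bond_formed", n_components = 2,
       bins_per_decade = 10, min_count = 50, e2e_bin_width = 0.05,
       acf_window_threshold = 0.05, dwell_rule = "amplitude")
}

# Analyse one trajectory of one condition: kinetics, dwell/local friction,
# landscape/global friction. Returns a list of stage outputs.
.analyse_trajectory <- function(traj, settings) {
  states <- if (!is.null(traj$states)) traj$states
            else simulate_hb_states(traj$kinetics)
  e2e <- if (!is.null(traj$e2e)) traj$e2e
         else hb_to_end_to_end(states, traj$geometry)
  consts <- physical_constants(temperature = settings$temperature,
                               delta = settings$delta,
                               delta_alt = settings$delta_alt)
  n <- length(states$h_series)
  max_lag <- min(n - 1L, n %/% 4L)
  acf_vals <- autocorrelation(states$h_series, max_lag)
  rel <- fit_relaxation(acf_vals, states$dt,
                        window_threshold = settings$acf_window_threshold)
  tau_f_us <- rel$tau * 1e-6  # ps -> us
  f <- helix_fraction(states)
  rates <- rates_from_relaxation(tau_f_us, f)

  dwells <- extract_dwells(states, mode = settings$dwell_mode)
  hist <- log_histogram(dwells, bins_per_decade = settings$bins_per_decade)
  mix <- fit_exponential_mixture(hist, n_components = settings$n_components)
  tau_dwell <- ensemble_dwell_time(mix, rule = settings$dwell_rule)
  gamma_local <- local_friction(tau_dwell, consts)

  surface <- build_surface(states$h_series, e2e,
                           bin_width = settings$e2e_bin_width,
                           temperature = settings$temperature,
                           h_max = states$h_max)
  centers <- histogram_centers(surface, min_count = settings$min_count)
  gamma_global <- global_friction(rates$k_fold, centers$delta_x_sq_total,
                                  consts)

  list(rates = rates, dwells = dwells, mixture = mix,
       tau_dwell = tau_dwell, gamma_local = gamma_local,
       centers = centers, gamma_global = gamma_global,
       seed = states$meta$seed)
}

# Average a named scalar across the e/h runs of one condition; returns
# c(mean, error) with NA error for single-trajectory conditions.
.avg_field <- function(runs, extract) {
  vals <- vapply(runs, extract, numeric(1))
  if (length(vals) >= 2) {
    av <- average_eh(vals[1], vals[2])
    c(av$mean, av$error)
  } else c(vals[1], NA_real_)
}

#' Run the full analysis pipeline
#'
#' For every condition in the config, analyses each trajectory (e/h) through
#' kinetics, dwell/local-friction and landscape/global-friction stages, then
#' averages paired trajectories with half-difference errors. A stage error
#' aborts only that peptide x condition cell, with the diagnostic recorded
#' in the manifest.
#'
#' @param config list with `settings` (optional overrides of temperature,
#'   cutoff, delta, dwell_mode, n_components, bins_per_decade, min_count,
#'   e2e_bin_width) and `conditions`: a list of entries, each with
#'   `peptide`, `condition`, and `trajectories` -- a named list (names `e`,
#'   `h`) whose elements carry either `kinetics` ([kinetics_spec()]) and
#'   `geometry` ([geometry_spec()]) for synthetic input, or pre-computed
#'   `states` ([hb_state_matrix()]) and `e2e` series.
#' @return a `PipelineResult`: list with data.frames `kinetics`, `local`,
#'   `global` (3 significant figures), the full per-trajectory `runs`, and
#'   a `manifest` (settings, seeds, package version, errors).
#' @export
run_pipeline <- function(config) {
  settings <- utils::modifyList(.default_settings(),
                                config$settings %||% list())
  kin_rows <- list(); loc_rows <- list(); glob_rows <- list()
  runs_all <- list(); errors <- list()
  for (cond in config$conditions) {
    tag <- paste(cond$peptide, cond$condition, sep = "/")
    runs <- list()
    for (tr_name in names(cond$trajectories)) {
      res <- tryCatch(
        .analyse_trajectory(cond$trajectories[[tr_name]], settings),
        error = function(e) e)
      if (inherits(res, "error")) {
        errors[[paste(tag, tr_name, sep = "/")]] <- conditionMessage(res)
      } else {
        runs[[tr_name]] <- res
      }
    }
    runs_all[[tag]] <- runs
    if (length(runs) == 0) next
    single <- length(runs) < 2

    ku <- .avg_field(runs, function(r) r$rates$k_unfold)
    kf <- .avg_field(runs, function(r) r$rates$k_fold)
    Kv <- .avg_field(runs, function(r) r$rates$K)
    K_err <- if (!single && ku[1] > 0 && kf[1] > 0)
      propagate_K_error(Kv[1], kf[1], kf[2], ku[1], ku[2]) else NA_real_
    kin_rows[[tag]] <- data.frame(
      peptide = cond$peptide, condition = cond$condition,
      k_unfold_per_us = signif(ku[1], 3), k_unfold_err = signif(ku[2], 3),
      k_fold_per_us = signif(kf[1], 3), k_fold_err = signif(kf[2], 3),
      K = signif(Kv[1], 3), K_err = signif(K_err, 3),
      single_trajectory = single)

    tau <- .avg_field(runs, function(r) r$tau_dwell)
    gl <- .avg_field(runs, function(r) friction_in(r$gamma_local, "ng/s"))
    loc_rows[[tag]] <- data.frame(
      peptide = cond$peptide, condition = cond$condition,
      dwell_time_ps = signif(tau[1], 3), dwell_time_err = signif(tau[2], 3),
      local_friction_ng_s = signif(gl[1], 3),
      local_friction_err = signif(gl[2], 3),
      single_trajectory = single)

    dx <- .avg_field(runs, function(r) r$centers$delta_x_reported * 10)  # nm -> Angstrom
    gg <- .avg_field(runs, function(r) friction_in(r$gamma_global, "ug/s"))
    glob_rows[[tag]] <- data.frame(
      peptide = cond$peptide, condition = cond$condition,
      delta_x_A = signif(dx[1], 3), delta_x_err = signif(dx[2], 3),
      global_friction_ug_s = signif(gg[1], 3),
      global_friction_err = signif(gg[2], 3),
      single_trajectory = single)
  }
  bind <- function(rows) {
    if (length(rows) == 0) return(data.frame())
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
  seeds <- lapply(runs_all, function(runs) lapply(runs, `[[`, "seed"))
  structure(list(kinetics = bind(kin_rows), local = bind(loc_rows),
                 global = bind(glob_rows), runs = runs_all,
                 manifest = list(settings = settings, seeds = seeds,
                                 errors = errors,
                                 package_version =
                                   as.character(packageVersion("helixfriction")))),
            class = "PipelineResult")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.PipelineResult <- function(x, ...) {
  cat("PipelineResult\n== kinetics ==\n"); print(x$kinetics)
  cat("== local friction ==\n"); print(x$local)
  cat("== global friction ==\n"); print(x$global)
  if (length(x$manifest$errors)) {
    cat("== stage errors ==\n")
    for (nm in names(x$manifest$errors))
      cat(sprintf("  %s: %s\n", nm, x$manifest$errors[[nm]]))
  }
  invisible(x)
}

#' Write pipeline tables and manifest to a directory
#'
#' Emits `kinetics.csv`, `local_friction.csv`, `global_friction.csv` and a
#' JSON `manifest.json` recording the settings, seeds and package version.
#'
#' @param result a `PipelineResult`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_tables <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$kinetics, file.path(out_dir, "kinetics.csv"),
                   row.names = FALSE)
  utils::write.csv(result$local, file.path(out_dir, "local_friction.csv"),
                   row.names = FALSE)
  utils::write.csv(result$global, file.path(out_dir, "global_friction.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(out_dir)
}

#' Read a pipeline configuration from JSON
#'
#' The JSON mirrors the list accepted by [run_pipeline()]: an optional
#' `settings` object and a `conditions` array whose trajectories carry
#' `kinetics` and `geometry` parameter objects (fields of [kinetics_spec()]
#' and [geometry_spec()]).
#'
#' @param path JSON file.
#' @return config list suitable for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  conds <- lapply(raw$conditions, function(cond) {
    cond$trajectories <- lapply(cond$trajectories, function(tr) {
      list(kinetics = do.call(kinetics_spec, tr$kinetics),
           geometry = do.call(geometry_spec, tr$geometry %||% list()))
    })
    cond
  })
  list(settings = lapply(raw$settings %||% list(), function(v) v),
       conditions = conds)
}
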