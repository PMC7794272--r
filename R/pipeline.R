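#' Configuration for an end-to-end pipeline run
#'
#' Collects every tunable of the pipeline in one serialisable (YAML-safe)
#' list: the ground truth, the experimental design, the fitting options, and
#' the master seed.
#'
#' @param mode `"simulate"` (generate trials from the ground-truth model) or
#'   `"ingest"` (read trials from `trials_file`).
#' @param n_observers Number of simulated observers.
#' @param conditions Viewing condition(s) to simulate.
#' @param seed Master seed for all randomness.
#' @param lines `"binocular"` ([pf_lines_binocular()]), `"by_condition"`
#'   ([pf_lines_by_condition()]), or a line table as a data frame/list.
#' @param sigma_observer,sigma_location,lambda,gamma Passed to
#'   [performance_field_model()].
#' @param n_sessions,blocks_per_session,cardinal_extra_blocks,step_deg,eccentricity_deg,trials_per_sf,sf_center_cpd
#'   Passed to [schedule_blocks()].
#' @param recenter Recentre SF grids between simulated blocks.
#' @param fit Named list of overrides for [fit_control()].
#' @param trials_file Trial CSV to ingest (mode `"ingest"`).
#' @param out_dir Output directory (optional; can also be given to
#'   [run_pipeline()]).
#'
#' @return A list of class `pf_config`.
#' @export
pf_config <- function(mode = c("simulate", "ingest"),
                      n_observers = 14,
                      conditions = "binocular",
                      seed = 1,
                      lines = "binocular",
                      sigma_observer = 0.06,
                      sigma_location = 0,
                      lambda = 0,
                      gamma = 0.5,
                      n_sessions = 4,
                      blocks_per_session = 7,
                      cardinal_extra_blocks = 0,
                      step_deg = 15,
                      eccentricity_deg = 10,
                      trials_per_sf = 5,
                      sf_center_cpd = 7,
                      recenter = TRUE,
                      fit = list(),
                      trials_file = NULL,
                      out_dir = NULL) {
  mode <- match.arg(mode)
  cfg <- list(
    mode = mode, n_observers = n_observers, conditions = conditions,
    seed = seed, lines = lines, sigma_observer = sigma_observer,
    sigma_location = sigma_location, lambda = lambda, gamma = gamma,
    n_sessions = n_sessions, blocks_per_session = blocks_per_session,
    cardinal_extra_blocks = cardinal_extra_blocks, step_deg = step_deg,
    eccentricity_deg = eccentricity_deg, trials_per_sf = trials_per_sf,
    sf_center_cpd = sf_center_cpd, recenter = recenter, fit = fit,
    trials_file = trials_file, out_dir = out_dir
  )
  class(cfg) <- "pf_config"
  cfg
}

config_model <- function(config) {
  lines <- config$lines
  if (is.character(lines) && length(lines) == 1) {
    lines <- switch(lines,
                    binocular = pf_lines_binocular(),
                    by_condition = pf_lines_by_condition(),
                    abort(paste0("Unknown line table keyword: ", lines)))
  } else {
    lines <- dplyr::bind_rows(lapply(
      if (is.data.frame(lines)) list(lines) else lines, tibble::as_tibble))
  }
  performance_field_model(lines, config$sigma_observer,
                          config$sigma_location, config$lambda, config$gamma)
}

config_schedule <- function(config) {
  schedule_blocks(
    n_sessions = config$n_sessions,
    blocks_per_session = config$blocks_per_session,
    cardinal_extra_blocks = config$cardinal_extra_blocks,
    step_deg = config$step_deg,
    eccentricity_deg = config$eccentricity_deg,
    trials_per_sf = config$trials_per_sf,
    sf_center_cpd = config$sf_center_cpd
  )
}

#' Run the full performance-fields pipeline
#'
#' Sequences the analysis end to end: simulate (or ingest) trials, collapse
#' hemifields, fit per-location psychometric functions, and run the
#' asymmetry analyses (angular-distance mixed models for threshold and
#' cutoff, VF-averaged and per-VF; cardinal HVA/VMA summaries; accuracy-ratio
#' curves). Identical configurations produce identical reports.
#'
#' @param config A [pf_config()].
#' @param out_dir Output directory; when given, the run writes its config
#'   echo, the (simulated) trial table, the estimates CSV, a JSON report, and
#'   a log file there.
#'
#' @return An object of class `pf_report`: the config, seed, package
#'   version, trial and estimate tables, fitted angular models, asymmetry
#'   summaries, ratio curves, and the run log.
#' @examples
#' \donttest{
#' cfg <- pf_config(n_observers = 3, n_sessions = 1, seed = 7)
#' rep <- run_pipeline(cfg)
#' rep$angular$threshold_vf$lines
#' }
#' @export
run_pipeline <- function(config, out_dir = config$out_dir) {
  stopifnot(inherits(config, "pf_config"))
  log_lines <- character()
  note <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  if (config$mode == "simulate" && config$n_observers < 1) {
    abort("stage config: `n_observers` must be >= 1.",
          class = "acuityfields_invalid_design")
  }
  if (config$mode == "ingest" && is.null(config$trials_file)) {
    abort("stage config: ingest mode requires `trials_file`.",
          class = "acuityfields_io_error")
  }

  model <- config_model(config)
  fit_ctrl <- do.call(fit_control, config$fit)

  if (config$mode == "simulate") {
    note("stage simulate: %d observer(s), conditions %s, seed %d",
         config$n_observers, paste(config$conditions, collapse = "/"),
         config$seed)
    trials <- simulate_experiment(
      model = model, schedule = config_schedule(config),
      n_observers = config$n_observers, conditions = config$conditions,
      seed = config$seed, recenter = config$recenter
    )
  } else {
    note("stage ingest: %s", config$trials_file)
    trials <- read_trials(config$trials_file)
  }
  note("stage collapse: %d trials", nrow(trials))
  collapsed <- collapse_hemifields(trials)

  note("stage fit: per-location psychometric fits")
  estimates <- estimate_locations(collapsed, fit_ctrl)
  n_degen <- sum(estimates$degenerate)
  n_nonconv <- sum(!estimates$converged & !estimates$degenerate)
  note("stage fit: %d fits (%d degenerate, %d non-converged)",
       nrow(estimates), n_degen, n_nonconv)

  note("stage analyze: angular models and asymmetries")
  multi_cond <- dplyr::n_distinct(estimates$condition) > 1
  vf_preds <- c("angular_distance", "visual_field",
                if (multi_cond) "condition")
  avg_preds <- c("angular_distance", if (multi_cond) "condition")
  angular <- list(
    threshold_avg = fit_angular_model(estimates, "threshold", avg_preds),
    threshold_vf = fit_angular_model(estimates, "threshold", vf_preds),
    cutoff_avg = fit_angular_model(estimates, "cutoff", avg_preds),
    cutoff_vf = fit_angular_model(estimates, "cutoff", vf_preds),
    max_slope_avg = fit_angular_model(estimates, "max_slope", avg_preds)
  )
  asymmetry <- list(
    threshold = cardinal_asymmetries(estimates, "threshold"),
    cutoff = cardinal_asymmetries(estimates, "cutoff")
  )
  curves <- purrr::map(split(collapsed, collapsed$condition), function(tr) {
    list(hva = accuracy_ratio_by_sf(tr, "hva"),
         vma = accuracy_ratio_by_sf(tr, "vma"))
  })

  report <- structure(
    list(
      config = config,
      seed = config$seed,
      version = as.character(packageVersion("acuityfields")),
      trials = trials,
      estimates = estimates,
      angular = angular,
      asymmetry = asymmetry,
      ratio_curves = curves,
      log = log_lines
    ),
    class = "pf_report"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_run_config(config, file.path(out_dir, "config.yaml"))
    if (config$mode == "simulate") {
      write_trials(trials, file.path(out_dir, "trials.csv"))
    }
    readr::write_csv(estimates, file.path(out_dir, "estimates.csv"),
                     progress = FALSE)
    jsonlite::write_json(report_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(report$log, file.path(out_dir, "log.txt"))
    note("stage write: artifacts in %s", out_dir)
  }
  report
}

report_json <- function(report) {
  list(
    version = report$version,
    seed = report$seed,
    config = unclass(report$config),
    n_trials = nrow(report$trials),
    angular = purrr::map(report$angular, function(m) {
      list(response = m$response,
           predictors = m$predictors,
           coefficients = m$coefficients,
           lines = m$lines,
           sigma_observer = m$sigma_observer,
           sigma_residual = m$sigma_residual)
    }),
    asymmetry = purrr::map(report$asymmetry, function(a) {
      list(measure = a$measure, group = a$group,
           observers = a$observer_ratios)
    }),
    ratio_curves = report$ratio_curves
  )
}

#' @method print pf_report
#' @export
print.pf_report <- function(x, ...) {
  cat(sprintf("<pf_report> acuityfields %s, seed %d\n", x$version, x$seed))
  cat(sprintf("  %d trials, %d location fits\n",
              nrow(x$trials), nrow(x$estimates)))
  cat("Threshold lines (per VF):\n")
  print(x$angular$threshold_vf$lines)
  cat("Cardinal asymmetries (threshold):\n")
  print(x$asymmetry$threshold$group)
  invisible(x)
}
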