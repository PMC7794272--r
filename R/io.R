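#' Read and write the trial CSV dialect
#'
#' The trial table dialect is a UTF-8 CSV with '.' decimal separator and
#' header columns `observer_id`, `condition` (binocular/monocular),
#' `session`, `block`, `polar_angle_deg` (in \[0, 360)), `eccentricity_deg`,
#' `sf_cpd` (> 0), and `correct` (0/1). Unknown columns are preserved on a
#' round trip.
#'
#' `read_trials()` validates every row. Rows failing validation are reported
#' by row number; by default any invalid row aborts the read, while
#' `skip_bad = TRUE` drops them with a warning.
#'
#' @param path File path.
#' @param skip_bad Drop invalid rows instead of aborting.
#' @param trials A trial table to write.
#'
#' @return `read_trials()` returns a tibble of validated trials (invalid rows
#'   removed when `skip_bad = TRUE`); `write_trials()` returns `trials`
#'   invisibly.
#' @export
read_trials <- function(path, skip_bad = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("No such file: ", path), class = "acuityfields_io_error")
  }
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("observer_id", "condition", "session", "block",
                "polar_angle_deg", "eccentricity_deg", "sf_cpd", "correct")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols) > 0) {
    abort(paste0("Trial file is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "acuityfields_format_error")
  }
  bad <- !is.finite(d$sf_cpd) | d$sf_cpd <= 0 |
    !is.finite(d$polar_angle_deg) | d$polar_angle_deg < 0 |
    d$polar_angle_deg >= 360 |
    !(d$correct %in% c(0, 1)) |
    !(d$condition %in% c("binocular", "monocular"))
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    rows <- which(bad)
    msg <- paste0(sum(bad), " invalid row(s) at line(s): ",
                  paste(head(rows, 10), collapse = ", "),
                  if (length(rows) > 10) ", ...")
    if (!skip_bad) {
      abort(paste0(msg, " (use skip_bad = TRUE to drop them)"),
            class = "acuityfields_format_error")
    }
    warn(paste0("Dropping ", msg))
    d <- d[!bad, ]
  }
  d$correct <- as.integer(d$correct)
  d
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path, progress = FALSE)
  invisible(trials)
}

#' Read and write run configurations
#'
#' Serialises a [pf_config()] to YAML and back; a run's configuration is
#' echoed verbatim into its output directory.
#'
#' @param config A [pf_config()] list.
#' @param path File path.
#' @return `read_run_config()` returns a `pf_config`; `write_run_config()`
#'   returns `config` invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(config)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pf_config, cfg)
}
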