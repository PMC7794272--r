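#' Derive polar-angle geometry for isoeccentric locations
#'
#' Given polar angles (0 degrees = right horizontal meridian, counterclockwise
#' positive), computes the angular distance from the vertical meridian (VM),
#' the visual field, and the hemifield of each location.
#'
#' @param polar_angle_deg Numeric vector of polar angles in degrees; reduced
#'   modulo 360.
#' @param eccentricity_deg Eccentricity in degrees of visual angle (recycled).
#'
#' @return A tibble with columns `polar_angle_deg`, `eccentricity_deg`,
#'   `angular_distance_deg` (distance from the VM, in \[0, 90\]),
#'   `visual_field` (`"upper"`, `"lower"`, or `"horizontal"`), and
#'   `hemifield` (`"left"`, `"right"`, or `"vertical"`).
#'
#' @examples
#' location_info(c(0, 45, 90, 270, 300))
#' @export
location_info <- function(polar_angle_deg, eccentricity_deg = 10) {
  phi <- polar_angle_deg %% 360
  circ_sep <- function(a, m) {
    d <- abs(a - m)
    pmin(d, 360 - d)
  }
  dist <- pmin(circ_sep(phi, 90), circ_sep(phi, 270))
  tol <- 1e-9
  on_hm <- abs(phi) < tol | abs(phi - 180) < tol | abs(phi - 360) < tol
  on_vm <- abs(phi - 90) < tol | abs(phi - 270) < tol
  vf <- dplyr::case_when(
    on_hm ~ "horizontal",
    phi > 0 & phi < 180 ~ "upper",
    TRUE ~ "lower"
  )
  hemi <- dplyr::case_when(
    on_vm ~ "vertical",
    phi > 90 & phi < 270 ~ "left",
    TRUE ~ "right"
  )
  tibble::tibble(
    polar_angle_deg = phi,
    eccentricity_deg = eccentricity_deg,
    angular_distance_deg = dist,
    visual_field = vf,
    hemifield = hemi
  )
}

#' Build the grid of isoeccentric test locations
#'
#' Places locations every `step_deg` degrees of polar angle around a circle of
#' the given eccentricity. The default 15-degree step yields the 24-location
#' layout used throughout the package.
#'
#' @param step_deg Polar-angle step in degrees; must divide 360.
#' @param eccentricity_deg Eccentricity in degrees of visual angle.
#'
#' @return A tibble of locations, one row per polar angle, with the derived
#'   columns of [location_info()].
#' @examples
#' build_location_grid(15, 10)   # 24 locations
#' build_location_grid(90, 10)   # the four cardinals
#' @export
build_location_grid <- function(step_deg = 15, eccentricity_deg = 10) {
  if (!is.numeric(step_deg) || length(step_deg) != 1 || step_deg <= 0 ||
      abs(360 / step_deg - round(360 / step_deg)) > 1e-9) {
    abort("`step_deg` must be a positive divisor of 360.",
          class = "acuityfields_invalid_design")
  }
  angles <- seq(0, 360 - step_deg, by = step_deg)
  location_info(angles, eccentricity_deg)
}

#' Distance between the centres of adjacent locations
#'
#' Chord length, in degrees of visual angle, between two adjacent isoeccentric
#' locations separated by `step_deg` of polar angle:
#' `2 * eccentricity * sin(step/2)`.
#'
#' @inheritParams build_location_grid
#' @return Chord distance in degrees of visual angle.
#' @examples
#' location_spacing(15, 10)  # ~2.61 deg
#' @export
location_spacing <- function(step_deg = 15, eccentricity_deg = 10) {
  2 * eccentricity_deg * sin(step_deg / 2 * pi / 180)
}

#' Build a spatial-frequency sampling grid
#'
#' A block samples 13 spatial frequencies centred on `center_cpd` in equal
#' 0.25-cpd steps, plus the fixed anchors 2 and 12 cpd that pin the upper and
#' lower asymptotes of the psychometric function. Values falling outside the
#' anchor range are clamped to it and duplicates removed, so grids whose
#' centre is near an anchor have fewer than 15 distinct values.
#'
#' @param center_cpd Central spatial frequency, cycles per degree; must lie
#'   strictly between the anchors.
#' @param step_cpd Step between centred values (cpd).
#' @param n_centered Number of centred values (odd).
#' @param anchors Low/high anchor frequencies always included (cpd).
#'
#' @return An object of class `sf_grid`: a list with `values_cpd` (sorted,
#'   distinct sampling frequencies) and `center_cpd`.
#' @examples
#' build_sf_grid(7)       # 15 values from 2 to 12 cpd
#' build_sf_grid(10.75)   # clamped near the upper anchor, < 15 values
#' @export
build_sf_grid <- function(center_cpd = 7, step_cpd = 0.25, n_centered = 13,
                          anchors = c(2, 12)) {
  lo <- min(anchors)
  hi <- max(anchors)
  if (!is.numeric(center_cpd) || length(center_cpd) != 1 ||
      center_cpd <= lo || center_cpd >= hi) {
    abort(sprintf("`center_cpd` must lie strictly between the anchors (%g, %g).",
                  lo, hi),
          class = "acuityfields_invalid_design")
  }
  if (n_centered %% 2 != 1) {
    abort("`n_centered` must be odd so the grid is symmetric about its centre.",
          class = "acuityfields_invalid_design")
  }
  half <- (n_centered - 1) / 2
  vals <- center_cpd + step_cpd * seq(-half, half)
  vals <- pmin(pmax(vals, lo), hi)
  vals <- sort(unique(c(vals, lo, hi)))
  structure(
    list(values_cpd = vals, center_cpd = center_cpd, step_cpd = step_cpd),
    class = "sf_grid"
  )
}

#' @method print sf_grid
#' @export
print.sf_grid <- function(x, ...) {
  cat(sprintf("<sf_grid> %d values (cpd), centre %.2f: %s\n",
              length(x$values_cpd), x$center_cpd,
              paste(format(x$values_cpd, trim = TRUE), collapse = ", ")))
  invisible(x)
}

#' Schedule testing blocks over rotations of the four-location layout
#'
#' Each block tests four locations separated by 90 degrees of polar angle,
#' obtained by rotating the vertical-meridian-anchored layout clockwise by
#' 0, 15, 30, 45, 60, 75, or 90 degrees. Rotation-0 and rotation-90 blocks
#' both land on the four cardinal locations, so with the default schedule
#' (4 sessions of 7 blocks, cycling the rotations) cardinals accumulate twice
#' the trials of noncardinal locations (expected 600 vs 300 per location with
#' a 15-value grid). `cardinal_extra_blocks` appends further rotation-0/90
#' blocks to concentrate even more trials on the cardinals.
#'
#' @param n_sessions Number of sessions.
#' @param blocks_per_session Blocks per session.
#' @param cardinal_extra_blocks Extra cardinal blocks appended to the final
#'   session, alternating rotation 0 and 90.
#' @param step_deg Rotation step in degrees.
#' @param eccentricity_deg Eccentricity of all locations.
#' @param trials_per_sf Trials per spatial-frequency value per location per
#'   block.
#' @param sf_center_cpd Initial centre of every location's SF grid (cpd).
#'
#' @return A tibble of class `pf_schedule` with one row per block-location:
#'   `session`, `block`, `rotation_deg`, location geometry columns,
#'   `trials_per_sf`, and `sf_center_cpd`.
#' @examples
#' sched <- schedule_blocks()
#' expected_location_trials(sched)
#' @export
schedule_blocks <- function(n_sessions = 4, blocks_per_session = 7,
                            cardinal_extra_blocks = 0, step_deg = 15,
                            eccentricity_deg = 10, trials_per_sf = 5,
                            sf_center_cpd = 7) {
  if (n_sessions < 1 || blocks_per_session < 1 || cardinal_extra_blocks < 0) {
    abort("Session and block counts must be positive.",
          class = "acuityfields_invalid_design")
  }
  rotations <- seq(0, 90, by = step_deg)
  n_base <- n_sessions * blocks_per_session
  rot <- rep_len(rotations, n_base)
  session <- rep(seq_len(n_sessions), each = blocks_per_session)
  if (cardinal_extra_blocks > 0) {
    rot <- c(rot, rep_len(c(0, 90), cardinal_extra_blocks))
    session <- c(session, rep(n_sessions, cardinal_extra_blocks))
  }
  blocks <- tibble::tibble(
    session = session,
    block = seq_along(rot),
    rotation_deg = rot
  )
  out <- tidyr::expand_grid(blocks, offset = c(0, 90, 180, 270)) %>%
    dplyr::mutate(polar_angle_deg = (90 - .data$rotation_deg + .data$offset) %% 360) %>%
    dplyr::select(-"offset")
  out <- dplyr::bind_cols(
    out[c("session", "block", "rotation_deg")],
    location_info(out$polar_angle_deg, eccentricity_deg)
  ) %>%
    dplyr::mutate(trials_per_sf = trials_per_sf, sf_center_cpd = sf_center_cpd)
  class(out) <- c("pf_schedule", class(out))
  out
}

#' Expected trial totals per location for a schedule
#'
#' @param schedule A schedule from [schedule_blocks()].
#' @param n_sf_values Number of distinct spatial frequencies sampled per
#'   location per block (15 for an unclamped grid).
#'
#' @return A tibble with one row per location: geometry columns, the number of
#'   blocks testing it, and `expected_trials`.
#' @export
expected_location_trials <- function(schedule, n_sf_values = 15) {
  schedule %>%
    dplyr::group_by(.data$polar_angle_deg, .data$eccentricity_deg,
                    .data$angular_distance_deg, .data$visual_field,
                    .data$hemifield) %>%
    dplyr::summarise(
      n_blocks = dplyr::n(),
      expected_trials = sum(.data$trials_per_sf) * n_sf_values,
      .groups = "drop"
    )
}

#' Recentre a spatial-frequency grid on a fitted threshold
#'
#' Emulates the between-block adjustment that keeps the sampled SF range
#' centred on the dynamic range of each location's psychometric function: the
#' new centre is the fitted 75%-correct threshold (in cpd) rounded to the
#' nearest 0.25 cpd and clamped to \[2.25, 11.75\]. To avoid churn the grid is
#' left unchanged when the recentred value moves by less than 0.5 cpd (the
#' dead band) or when the previous fit did not converge (in which case the
#' returned grid carries attribute `recenter_warning = TRUE`).
#'
#' @param previous_fit A [fit_psychometric()] fit of the data collected so far
#'   at the location.
#' @param old_grid The current `sf_grid`.
#'
#' @return An `sf_grid`, possibly the old one.
#' @export
recenter_sf_grid <- function(previous_fit, old_grid) {
  stopifnot(inherits(old_grid, "sf_grid"))
  if (!inherits(previous_fit, "pf_fit") || previous_fit$degenerate ||
      !isTRUE(previous_fit$converged)) {
    attr(old_grid, "recenter_warning") <- TRUE
    return(old_grid)
  }
  p <- previous_fit$params
  thr_cpd <- 10^invert_performance(0.75, p$alpha, p$beta, p$gamma, p$lambda)
  new_center <- round(thr_cpd / 0.25) * 0.25
  new_center <- min(max(new_center, 2.25), 11.75)
  if (abs(new_center - old_grid$center_cpd) < 0.5) {
    return(old_grid)
  }
  build_sf_grid(new_center, step_cpd = old_grid$step_cpd)
}
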