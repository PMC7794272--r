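#' Ground-truth line tables for the performance-field model
#'
#' Each table gives, per visual field and viewing condition, the linear
#' dependence of the log10-cpd SF threshold (75% correct) and SF cutoff
#' (51% correct) on the angular distance from the vertical meridian:
#' `value = intercept + slope * distance`.
#'
#' `pf_lines_binocular()` is the default table for the binocular cohort:
#' threshold lines `0.7083 + 0.00194 d` (upper VF) and `0.7922 + 0.00115 d`
#' (lower VF); cutoff lines `0.8326 + 0.00197 d` and `0.9067 + 0.00114 d`.
#'
#' `pf_lines_by_condition()` describes the smaller cohort tested under both
#' viewing conditions. Its VF-averaged lines are `0.7085 + 0.00151 d`
#' (monocular threshold), `0.7406 + 0.00150 d` (binocular threshold),
#' `0.8188 + 0.00186 d` (monocular cutoff), and `0.8545 + 0.00147 d`
#' (binocular cutoff); upper and lower VF lines are obtained by applying the
#' binocular cohort's upper-lower intercept and slope offsets around each
#' average, since no per-VF-by-condition equations are available.
#'
#' @return A tibble with columns `condition`, `visual_field`, `measure`
#'   (`"threshold"` or `"cutoff"`), `intercept` (log10 cpd), and `slope`
#'   (log10 cpd per degree).
#' @examples
#' pf_lines_binocular()
#' @export
pf_lines_binocular <- function() {
  tibble::tribble(
    ~condition,  ~visual_field, ~measure,    ~intercept, ~slope,
    "binocular", "upper",       "threshold", 0.7083,     0.00194,
    "binocular", "lower",       "threshold", 0.7922,     0.00115,
    "binocular", "upper",       "cutoff",    0.8326,     0.00197,
    "binocular", "lower",       "cutoff",    0.9067,     0.00114
  )
}

#' @rdname pf_lines_binocular
#' @export
pf_lines_by_condition <- function() {
  # upper-lower offsets taken from the binocular cohort's per-VF lines
  d_int_thr <- 0.7922 - 0.7083
  d_slp_thr <- 0.00115 - 0.00194
  d_int_cut <- 0.9067 - 0.8326
  d_slp_cut <- 0.00114 - 0.00197
  avg <- tibble::tribble(
    ~condition,  ~measure,    ~intercept, ~slope,
    "monocular", "threshold", 0.7085,     0.00151,
    "binocular", "threshold", 0.7406,     0.00150,
    "monocular", "cutoff",    0.8188,     0.00186,
    "binocular", "cutoff",    0.8545,     0.00147
  )
  tidyr::expand_grid(avg, visual_field = c("upper", "lower")) %>%
    dplyr::mutate(
      sign = ifelse(.data$visual_field == "lower", 0.5, -0.5),
      d_int = ifelse(.data$measure == "threshold", d_int_thr, d_int_cut),
      d_slp = ifelse(.data$measure == "threshold", d_slp_thr, d_slp_cut),
      intercept = .data$intercept + .data$sign * .data$d_int,
      slope = .data$slope + .data$sign * .data$d_slp
    ) %>%
    dplyr::select("condition", "visual_field", "measure", "intercept", "slope")
}

#' Construct a performance-field ground-truth model
#'
#' Bundles the per-VF/condition threshold and cutoff lines with the
#' between-observer variability, location jitter, and asymptote parameters
#' used to simulate trial-level data.
#'
#' @param lines A line table in the format of [pf_lines_binocular()].
#' @param sigma_observer SD of the observer random intercept (log10 cpd).
#'   The default 0.06 gives between-observer threshold SDs of about 1 cpd
#'   near 7.8 cpd at the horizontal meridian.
#' @param sigma_location SD of location-level jitter (log10 cpd; default 0).
#' @param lambda Lapse rate (upper-asymptote deficit), in \[0, 0.1\].
#' @param gamma Guess rate (lower asymptote); 0.5 for a 2AFC task.
#'
#' @return An object of class `pf_model`.
#' @examples
#' performance_field_model()
#' performance_field_model(pf_lines_by_condition())
#' @export
performance_field_model <- function(lines = pf_lines_binocular(),
                                    sigma_observer = 0.06,
                                    sigma_location = 0,
                                    lambda = 0, gamma = 0.5) {
  needed <- c("condition", "visual_field", "measure", "intercept", "slope")
  if (!all(needed %in% names(lines))) {
    abort("`lines` must have columns condition, visual_field, measure, intercept, slope.",
          class = "acuityfields_invalid_model")
  }
  if (lambda < 0 || lambda > 0.1) {
    abort("`lambda` must lie in [0, 0.1].", class = "acuityfields_invalid_model")
  }
  model <- structure(
    list(lines = tibble::as_tibble(lines), sigma_observer = sigma_observer,
         sigma_location = sigma_location, lambda = lambda, gamma = gamma),
    class = "pf_model"
  )
  # the 51% cutoff must lie above the 75% threshold everywhere on [0, 90]
  for (cond in unique(lines$condition)) {
    for (vf in c("upper", "lower", "horizontal")) {
      tl <- true_lines_at(model, c(0, 90), vf, cond)
      if (any(tl$cutoff_log10 <= tl$threshold_log10)) {
        abort(sprintf("Cutoff line must exceed threshold line for %s/%s over [0, 90].",
                      vf, cond),
              class = "acuityfields_invalid_model")
      }
    }
  }
  model
}

#' @method print pf_model
#' @export
print.pf_model <- function(x, ...) {
  cat("<pf_model>\n")
  cat(sprintf("  sigma_observer = %g, sigma_location = %g, lambda = %g, gamma = %g\n",
              x$sigma_observer, x$sigma_location, x$lambda, x$gamma))
  print(x$lines)
  invisible(x)
}

#' Evaluate the ground-truth threshold and cutoff lines
#'
#' Returns the true log10-cpd threshold and cutoff at given angular distances
#' from the vertical meridian. On the horizontal meridian (distance 90, where
#' the upper- and lower-VF lines meet but do not exactly agree) the mean of
#' the two VF lines is used.
#'
#' @param model A [performance_field_model()].
#' @param angular_distance Angular distance(s) from the VM, degrees in
#'   \[0, 90\].
#' @param visual_field `"upper"`, `"lower"`, or `"horizontal"` (recycled).
#' @param condition Viewing condition present in the model's line table.
#' @param u Observer (plus any location) intercept offset, log10 cpd.
#'
#' @return A tibble with columns `threshold_log10` and `cutoff_log10`.
#' @examples
#' m <- performance_field_model()
#' true_lines_at(m, 0, "upper", "binocular")   # threshold 0.7083
#' @export
true_lines_at <- function(model, angular_distance, visual_field,
                          condition = "binocular", u = 0) {
  stopifnot(inherits(model, "pf_model"))
  if (any(angular_distance < 0 | angular_distance > 90)) {
    abort("`angular_distance` must lie in [0, 90].",
          class = "acuityfields_invalid_model")
  }
  n <- max(length(angular_distance), length(visual_field), length(u))
  d <- rep_len(angular_distance, n)
  vf <- rep_len(visual_field, n)
  u <- rep_len(u, n)
  line <- function(measure, field) {
    row <- model$lines[model$lines$condition == condition &
                         model$lines$visual_field == field &
                         model$lines$measure == measure, ]
    if (nrow(row) != 1) {
      abort(sprintf("Model has no unique %s line for %s/%s.",
                    measure, field, condition),
            class = "acuityfields_invalid_model")
    }
    list(a = row$intercept, b = row$slope)
  }
  value <- function(measure) {
    up <- line(measure, "upper")
    lo <- line(measure, "lower")
    v_up <- up$a + up$b * d
    v_lo <- lo$a + lo$b * d
    ifelse(vf == "horizontal", (v_up + v_lo) / 2,
           ifelse(vf == "upper", v_up, v_lo))
  }
  tibble::tibble(
    threshold_log10 = value("threshold") + u,
    cutoff_log10 = value("cutoff") + u
  )
}

#' Psychometric parameters reproducing given threshold and cutoff
#'
#' Inverts the criterion definitions: finds the cumulative-normal parameters
#' (alpha, beta) for which the 75%-correct point falls exactly at
#' `threshold_log10` and the 51%-correct point at `cutoff_log10`, given the
#' asymptotes. With `q(p) = (p - gamma) / (1 - gamma - lambda)`,
#' `beta = (qnorm(q(0.75)) - qnorm(q(0.51))) / (cutoff - threshold)` and
#' alpha is placed so that [invert_performance()] at 0.75 returns the
#' threshold exactly.
#'
#' @param threshold_log10,cutoff_log10 Criterion locations, log10 cpd
#'   (vectorised); the cutoff must exceed the threshold.
#' @param lambda Lapse rate; must be below 0.24 so both criteria are
#'   attainable.
#' @param gamma Guess rate.
#'
#' @return A tibble with columns `alpha`, `beta`, `gamma`, `lambda`.
#' @examples
#' params_from_truth(0.7503, 0.8696)  # beta ~ 17.2
#' @export
params_from_truth <- function(threshold_log10, cutoff_log10,
                              lambda = 0, gamma = 0.5) {
  if (any(cutoff_log10 <= threshold_log10)) {
    abort("`cutoff_log10` must be strictly greater than `threshold_log10`.",
          class = "acuityfields_invalid_model")
  }
  if (lambda >= 0.24) {
    abort("`lambda` must be below 0.24 so the 75% criterion is attainable.",
          class = "acuityfields_invalid_model")
  }
  q <- function(p) (p - gamma) / (1 - gamma - lambda)
  beta <- (qnorm(q(0.75)) - qnorm(q(0.51))) / (cutoff_log10 - threshold_log10)
  alpha <- threshold_log10 + qnorm(q(0.75)) / beta
  tibble::tibble(alpha = alpha, beta = beta, gamma = gamma, lambda = lambda)
}

#' Draw simulated observers
#'
#' Observer intercepts `u_i` are i.i.d. normal with SD `sigma_observer`. By
#' default the draws are then centred to exact zero mean, so the simulated
#' cohort's mean threshold/cutoff lines coincide with the model's line table
#' and recovery analyses measure pipeline error rather than cohort sampling
#' error; set `center = FALSE` for strictly i.i.d. draws.
#'
#' @param model A [performance_field_model()].
#' @param n_observers Number of observers.
#' @param seed Integer seed for the observer substream.
#' @param center Centre the draws to exact zero mean (default `TRUE`).
#'
#' @return A tibble with `observer_id` and `u_i` (log10 cpd).
#' @export
draw_observers <- function(model, n_observers, seed = 1, center = TRUE) {
  stopifnot(n_observers >= 1)
  set.seed(derive_seed(seed, 0L, 0L))
  u <- rnorm(n_observers, 0, model$sigma_observer)
  if (center && n_observers > 1 && model$sigma_observer > 0) {
    u <- u - mean(u)
  }
  tibble::tibble(
    observer_id = sprintf("obs%02d", seq_len(n_observers)),
    u_i = u
  )
}

# Deterministic 31-bit substream seed from (master seed, observer, stream).
derive_seed <- function(seed, i, j = 0L) {
  s <- (abs(as.numeric(seed)) %% 2147483647) * 48271 + i * 75353 + j * 10007
  as.integer(s %% 2147483647L) + 1L
}
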