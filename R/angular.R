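#' Random-intercept linear model of SF estimates on angular distance
#'
#' Fits the linear mixed-effects model used to quantify how log10 SF
#' estimates change with the angular distance from the vertical meridian,
#' with a random intercept per observer (estimated by maximum likelihood, not
#' REML, so fixed effects on balanced designs coincide with ordinary least
#' squares).
#'
#' Predictors are built from `predictors`:
#' * `"angular_distance"` - always included (degrees, 0-90).
#' * `"visual_field"` - a +-0.5 contrast (`upper = -0.5`, `lower = +0.5`).
#'   The distance main effect is then the VF-averaged slope, and per-VF lines
#'   are main effect -/+ half the interaction. Horizontal-meridian rows
#'   (distance 90) belong to both VFs and are duplicated into each.
#' * `"condition"` - a +-0.5 contrast (`monocular = -0.5`,
#'   `binocular = +0.5`).
#'
#' When `"visual_field"` is not a predictor, estimates are first averaged
#' across visual fields within observer x condition x distance; likewise for
#' `"condition"` when several conditions are present.
#'
#' All included predictors interact (full factorial fixed effects).
#'
#' @param estimates A `pf_estimates` table from [estimate_locations()].
#' @param response `"threshold"`, `"cutoff"`, or `"max_slope"`; modelled on
#'   the log10 scale.
#' @param predictors Character vector, a subset of
#'   `c("angular_distance", "visual_field", "condition")`.
#'
#' @return An object of class `pf_angular_fit` with elements `model` (the
#'   lme4 fit), `coefficients` (tidy fixed effects with Wald 95% CIs),
#'   `lines` (derived intercept/slope per VF and/or condition group),
#'   `sigma_observer`, `sigma_residual`, `data`, `response`, `predictors`.
#' @examples
#' \donttest{
#' trials <- simulate_experiment(
#'   n_observers = 4,
#'   schedule = schedule_blocks(n_sessions = 1, blocks_per_session = 7))
#' est <- estimate_locations(collapse_hemifields(trials))
#' fit <- fit_angular_model(est, "threshold",
#'                          c("angular_distance", "visual_field"))
#' fit$lines
#' }
#' @export
fit_angular_model <- function(estimates,
                              response = c("threshold", "cutoff", "max_slope"),
                              predictors = "angular_distance") {
  response <- match.arg(response)
  bad <- setdiff(predictors, c("angular_distance", "visual_field", "condition"))
  if (length(bad) > 0) {
    abort(paste0("Unknown predictor(s): ", paste(bad, collapse = ", ")))
  }
  ycol <- c(threshold = "threshold_log10", cutoff = "cutoff_log10",
            max_slope = "max_slope_log10")[[response]]
  d <- tibble::as_tibble(estimates) %>%
    dplyr::filter(!.data$degenerate, !is.na(.data[[ycol]])) %>%
    dplyr::mutate(y = .data[[ycol]])
  if (dplyr::n_distinct(d$observer_id) < 2) {
    abort("At least 2 observers are required for the random-intercept model.")
  }
  use_vf <- "visual_field" %in% predictors
  use_cond <- "condition" %in% predictors

  if (use_vf) {
    hm <- dplyr::filter(d, .data$visual_field == "horizontal")
    d <- dplyr::bind_rows(
      dplyr::filter(d, .data$visual_field != "horizontal"),
      dplyr::mutate(hm, visual_field = "upper"),
      dplyr::mutate(hm, visual_field = "lower")
    ) %>%
      dplyr::mutate(vf_code = ifelse(.data$visual_field == "lower", 0.5, -0.5))
  } else {
    d <- d %>%
      dplyr::group_by(.data$observer_id, .data$condition,
                      .data$angular_distance_deg) %>%
      dplyr::summarise(y = mean(.data$y), .groups = "drop")
  }
  if (use_cond) {
    d <- dplyr::mutate(d, cond_code = ifelse(.data$condition == "binocular",
                                             0.5, -0.5))
  } else if (dplyr::n_distinct(d$condition) > 1) {
    grp <- c("observer_id", "angular_distance_deg",
             if (use_vf) c("visual_field", "vf_code"))
    d <- d %>%
      dplyr::group_by(dplyr::across(dplyr::all_of(grp))) %>%
      dplyr::summarise(y = mean(.data$y), .groups = "drop")
  }

  terms <- c("angular_distance_deg", if (use_vf) "vf_code",
             if (use_cond) "cond_code")
  fixed <- paste(terms, collapse = " * ")
  X <- model.matrix(as.formula(paste("~", fixed)), d)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("Design is rank deficient; aliased term(s): ",
                 paste(aliased, collapse = ", ")),
          class = "acuityfields_rank_deficient")
  }
  # Data that interpolate exactly (zero residual once observer intercepts are
  # accounted for) make the ML mixed-model likelihood unbounded and the
  # optimiser unreliable. On these balanced designs the fixed effects equal
  # OLS for any variance ratio, so fall back to least squares there.
  ols_sat <- stats::lm(as.formula(paste("y ~", fixed, "+ observer_id")),
                       data = d)
  exact_fit <- sigma(ols_sat) < 1e-10 + 1e-8 * sd(d$y)
  if (exact_fit) {
    fit <- stats::lm(as.formula(paste("y ~", fixed)), data = d)
    est <- stats::coef(fit)
    obs_dev <- tapply(stats::resid(fit), d$observer_id, mean)
    sigma_obs <- if (length(obs_dev) > 1) sd(obs_dev) else 0
    sigma_res <- sigma(ols_sat)
  } else {
    fml <- as.formula(paste("y ~", fixed, "+ (1 | observer_id)"))
    fit <- lme4::lmer(fml, data = d, REML = FALSE)
    est <- lme4::fixef(fit)
    vc <- as.data.frame(lme4::VarCorr(fit))
    sigma_obs <- vc$sdcor[vc$grp == "observer_id"]
    sigma_res <- sigma(fit)
  }
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- qnorm(0.975)
  coefs <- tibble::tibble(
    term = names(est), estimate = unname(est), std_error = unname(se),
    statistic = unname(est / se),
    conf_low = unname(est - z * se), conf_high = unname(est + z * se)
  )

  groups <- tidyr::expand_grid(
    visual_field = if (use_vf) c("upper", "lower") else "average",
    condition = if (use_cond) c("monocular", "binocular") else "all"
  )
  line_of <- function(vf, cond) {
    nd <- tibble::tibble(angular_distance_deg = c(0, 1))
    if (use_vf) nd$vf_code <- ifelse(vf == "lower", 0.5, -0.5)
    if (use_cond) nd$cond_code <- ifelse(cond == "binocular", 0.5, -0.5)
    Xn <- model.matrix(as.formula(paste("~", fixed)), nd)
    v <- unname(drop(Xn %*% est))
    tibble::tibble(intercept = v[1], slope = v[2] - v[1])
  }
  lines <- dplyr::bind_cols(
    groups,
    purrr::map2_dfr(groups$visual_field, groups$condition, line_of)
  )

  structure(
    list(model = fit, coefficients = coefs, lines = lines,
         sigma_observer = sigma_obs,
         sigma_residual = sigma_res,
         exact_fit = exact_fit,
         data = d, response = response, predictors = predictors,
         n_observers = dplyr::n_distinct(d$observer_id)),
    class = "pf_angular_fit"
  )
}

#' @method print pf_angular_fit
#' @export
print.pf_angular_fit <- function(x, ...) {
  cat(sprintf("<pf_angular_fit> log10 %s ~ %s + (1 | observer)\n",
              x$response, paste(x$predictors, collapse = " * ")))
  cat(sprintf("  %d observations, %d observers; sigma_obs = %.4f, sigma_res = %.4f\n",
              nrow(x$data), x$n_observers, x$sigma_observer, x$sigma_residual))
  cat("Derived lines (log10 cpd vs angular distance):\n")
  print(x$lines)
  invisible(x)
}

#' @export
tidy.pf_angular_fit <- function(x, ...) {
  x$coefficients
}

#' @export
glance.pf_angular_fit <- function(x, ...) {
  tibble::tibble(
    sigma_observer = x$sigma_observer,
    sigma_residual = x$sigma_residual,
    logLik = as.numeric(logLik(x$model)),
    AIC = AIC(x$model),
    nobs = nrow(x$data),
    n_observers = x$n_observers
  )
}
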