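#' Cumulative-normal psychometric function for SF discrimination
#'
#' Probability of a correct response as a function of stimulus spatial
#' frequency. Accuracy decreases with SF, so the model is a decreasing
#' cumulative normal of log10 SF:
#' `f(sf) = gamma + (1 - gamma - lambda) * pnorm(beta * (alpha - log10(sf)))`.
#' (Equivalently, an increasing cumulative normal fitted on the flipped
#' log-SF axis.)
#'
#' @param sf_cpd Spatial frequency in cycles per degree (> 0, vectorised).
#' @param alpha Location parameter, log10 cpd.
#' @param beta Slope, per log10 cpd (> 0).
#' @param gamma Guess rate (lower asymptote); 0.5 for 2AFC.
#' @param lambda Lapse rate (upper-asymptote deficit).
#'
#' @return Probabilities in `[gamma, 1 - lambda]`.
#' @examples
#' psychometric_probability(10^0.75, alpha = 0.75, beta = 17)  # 0.75
#' @export
psychometric_probability <- function(sf_cpd, alpha, beta, gamma = 0.5,
                                     lambda = 0) {
  if (any(sf_cpd <= 0)) {
    abort("`sf_cpd` must be positive.", class = "acuityfields_domain_error")
  }
  gamma + (1 - gamma - lambda) * pnorm(beta * (alpha - log10(sf_cpd)))
}

#' Binomial negative log-likelihood of a psychometric function
#'
#' @param aggregates A data frame with one row per spatial-frequency level:
#'   columns `sf_cpd`, `n` (trials), and `n_correct`.
#' @inheritParams psychometric_probability
#' @param clip Probabilities are clipped to `[clip, 1 - clip]` so the
#'   likelihood stays finite at degenerate parameter values.
#'
#' @return The negative log-likelihood (a nonnegative number).
#' @export
negative_log_likelihood <- function(aggregates, alpha, beta, gamma = 0.5,
                                    lambda = 0, clip = 1e-9) {
  stopifnot(all(aggregates$n_correct >= 0),
            all(aggregates$n_correct <= aggregates$n))
  p <- psychometric_probability(aggregates$sf_cpd, alpha, beta, gamma, lambda)
  p <- pmin(pmax(p, clip), 1 - clip)
  -sum(aggregates$n_correct * log(p) +
         (aggregates$n - aggregates$n_correct) * log(1 - p))
}

#' Control options for psychometric fitting
#'
#' Defines the parameter bounds and the deterministic multi-start grid used
#' by [fit_psychometric()]. Starts are ranked by their likelihood and local
#' optimisation is run from the `top_starts` best, which gives the same
#' optimum as optimising from every start at a fraction of the cost.
#'
#' @param alpha_bounds Bounds on alpha, log10 cpd (defaults span 1-24 cpd).
#' @param beta_bounds Bounds on beta (per log10 cpd).
#' @param lambda_bounds Bounds on the lapse rate.
#' @param n_alpha_starts Number of alpha starting values (quantiles of the
#'   observed log10 SFs).
#' @param beta_starts,lambda_starts Starting values for beta and lambda.
#' @param top_starts Number of best-ranked starts to optimise from.
#' @param gamma Fixed guess rate.
#' @param tie_tol Likelihood plateaus narrower than this are treated as ties
#'   and resolved by smallest lambda, then smallest beta.
#'
#' @return A list of class `pf_fit_control`.
#' @export
fit_control <- function(alpha_bounds = c(0, log10(24)),
                        beta_bounds = c(0.5, 100),
                        lambda_bounds = c(0, 0.1),
                        n_alpha_starts = 9,
                        beta_starts = c(2, 8, 32),
                        lambda_starts = c(0, 0.05),
                        top_starts = 5,
                        gamma = 0.5,
                        tie_tol = 1e-6) {
  structure(
    list(alpha_bounds = alpha_bounds, beta_bounds = beta_bounds,
         lambda_bounds = lambda_bounds, n_alpha_starts = n_alpha_starts,
         beta_starts = beta_starts, lambda_starts = lambda_starts,
         top_starts = top_starts, gamma = gamma, tie_tol = tie_tol),
    class = "pf_fit_control"
  )
}

# Reduced-start control used for the cheap between-block recentering fits.
fast_fit_control <- function() {
  fit_control(n_alpha_starts = 5, beta_starts = c(4, 16), lambda_starts = 0,
              top_starts = 2)
}

#' Fit a psychometric function by maximum likelihood
#'
#' Fits the decreasing cumulative normal of [psychometric_probability()] to
#' binary trials at one location. The guess rate is fixed at `gamma`; alpha,
#' beta, and the lapse rate are estimated within bounds by bounded
#' quasi-Newton optimisation from a deterministic multi-start grid, so fits
#' are reproducible without a seed. Data that are all-correct or
#' all-incorrect (or with fewer than two SF levels) cannot constrain the
#' curve and yield a fit flagged `degenerate` rather than an error.
#'
#' @param trials A data frame of trials with columns `sf_cpd` and `correct`
#'   (0/1), or pre-aggregated with columns `sf_cpd`, `n`, `n_correct`.
#' @param control A [fit_control()] list.
#'
#' @return An object of class `pf_fit`: `params` (tibble with alpha, beta,
#'   gamma, lambda), `nll`, `converged`, `degenerate`, `n_trials`, and the
#'   per-SF `aggregates`.
#' @examples
#' sf <- rep(build_sf_grid(7)$values_cpd, each = 40)
#' set.seed(1)
#' correct <- simulate_response(sf, alpha = 0.85, beta = 15)
#' fit <- fit_psychometric(data.frame(sf_cpd = sf, correct = correct))
#' tidy(fit)
#' @export
fit_psychometric <- function(trials, control = fit_control()) {
  agg <- aggregate_trials(trials)
  n_trials <- sum(agg$n)
  k_tot <- sum(agg$n_correct)
  degenerate <- nrow(agg) < 2 || k_tot == 0 || k_tot == n_trials
  if (degenerate) {
    return(new_pf_fit(params = tibble::tibble(alpha = NA_real_, beta = NA_real_,
                                              gamma = control$gamma,
                                              lambda = NA_real_),
                      nll = NA_real_, converged = FALSE, degenerate = TRUE,
                      n_trials = n_trials, aggregates = agg))
  }
  x <- log10(agg$sf_cpd)
  n <- agg$n
  k <- agg$n_correct
  gamma <- control$gamma
  nll_fn <- function(par) {
    p <- gamma + (1 - gamma - par[3]) * pnorm(par[2] * (par[1] - x))
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    v <- -sum(k * log(p) + (n - k) * log(1 - p))
    if (!is.finite(v)) v <- 1e12
    v
  }
  lower <- c(control$alpha_bounds[1], control$beta_bounds[1],
             control$lambda_bounds[1])
  upper <- c(control$alpha_bounds[2], control$beta_bounds[2],
             control$lambda_bounds[2])
  probs <- seq(0.1, 0.9, length.out = control$n_alpha_starts)
  a0 <- unique(pmin(pmax(quantile(x, probs, names = FALSE, type = 7),
                         lower[1]), upper[1]))
  starts <- as.matrix(expand.grid(alpha = a0,
                                  beta = pmin(pmax(control$beta_starts,
                                                   lower[2]), upper[2]),
                                  lambda = pmin(pmax(control$lambda_starts,
                                                     lower[3]), upper[3])))
  start_nll <- apply(starts, 1, nll_fn)
  keep <- order(start_nll)[seq_len(min(control$top_starts, nrow(starts)))]
  fits <- lapply(keep, function(i) {
    nlminb(starts[i, ], nll_fn, lower = lower, upper = upper,
           control = list(iter.max = 300, eval.max = 500))
  })
  nlls <- vapply(fits, function(f) f$objective, numeric(1))
  best_nll <- min(nlls)
  tied <- which(nlls <= best_nll + control$tie_tol)
  # resolve likelihood plateaus: prefer the simplest curve
  pars <- t(vapply(fits[tied], function(f) f$par, numeric(3)))
  pick <- tied[order(pars[, 3], pars[, 2])[1]]
  best <- fits[[pick]]
  par <- unname(best$par)
  new_pf_fit(
    params = tibble::tibble(alpha = par[1], beta = par[2],
                            gamma = gamma, lambda = par[3]),
    nll = best$objective,
    converged = best$convergence == 0,
    degenerate = FALSE,
    n_trials = n_trials,
    aggregates = agg
  )
}

aggregate_trials <- function(trials) {
  if (all(c("n", "n_correct") %in% names(trials))) {
    agg <- tibble::as_tibble(trials)[c("sf_cpd", "n", "n_correct")]
  } else {
    stopifnot(all(c("sf_cpd", "correct") %in% names(trials)))
    agg <- tibble::as_tibble(trials) %>%
      dplyr::group_by(.data$sf_cpd) %>%
      dplyr::summarise(n = dplyr::n(), n_correct = sum(.data$correct),
                       .groups = "drop")
  }
  dplyr::arrange(agg, .data$sf_cpd)
}

new_pf_fit <- function(params, nll, converged, degenerate, n_trials,
                       aggregates) {
  structure(
    list(params = params, nll = nll, converged = converged,
         degenerate = degenerate, n_trials = n_trials,
         aggregates = aggregates),
    class = "pf_fit"
  )
}

#' @method print pf_fit
#' @export
print.pf_fit <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<pf_fit> degenerate (%d trials)\n", x$n_trials))
  } else {
    p <- x$params
    cat(sprintf(
      "<pf_fit> alpha = %.4f, beta = %.2f, lambda = %.4f (gamma fixed %.2f)\n",
      p$alpha, p$beta, p$lambda, p$gamma))
    cat(sprintf("  nll = %.3f over %d trials (%d SF levels), converged: %s\n",
                x$nll, x$n_trials, nrow(x$aggregates), x$converged))
  }
  invisible(x)
}

#' Invert the psychometric function at a performance criterion
#'
#' Closed-form log10 SF at which performance equals `p`:
#' `alpha - qnorm((p - gamma) / (1 - gamma - lambda)) / beta`.
#' `p = 0.75` gives the SF threshold and `p = 0.51` the SF cutoff.
#'
#' @param p Target proportion correct, strictly between `gamma` and
#'   `1 - lambda`.
#' @inheritParams psychometric_probability
#'
#' @return log10 SF (log10 cpd), vectorised over the parameters.
#' @examples
#' invert_performance(0.75, alpha = 0.75, beta = 17)  # alpha when lambda = 0
#' @export
invert_performance <- function(p, alpha, beta, gamma = 0.5, lambda = 0) {
  if (any(p <= gamma | p >= 1 - lambda)) {
    abort("Criterion `p` must lie strictly between `gamma` and `1 - lambda`.",
          class = "acuityfields_criterion_unattainable")
  }
  alpha - qnorm((p - gamma) / (1 - gamma - lambda)) / beta
}

#' Maximum slope of the psychometric function
#'
#' Converts the cumulative-normal slope parameter into the maximum slope of
#' the fitted curve (its steepest derivative in probability per log10 cpd):
#' `beta_prime = (1 - gamma) * beta / sqrt(2 * pi)`.
#'
#' @param beta Slope parameter (> 0).
#' @param gamma Guess rate.
#'
#' @return The maximum slope `beta_prime`.
#' @examples
#' max_slope(1)  # 0.5 / sqrt(2 * pi)
#' @export
max_slope <- function(beta, gamma = 0.5) {
  stopifnot(all(beta > 0))
  (1 - gamma) * beta / sqrt(2 * pi)
}

#' Collapse right-hemifield trials onto their left-hemifield mirrors
#'
#' Maps every right-hemifield polar angle `phi` to `180 - phi` (mod 360), the
#' horizontally corresponding left-hemifield position, pooling trials across
#' hemifields before refitting. Vertical-meridian and left-hemifield trials
#' are unchanged; the operation conserves trial counts and is idempotent.
#'
#' @param trials A trial table with a `polar_angle_deg` column; derived
#'   geometry columns, if present, are recomputed.
#'
#' @return The trial table with collapsed polar angles.
#' @examples
#' collapse_hemifields(data.frame(polar_angle_deg = c(0, 45, 300)))
#' @export
collapse_hemifields <- function(trials) {
  stopifnot("polar_angle_deg" %in% names(trials))
  phi <- trials$polar_angle_deg %% 360
  right <- location_info(phi)$hemifield == "right"
  phi[right] <- (180 - phi[right]) %% 360
  trials$polar_angle_deg <- phi
  geo_cols <- c("angular_distance_deg", "visual_field", "hemifield")
  present <- intersect(geo_cols, names(trials))
  if (length(present) > 0) {
    info <- location_info(phi)
    for (cl in present) trials[[cl]] <- info[[cl]]
  }
  trials
}

#' Threshold, cutoff, and maximum slope for one location's trials
#'
#' Fits the psychometric function to the trials of a single (collapsed)
#' location and derives the 75%-correct threshold, the 51%-correct cutoff,
#' and the maximum slope, each on both the linear (cpd) and log10 scales.
#'
#' @param trials Trials at one location (columns `sf_cpd`, `correct`).
#' @param control A [fit_control()] list.
#'
#' @return A one-row tibble of estimates plus fit diagnostics; estimates are
#'   `NA` when the fit is degenerate.
#' @export
estimate_location <- function(trials, control = fit_control()) {
  fit <- fit_psychometric(trials, control)
  if (fit$degenerate) {
    est <- tibble::tibble(
      threshold_log10 = NA_real_, threshold_cpd = NA_real_,
      cutoff_log10 = NA_real_, cutoff_cpd = NA_real_,
      max_slope = NA_real_, max_slope_log10 = NA_real_
    )
  } else {
    p <- fit$params
    thr <- invert_performance(0.75, p$alpha, p$beta, p$gamma, p$lambda)
    cut <- invert_performance(0.51, p$alpha, p$beta, p$gamma, p$lambda)
    bp <- max_slope(p$beta, p$gamma)
    est <- tibble::tibble(
      threshold_log10 = thr, threshold_cpd = 10^thr,
      cutoff_log10 = cut, cutoff_cpd = 10^cut,
      max_slope = bp, max_slope_log10 = log10(bp)
    )
  }
  dplyr::bind_cols(
    est,
    tibble::tibble(
      alpha = fit$params$alpha, beta = fit$params$beta,
      gamma = fit$params$gamma, lambda = fit$params$lambda,
      nll = fit$nll, converged = fit$converged, degenerate = fit$degenerate,
      n_trials = fit$n_trials
    )
  )
}

#' Per-location psychometric estimates for a whole trial table
#'
#' Splits a (typically hemifield-collapsed) trial table by observer,
#' condition, and location, fits each group with [fit_psychometric()], and
#' returns one row of estimates per group.
#'
#' @param trials A trial table with columns `observer_id`, `condition`,
#'   `polar_angle_deg`, `sf_cpd`, `correct` (and optionally
#'   `eccentricity_deg`).
#' @param control A [fit_control()] list.
#'
#' @return A tibble of class `pf_estimates`: one row per observer x condition
#'   x location with the location geometry, criterion estimates in cpd and
#'   log10 cpd, the maximum slope, and fit diagnostics.
#' @export
estimate_locations <- function(trials, control = fit_control()) {
  needed <- c("observer_id", "condition", "polar_angle_deg", "sf_cpd", "correct")
  missing_cols <- setdiff(needed, names(trials))
  if (length(missing_cols) > 0) {
    abort(paste0("Trial table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "acuityfields_format_error")
  }
  ecc <- if ("eccentricity_deg" %in% names(trials)) trials$eccentricity_deg[1] else 10
  out <- tibble::as_tibble(trials) %>%
    dplyr::group_by(.data$observer_id, .data$condition, .data$polar_angle_deg) %>%
    dplyr::group_modify(~ estimate_location(.x, control)) %>%
    dplyr::ungroup()
  out <- dplyr::bind_cols(
    out[c("observer_id", "condition")],
    location_info(out$polar_angle_deg, ecc),
    out[setdiff(names(out), c("observer_id", "condition", "polar_angle_deg"))]
  )
  class(out) <- c("pf_estimates", class(out))
  out
}
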