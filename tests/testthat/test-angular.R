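test_that("noise-free line data are recovered exactly", {
  est <- make_line_estimates(0.7083, 0.00194, 0.7922, 0.00115,
                             n_obs = 3, obs_sd = 0.05)
  fit <- suppressWarnings(suppressMessages(
    fit_angular_model(est, "threshold", c("angular_distance", "visual_field"))
  ))
  lines <- fit$lines
  up <- lines[lines$visual_field == "upper", ]
  lo <- lines[lines$visual_field == "lower", ]
  expect_equal(up$intercept, 0.7083, tolerance = 1e-8)
  expect_equal(up$slope, 0.00194, tolerance = 1e-8)
  expect_equal(lo$intercept, 0.7922, tolerance = 1e-8)
  expect_equal(lo$slope, 0.00115, tolerance = 1e-8)

  # the VF-averaged model recovers the mean line
  avg <- suppressWarnings(suppressMessages(
    fit_angular_model(est, "threshold", "angular_distance")
  ))
  expect_equal(avg$lines$intercept, mean(c(0.7083, 0.7922)), tolerance = 1e-8)
  expect_equal(avg$lines$slope, mean(c(0.00194, 0.00115)), tolerance = 1e-8)
})

test_that("fixed effects on balanced data equal ordinary least squares", {
  est <- make_line_estimates(0.71, 0.0019, 0.79, 0.0012, n_obs = 8,
                             noise_sd = 0.02, obs_sd = 0.05, seed = 4)
  fit <- fit_angular_model(est, "threshold",
                           c("angular_distance", "visual_field"))
  ols <- stats::lm(y ~ angular_distance_deg * vf_code, data = fit$data)
  expect_equal(unname(lme4::fixef(fit$model)), unname(stats::coef(ols)),
               tolerance = 1e-6)
})

test_that("the VF contrast is +-0.5 so lines are main effect -/+ half interaction", {
  est <- make_line_estimates(0.70, 0.0020, 0.80, 0.0010, n_obs = 6,
                             noise_sd = 0.01, obs_sd = 0.04, seed = 6)
  fit <- fit_angular_model(est, "threshold",
                           c("angular_distance", "visual_field"))
  b <- lme4::fixef(fit$model)
  up <- fit$lines[fit$lines$visual_field == "upper", ]
  expect_equal(up$intercept, unname(b["(Intercept)"] - 0.5 * b["vf_code"]),
               tolerance = 1e-10)
  expect_equal(up$slope,
               unname(b["angular_distance_deg"] -
                        0.5 * b["angular_distance_deg:vf_code"]),
               tolerance = 1e-10)
})

test_that("horizontal-meridian estimates enter both visual-field groups", {
  est <- make_line_estimates(0.71, 0.0019, 0.79, 0.0012, n_obs = 4,
                             noise_sd = 0.01, obs_sd = 0, seed = 2)
  # relabel distance-90 rows as 'horizontal' (one row per observer),
  # as produced by the collapsed pipeline
  hm <- est[est$angular_distance_deg == 90 & est$visual_field == "upper", ]
  hm$visual_field <- "horizontal"
  est2 <- rbind(est[est$angular_distance_deg < 90, ], hm)
  fit <- fit_angular_model(est2, "threshold",
                           c("angular_distance", "visual_field"))
  d <- fit$data
  expect_equal(sum(d$angular_distance_deg == 90),
               2 * nrow(hm))
  expect_setequal(unique(d$visual_field), c("upper", "lower"))
})

test_that("rank-deficient designs raise an informative error", {
  est <- make_line_estimates(0.71, 0.0019, 0.79, 0.0012, n_obs = 4,
                             noise_sd = 0.01, seed = 3)
  only_upper <- est[est$visual_field == "upper", ]
  err <- expect_error(
    fit_angular_model(only_upper, "threshold",
                      c("angular_distance", "visual_field")),
    class = "acuityfields_rank_deficient"
  )
  expect_match(conditionMessage(err), "vf_code")
  expect_error(fit_angular_model(est[est$observer_id == "o01", ], "threshold"),
               "2 observers")
})

test_that("pipeline recovery is unbiased across master seeds (reduced design)", {
  # 6 observers, one session per seed: a scaled-down replicate study
  sched <- small_schedule()
  rec <- purrr::map_dfr(1:20, function(s) {
    trials <- simulate_experiment(n_observers = 6, schedule = sched, seed = s)
    est <- estimate_locations(collapse_hemifields(trials))
    fit <- fit_angular_model(est, "threshold",
                             c("angular_distance", "visual_field"))
    avg <- fit_angular_model(est, "threshold", "angular_distance")
    up <- fit$lines[fit$lines$visual_field == "upper", ]
    tibble::tibble(slope_up = up$slope, int_avg = avg$lines$intercept)
  })
  mc_se <- function(x) sd(x) / sqrt(length(x))
  # the generator feeds the VF-averaged HM truth into both VF groups, so
  # the expected upper slope is the implied regression value, not the raw
  # generating slope
  implied <- implied_vf_line(0.7083, 0.00194, 0.7922, 0.00115, "upper")
  expect_lt(abs(mean(rec$slope_up) - implied$slope), 2 * mc_se(rec$slope_up))
  expect_lt(abs(mean(rec$int_avg) - mean(c(0.7083, 0.7922))),
            2 * mc_se(rec$int_avg))
})

test_that("tidy and glance expose coefficients and variance components", {
  est <- make_line_estimates(0.71, 0.0019, 0.79, 0.0012, n_obs = 5,
                             noise_sd = 0.015, obs_sd = 0.06, seed = 8)
  fit <- fit_angular_model(est, "threshold",
                           c("angular_distance", "visual_field"))
  td <- tidy(fit)
  expect_setequal(td$term, c("(Intercept)", "angular_distance_deg", "vf_code",
                             "angular_distance_deg:vf_code"))
  expect_true(all(td$conf_low <= td$estimate & td$estimate <= td$conf_high))
  gl <- glance(fit)
  expect_equal(gl$n_observers, 5)
  expect_gt(gl$sigma_observer, 0)
})
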