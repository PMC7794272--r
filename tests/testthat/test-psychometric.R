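test_that("psychometric probability has the right criteria and asymptotes", {
  # at sf = 10^alpha with no lapse, performance is exactly 75%
  expect_equal(psychometric_probability(10^0.75, 0.75, 17), 0.75)
  # asymptotes: 1 - lambda at very low SF, gamma at very high SF
  expect_equal(psychometric_probability(1e-6, 0.75, 17, lambda = 0.03), 0.97,
               tolerance = 1e-9)
  expect_equal(psychometric_probability(1e6, 0.75, 17), 0.5, tolerance = 1e-9)
  expect_error(psychometric_probability(-1, 0.75, 17),
               class = "acuityfields_domain_error")
})

test_that("psychometric probability is monotone nonincreasing in SF", {
  set.seed(11)
  sf <- sort(10^seq(0.1, 1.2, length.out = 100))
  for (i in 1:25) {
    a <- runif(1, 0.3, 1.1)
    b <- runif(1, 1, 60)
    l <- runif(1, 0, 0.1)
    p <- psychometric_probability(sf, a, b, lambda = l)
    expect_true(all(diff(p) <= 1e-12))
    expect_true(all(p >= 0.5 - 1e-12 & p <= 1 - l + 1e-12))
  }
})

test_that("binomial NLL matches hand values and is linear in counts", {
  # one correct trial where performance is at the 0.5 guess asymptote
  one <- tibble::tibble(sf_cpd = 1e6, n = 1, n_correct = 1)
  expect_equal(negative_log_likelihood(one, alpha = 0.75, beta = 17), log(2),
               tolerance = 1e-9)
  # and at the 75% point the NLL of a correct trial is -log(0.75)
  at75 <- tibble::tibble(sf_cpd = 10^0.75, n = 1, n_correct = 1)
  expect_equal(negative_log_likelihood(at75, alpha = 0.75, beta = 17),
               -log(0.75))
  agg <- tibble::tibble(sf_cpd = c(4, 6, 8), n = c(10, 10, 10),
                        n_correct = c(9, 7, 5))
  expect_equal(
    negative_log_likelihood(dplyr::mutate(agg, n = n * 2, n_correct = n_correct),
                            0.8, 12),
    # doubling n while keeping k changes the NLL; linearity means doubling both
    negative_log_likelihood(agg, 0.8, 12) +
      negative_log_likelihood(dplyr::mutate(agg, n_correct = 0), 0.8, 12)
  )
  doubled <- dplyr::mutate(agg, n = n * 2, n_correct = n_correct * 2)
  expect_equal(negative_log_likelihood(doubled, 0.8, 12),
               2 * negative_log_likelihood(agg, 0.8, 12))
})

test_that("the ML fit beats a brute-force grid oracle", {
  # 60-trial fixture simulated from known parameters
  set.seed(42)
  sf <- rep(c(3, 4.5, 6, 7.5, 9, 11), each = 10)
  correct <- simulate_response(sf, alpha = 0.82, beta = 11, lambda = 0.03)
  fix <- data.frame(sf_cpd = sf, correct = correct)
  fit <- fit_psychometric(fix)
  agg <- fit$aggregates
  oracle <- grid_nll_min(agg,
                         alphas = seq(0.3, 1.3, length.out = 201),
                         betas = seq(0.5, 60, length.out = 201),
                         lambdas = seq(0, 0.1, length.out = 21))
  expect_lte(fit$nll, oracle + 1e-8)
  # and the sample optimum is at least as good as the generating parameters
  expect_lte(fit$nll, negative_log_likelihood(agg, 0.82, 11, lambda = 0.03))
})

test_that("fitting recovers known parameters from large samples", {
  set.seed(7)
  sf <- rep(build_sf_grid(7)$values_cpd, length.out = 1e4)
  correct <- simulate_response(sf, alpha = 0.85, beta = 15, lambda = 0.02)
  fit <- fit_psychometric(data.frame(sf_cpd = sf, correct = correct))
  expect_true(fit$converged)
  expect_equal(fit$params$alpha, 0.85, tolerance = 0.015)
  expect_equal(fit$params$beta, 15, tolerance = 0.15)
})

test_that("noise-free expected counts are fitted back exactly", {
  grid <- build_sf_grid(6)$values_cpd
  p <- psychometric_probability(grid, alpha = 0.78, beta = 14, lambda = 0.01)
  agg <- tibble::tibble(sf_cpd = grid, n = 2000, n_correct = 2000 * p)
  est <- estimate_location(agg)
  expect_equal(est$alpha, 0.78, tolerance = 1e-3)
  expect_equal(est$lambda, 0.01, tolerance = 1e-3)
  expect_equal(est$threshold_log10,
               invert_performance(0.75, 0.78, 14, lambda = 0.01),
               tolerance = 1e-3)
})

test_that("degenerate data are flagged instead of raising", {
  all_right <- data.frame(sf_cpd = c(3, 3, 4, 4, 5), correct = 1)
  fit <- fit_psychometric(all_right)
  expect_true(fit$degenerate)
  expect_false(fit$converged)
  expect_true(is.na(fit$params$alpha))
  one_level <- data.frame(sf_cpd = 5, correct = c(0, 1, 1))
  expect_true(fit_psychometric(one_level)$degenerate)
  est <- estimate_location(all_right)
  expect_true(est$degenerate)
  expect_true(is.na(est$threshold_cpd))
})

test_that("threshold recovery at realistic per-location trial counts", {
  # ~620 trials per location, grid centred near the true threshold
  truth <- params_from_truth(0.7503, 0.8696)
  grid <- build_sf_grid(5.5)$values_cpd
  errs <- vapply(1:50, function(i) {
    set.seed(1000 + i)
    sf <- rep(grid, each = 41)
    correct <- simulate_response(sf, truth$alpha, truth$beta)
    fit <- fit_psychometric(data.frame(sf_cpd = sf, correct = correct))
    p <- fit$params
    invert_performance(0.75, p$alpha, p$beta, p$gamma, p$lambda) - 0.7503
  }, numeric(1))
  expect_lt(median(abs(errs)), 0.02)
})

test_that("criterion inversion is the exact inverse of the probability", {
  # closed form vs numeric root finding, and the identity property
  set.seed(5)
  for (i in 1:20) {
    a <- runif(1, 0.4, 1.1)
    b <- runif(1, 3, 40)
    l <- runif(1, 0, 0.1)
    p <- runif(1, 0.51, 1 - l - 0.01)
    x <- invert_performance(p, a, b, lambda = l)
    expect_equal(psychometric_probability(10^x, a, b, lambda = l), p,
                 tolerance = 1e-9)
    root <- uniroot(function(z) psychometric_probability(10^z, a, b, lambda = l) - p,
                    c(-2, 3), tol = 1e-12)$root
    expect_equal(x, root, tolerance = 1e-9)
  }
  # the 51% cutoff sits qnorm(0.98)/beta above alpha when lambda = 0
  z98 <- z_quantile(0.98)
  expect_equal(invert_performance(0.51, 0.75, 17.2), 0.75 + z98 / 17.2,
               tolerance = 1e-9)
  expect_error(invert_performance(0.95, 0.75, 17, lambda = 0.1),
               class = "acuityfields_criterion_unattainable")
  expect_error(invert_performance(0.5, 0.75, 17),
               class = "acuityfields_criterion_unattainable")
})

test_that("maximum slope conversion is exact and linear in beta", {
  expect_equal(max_slope(1), 0.5 / sqrt(2 * pi))
  expect_equal(max_slope(1), 0.19947, tolerance = 1e-4)
  expect_equal(max_slope(2 * 18.7), 2 * max_slope(18.7))
  # a typical fitted slope lands inside the plausible log10 range [.53, .63]
  expect_gt(log10(max_slope(18.7)), 0.5352)
  expect_lt(log10(max_slope(18.7)), 0.6218)
})

test_that("hemifield collapsing mirrors the right hemifield and is idempotent", {
  tr <- data.frame(polar_angle_deg = c(0, 45, 300, 90, 270, 135, 180),
                   sf_cpd = 5, correct = 1)
  out <- collapse_hemifields(tr)
  expect_equal(out$polar_angle_deg, c(180, 135, 240, 90, 270, 135, 180))
  expect_equal(nrow(out), nrow(tr))
  # no location remains in the right hemifield; distances are preserved
  expect_true(all(location_info(out$polar_angle_deg)$hemifield != "right"))
  expect_equal(location_info(out$polar_angle_deg)$angular_distance_deg,
               location_info(tr$polar_angle_deg)$angular_distance_deg)
  expect_identical(collapse_hemifields(out)$polar_angle_deg,
                   out$polar_angle_deg)
})

test_that("location estimates preserve criterion ordering and the lambda-0 identity", {
  run <- cached_binocular_run(1)
  est <- run$estimates
  ok <- !est$degenerate
  expect_true(all(est$cutoff_log10[ok] >= est$threshold_log10[ok]))
  expect_equal(est$threshold_cpd[ok], 10^est$threshold_log10[ok],
               tolerance = 1e-12)
  expect_equal(est$max_slope_log10[ok], log10(est$max_slope[ok]),
               tolerance = 1e-12)
  # where the fitted lapse is ~0 the threshold coincides with alpha
  zl <- ok & est$lambda < 1e-8
  expect_true(any(zl))
  expect_equal(est$threshold_log10[zl], est$alpha[zl], tolerance = 1e-6)
})
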