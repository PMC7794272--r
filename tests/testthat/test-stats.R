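make_cardinal_estimates <- function(values) {
  # values: named list observer -> c(lhm, rhm, uvm, lvm) threshold in cpd
  purrr::imap_dfr(values, function(v, obs) {
    tibble::tibble(
      observer_id = obs,
      condition = "binocular",
      polar_angle_deg = c(180, 0, 90, 270),
      angular_distance_deg = c(90, 90, 0, 0),
      visual_field = c("horizontal", "horizontal", "upper", "lower"),
      threshold_cpd = v,
      threshold_log10 = log10(v),
      degenerate = FALSE
    )
  })
}

test_that("cardinal asymmetry ratios match hand-computed group means", {
  # group means engineered to the canonical LVM 6.22 / UVM 5.28 cpd split
  est <- make_cardinal_estimates(list(
    o1 = c(7.5, 7.7, 5.00, 6.00),
    o2 = c(8.1, 7.9, 5.56, 6.44)
  ))
  asym <- cardinal_asymmetries(est, "threshold")
  expect_equal(asym$group$uvm_mean, 5.28)
  expect_equal(asym$group$lvm_mean, 6.22)
  expect_equal(asym$group$vma_ratio, 6.22 / 5.28)
  expect_equal(asym$group$hm_mean, mean(c(7.6, 8.0)))
  expect_equal(asym$group$hva_ratio,
               mean(c(7.6, 8.0)) / mean(c(5.5, 6.0)))
  expect_equal(tidy(asym)$hva_ratio, c(7.6 / 5.5, 8.0 / 6.0))
})

test_that("equal cardinal estimates give unit ratios and LHM/RHM exchange invariance", {
  est <- make_cardinal_estimates(list(o1 = c(6, 6, 6, 6), o2 = c(5, 5, 5, 5)))
  asym <- cardinal_asymmetries(est)
  expect_equal(asym$group$hva_ratio, 1)
  expect_equal(asym$group$vma_ratio, 1)

  est2 <- make_cardinal_estimates(list(o1 = c(7.2, 8.4, 5, 6)))
  swapped <- est2
  swapped$threshold_cpd[swapped$polar_angle_deg == 180] <- 8.4
  swapped$threshold_cpd[swapped$polar_angle_deg == 0] <- 7.2
  expect_equal(cardinal_asymmetries(est2)$group$hva_ratio,
               cardinal_asymmetries(swapped)$group$hva_ratio)
})

test_that("observers missing a cardinal are dropped with a warning", {
  est <- make_cardinal_estimates(list(o1 = c(7, 7, 5, 6), o2 = c(8, 8, 5, 6)))
  est <- est[!(est$observer_id == "o2" & est$polar_angle_deg == 90), ]
  expect_warning(asym <- cardinal_asymmetries(est), "o2")
  expect_equal(asym$group$n_observers, 1)
})

test_that("paired t and Cohen's d match hand computation", {
  res <- paired_t_cohen(c(2, 3, 4), c(1, 1, 1))
  expect_equal(res$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$effect_size, 2)
  # antisymmetry under swapping the pair
  rev <- paired_t_cohen(c(1, 1, 1), c(2, 3, 4))
  expect_equal(rev$statistic, -res$statistic)
  expect_equal(rev$effect_size, -res$effect_size)
  # identical vectors: degenerate, t = 0, d = 0
  same <- paired_t_cohen(c(1, 2, 3), c(1, 2, 3))
  expect_true(same$degenerate)
  expect_equal(same$statistic, 0)
  expect_equal(same$effect_size, 0)
})

test_that("pearson_r reproduces exact and oracle correlations", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x + 1)$estimate, 1)
  expect_equal(pearson_r(x, -x)$estimate, -1)
  y <- c(2.1, 1.9, 3.5, 2.8, 4.4)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- pearson_r(x, y)
  expect_equal(res$estimate, r_oracle, tolerance = 1e-12)
  t_oracle <- r_oracle * sqrt(3 / (1 - r_oracle^2))
  expect_equal(res$statistic, t_oracle, tolerance = 1e-12)
  expect_true(pearson_r(x, rep(1, 5))$degenerate)
})

test_that("repeated-measures ANOVA matches an independent decomposition", {
  set.seed(21)
  n_s <- 5
  k <- 3
  Y <- matrix(rnorm(n_s * k, sd = 0.5), n_s, k) +
    matrix(rep(c(0, 0.8, 1.5), each = n_s), n_s, k)
  long <- tibble::tibble(
    s = factor(rep(seq_len(n_s), k)),
    a = factor(rep(seq_len(k), each = n_s)),
    y = as.vector(Y)
  )
  res <- rm_anova(long, "y", "s", "a")
  oracle <- rm_decomposition(Y)
  expect_equal(res$statistic, oracle$f, tolerance = 1e-10)
  expect_equal(res$df1, oracle$df1)
  expect_equal(res$df2, oracle$df2)
  expect_equal(res$pes, oracle$pes, tolerance = 1e-10)
  expect_equal(res$epsilon, gg_epsilon_oracle(Y), tolerance = 1e-8)
  expect_equal(res$df1_gg, res$epsilon * res$df1)
  expect_equal(res$p_value_gg,
               pf(oracle$f, res$df1_gg, res$df2_gg, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("two-level factors are trivially spherical and identical cells give F = 0", {
  set.seed(22)
  long2 <- tibble::tibble(
    s = factor(rep(1:8, 2)),
    a = factor(rep(1:2, each = 8)),
    y = rnorm(16)
  )
  res2 <- rm_anova(long2, "y", "s", "a")
  expect_equal(res2$epsilon, 1)
  # partial eta squared equals t^2 / (t^2 + df) from the matching paired t
  tt <- paired_t_cohen(long2$y[long2$a == 1], long2$y[long2$a == 2])
  expect_equal(res2$pes, tt$statistic^2 / (tt$statistic^2 + tt$df),
               tolerance = 1e-10)
  expect_equal(res2$statistic, tt$statistic^2, tolerance = 1e-10)

  flat <- tibble::tibble(s = factor(rep(1:4, 3)), a = factor(rep(1:3, each = 4)),
                         y = 2)
  res3 <- rm_anova(flat, "y", "s", "a")
  expect_equal(res3$statistic, 0)
  expect_equal(res3$p_value, 1)
  expect_equal(res3$pes, 0)
})

test_that("two-factor repeated-measures ANOVA returns all within effects", {
  set.seed(23)
  d <- tidyr::expand_grid(s = factor(1:6), a = factor(1:3), b = factor(1:2))
  d$y <- rnorm(nrow(d)) + as.numeric(d$a) * 0.4 + as.numeric(d$b) * 0.2
  res <- rm_anova(d, "y", "s", c("a", "b"))
  expect_setequal(res$effect, c("a", "b", "a:b"))
  expect_true(all(res$pes >= 0 & res$pes <= 1))
  expect_true(all(res$epsilon > 0 & res$epsilon <= 1 + 1e-12))
  # missing cells are rejected
  expect_error(rm_anova(d[-1, ], "y", "s", c("a", "b")),
               class = "acuityfields_missing_cells")
})

test_that("accuracy-ratio curves are ~1 for identical locations and filter correctly", {
  # same psychometric function at all four cardinals
  set.seed(31)
  grid <- build_sf_grid(7)$values_cpd
  tr <- tidyr::expand_grid(
    observer_id = sprintf("o%02d", 1:8),
    polar_angle_deg = c(0, 90, 180, 270),
    sf_cpd = rep(grid, each = 30)
  )
  tr$correct <- simulate_response(tr$sf_cpd, alpha = 0.85, beta = 15)
  curve <- accuracy_ratio_by_sf(tr, "hva")
  expect_gt(nrow(curve), 2)
  expect_true(all(abs(curve$ratio - 1) < 0.1))
  expect_true(all(curve$n_observers <= 8))

  # the dynamic-range rule drops ceiling/chance levels
  pooled_acc <- tr %>%
    dplyr::group_by(sf_cpd) %>%
    dplyr::summarise(acc = mean(correct))
  in_range <- pooled_acc$sf_cpd[pooled_acc$acc >= 0.55 & pooled_acc$acc <= 0.95]
  expect_setequal(curve$sf_cpd, in_range)

  expect_warning(
    empty <- accuracy_ratio_by_sf(tr, "vma", min_participants = 15),
    "No SF level"
  )
  expect_equal(nrow(empty), 0)
})
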