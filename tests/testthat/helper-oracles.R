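# Independent oracles used to cross-check the package's own computations.
# These deliberately avoid the code paths they verify.

# Brute-force minimum of the binomial NLL over an (alpha, beta, lambda) grid.
grid_nll_min <- function(agg, alphas, betas, lambdas, gamma = 0.5) {
  x <- log10(agg$sf_cpd)
  n <- agg$n
  k <- agg$n_correct
  best <- Inf
  for (l in lambdas) {
    for (b in betas) {
      p <- gamma + (1 - gamma - l) * pnorm(b * outer(alphas, x, "-"))
      p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
      nll <- -(log(p) %*% k + log(1 - p) %*% (n - k))
      best <- min(best, min(nll))
    }
  }
  best
}

# Standard-normal quantile via root finding on pnorm (independent of qnorm).
z_quantile <- function(p) {
  uniroot(function(z) pnorm(z) - p, c(-10, 10), tol = 1e-12)$root
}

# One-factor repeated-measures sums-of-squares decomposition.
# Y: subjects x levels matrix.
rm_decomposition <- function(Y) {
  grand <- mean(Y)
  cm <- colMeans(Y)
  sm <- rowMeans(Y)
  ss_f <- nrow(Y) * sum((cm - grand)^2)
  resid <- Y - outer(sm, cm, "+") + grand
  ss_e <- sum(resid^2)
  df1 <- ncol(Y) - 1
  df2 <- (nrow(Y) - 1) * (ncol(Y) - 1)
  list(ss_f = ss_f, ss_e = ss_e, df1 = df1, df2 = df2,
       f = (ss_f / df1) / (ss_e / df2),
       pes = ss_f / (ss_f + ss_e))
}

# Greenhouse-Geisser epsilon from the sample covariance of the cells,
# via orthonormal contrasts.
gg_epsilon_oracle <- function(Y) {
  k <- ncol(Y)
  S <- cov(Y)
  C <- qr.Q(qr(stats::contr.helmert(k)))
  M <- t(C) %*% S %*% C
  sum(diag(M))^2 / ((k - 1) * sum(M * M))
}

# Expected per-VF regression line implied by the generator: the ground truth
# at distance 90 (the horizontal meridian) is the average of the two VF
# lines and enters both VF groups, so the expected fitted line per VF is the
# least-squares line through six points on that VF's line plus the averaged
# HM point. Computed by closed-form OLS on the noise-free expectations.
implied_vf_line <- function(a_u, b_u, a_l, b_l, vf = c("upper", "lower")) {
  vf <- match.arg(vf)
  d <- seq(0, 90, by = 15)
  y_u <- a_u + b_u * d
  y_l <- a_l + b_l * d
  hm <- (y_u[d == 90] + y_l[d == 90]) / 2
  y <- if (vf == "upper") y_u else y_l
  y[d == 90] <- hm
  cf <- stats::coef(stats::lm(y ~ d))
  list(intercept = unname(cf[1]), slope = unname(cf[2]))
}

# Minimal psychometric fit object for exercising recenter_sf_grid rules.
fake_fit <- function(threshold_cpd, converged = TRUE) {
  p <- params_from_truth(log10(threshold_cpd), log10(threshold_cpd) + 0.12)
  structure(
    list(params = p, nll = 0, converged = converged, degenerate = FALSE,
         n_trials = 100, aggregates = NULL),
    class = "pf_fit"
  )
}

# Synthetic estimate tables generated directly from per-VF lines (bypassing
# the psychometric stage) for the angular-model tests.
make_line_estimates <- function(a_u, b_u, a_l, b_l, n_obs = 3, noise_sd = 0,
                                obs_sd = 0, seed = 1, response = "threshold") {
  set.seed(seed)
  u <- rnorm(n_obs, 0, obs_sd)
  if (n_obs > 1) u <- u - mean(u)  # cohort mean lines equal the generators
  d <- tidyr::expand_grid(
    obs = seq_len(n_obs),
    visual_field = c("upper", "lower"),
    angular_distance_deg = seq(0, 90, by = 15)
  )
  a <- ifelse(d$visual_field == "upper", a_u, a_l)
  b <- ifelse(d$visual_field == "upper", b_u, b_l)
  y <- a + b * d$angular_distance_deg + u[d$obs] +
    rnorm(nrow(d), 0, noise_sd)
  ycol <- paste0(response, "_log10")
  out <- tibble::tibble(
    observer_id = sprintf("o%02d", d$obs),
    condition = "binocular",
    visual_field = d$visual_field,
    angular_distance_deg = d$angular_distance_deg,
    degenerate = FALSE
  )
  out[[ycol]] <- y
  out
}
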