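#' Simulate binary 2AFC responses from a psychometric function
#'
#' Bernoulli draws with success probability given by
#' [psychometric_probability()], using R's current random-number stream.
#'
#' @inheritParams psychometric_probability
#'
#' @return An integer vector of 0/1 correctness values, one per element of
#'   `sf_cpd`.
#' @examples
#' set.seed(1)
#' mean(simulate_response(rep(10^0.75, 1e4), alpha = 0.75, beta = 17))  # ~0.75
#' @export
simulate_response <- function(sf_cpd, alpha, beta, gamma = 0.5, lambda = 0) {
  p <- psychometric_probability(sf_cpd, alpha, beta, gamma, lambda)
  rbinom(length(p), 1L, p)
}

#' Simulate a full method-of-constant-stimuli experiment
#'
#' Draws one intercept per observer from the model, then simulates every
#' scheduled block trial by trial: each block presents its four locations'
#' spatial-frequency grids `trials_per_sf` times, and correctness is drawn
#' from the location's true psychometric function (built by
#' [params_from_truth()] from the model's threshold/cutoff lines).
#'
#' When `recenter = TRUE` (the default, emulating the between-block
#' adjustment of the sampled SF range), each location's grid is recentred
#' before every repeat block via [recenter_sf_grid()], using a fast
#' reduced-start fit of the trials accumulated at that location. Recentring
#' is deterministic, so the simulation is reproducible from `seed` alone:
#' observer intercepts and each observer-by-condition trial stream use seeds
#' derived deterministically from `(seed, observer, condition)`.
#'
#' @param model A [performance_field_model()].
#' @param schedule A block schedule from [schedule_blocks()].
#' @param n_observers Number of simulated observers (>= 1).
#' @param conditions Character vector of viewing conditions to simulate; each
#'   must have lines in the model table. Observers keep the same intercept
#'   across conditions.
#' @param seed Master integer seed.
#' @param recenter Recentre SF grids between blocks (default `TRUE`).
#' @param recenter_control [fit_control()] list for the recentering fits.
#' @param center_observers Passed to [draw_observers()]: centre the cohort's
#'   intercepts to exact zero mean (default) so the cohort mean lines equal
#'   the model's line table; use `FALSE` for strictly i.i.d. cohorts, e.g.
#'   when replicating a study across seeds.
#'
#' @return A tibble of trials: `observer_id`, `condition`, `session`,
#'   `block`, `polar_angle_deg`, `eccentricity_deg`, `sf_cpd`, `correct`.
#' @examples
#' sched <- schedule_blocks(n_sessions = 1, blocks_per_session = 7)
#' trials <- simulate_experiment(n_observers = 2, schedule = sched, seed = 1)
#' dplyr::count(trials, observer_id)
#' @export
simulate_experiment <- function(model = performance_field_model(),
                                schedule = schedule_blocks(),
                                n_observers = 14,
                                conditions = "binocular",
                                seed = 1,
                                recenter = TRUE,
                                recenter_control = fast_fit_control(),
                                center_observers = TRUE) {
  if (n_observers < 1) {
    abort("`n_observers` must be at least 1.",
          class = "acuityfields_invalid_design")
  }
  missing_cond <- setdiff(conditions, unique(model$lines$condition))
  if (length(missing_cond) > 0) {
    abort(paste0("Model has no lines for condition(s): ",
                 paste(missing_cond, collapse = ", ")),
          class = "acuityfields_invalid_model")
  }
  observers <- draw_observers(model, n_observers, seed,
                              center = center_observers)
  locs <- dplyr::distinct(schedule, .data$polar_angle_deg,
                          .data$eccentricity_deg, .data$angular_distance_deg,
                          .data$visual_field)
  block_rows <- split(tibble::as_tibble(schedule), schedule$block)

  one_observer <- function(i, cond, cond_idx) {
    u_loc <- rep(0, nrow(locs))
    set.seed(derive_seed(seed, i, cond_idx * 2L))
    if (model$sigma_location > 0) {
      u_loc <- rnorm(nrow(locs), 0, model$sigma_location)
    }
    truth <- true_lines_at(model, locs$angular_distance_deg,
                           locs$visual_field, cond,
                           u = observers$u_i[i] + u_loc)
    pars <- params_from_truth(truth$threshold_log10, truth$cutoff_log10,
                              model$lambda, model$gamma)
    key <- as.character(locs$polar_angle_deg)
    pars_by_loc <- setNames(split(pars, seq_len(nrow(pars))), key)
    centers <- setNames(rep(schedule$sf_center_cpd[1], nrow(locs)), key)
    seen <- setNames(vector("list", nrow(locs)), key)

    set.seed(derive_seed(seed, i, cond_idx * 2L + 1L))
    out <- vector("list", length(block_rows))
    for (b in seq_along(block_rows)) {
      blk <- block_rows[[b]]
      blk_out <- vector("list", nrow(blk))
      for (r in seq_len(nrow(blk))) {
        kk <- as.character(blk$polar_angle_deg[r])
        grid <- build_sf_grid(centers[[kk]])
        sf <- rep(grid$values_cpd, each = blk$trials_per_sf[r])
        pp <- pars_by_loc[[kk]]
        correct <- simulate_response(sf, pp$alpha, pp$beta, pp$gamma, pp$lambda)
        blk_out[[r]] <- tibble::tibble(
          observer_id = observers$observer_id[i],
          condition = cond,
          session = blk$session[r],
          block = blk$block[r],
          polar_angle_deg = blk$polar_angle_deg[r],
          eccentricity_deg = blk$eccentricity_deg[r],
          sf_cpd = sf,
          correct = correct
        )
        seen[[kk]] <- c(seen[[kk]], list(blk_out[[r]][c("sf_cpd", "correct")]))
      }
      out[[b]] <- dplyr::bind_rows(blk_out)
      if (recenter) {
        for (kk in unique(as.character(blk$polar_angle_deg))) {
          acc <- dplyr::bind_rows(seen[[kk]])
          fit <- fit_psychometric(acc, recenter_control)
          centers[[kk]] <- recenter_sf_grid(fit,
                                            build_sf_grid(centers[[kk]]))$center_cpd
        }
      }
    }
    dplyr::bind_rows(out)
  }

  res <- purrr::map_dfr(seq_along(conditions), function(j) {
    purrr::map_dfr(seq_len(n_observers), function(i) {
      one_observer(i, conditions[j], j)
    })
  })
  res
}
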