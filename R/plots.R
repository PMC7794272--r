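#' Plot a fitted psychometric function
#'
#' Observed per-SF proportions correct (point size scaled by trial count)
#' with the fitted curve and the 75%-threshold and 51%-cutoff criteria.
#'
#' @param object A `pf_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pf_fit <- function(object, ...) {
  agg <- object$aggregates %>%
    dplyr::mutate(prop = .data$n_correct / .data$n)
  gg <- ggplot2::ggplot(agg, ggplot2::aes(x = .data$sf_cpd, y = .data$prop)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(x = "Spatial frequency (cpd)", y = "Proportion correct",
                  size = "Trials") +
    ggplot2::coord_cartesian(ylim = c(0.4, 1)) +
    ggplot2::theme_minimal()
  if (!object$degenerate) {
    p <- object$params
    sf <- 10^seq(log10(min(agg$sf_cpd)), log10(max(agg$sf_cpd)),
                 length.out = 200)
    curve <- tibble::tibble(
      sf_cpd = sf,
      prop = psychometric_probability(sf, p$alpha, p$beta, p$gamma, p$lambda)
    )
    thr <- 10^invert_performance(0.75, p$alpha, p$beta, p$gamma, p$lambda)
    cut <- 10^invert_performance(0.51, p$alpha, p$beta, p$gamma, p$lambda)
    gg <- gg +
      ggplot2::geom_line(data = curve) +
      ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
      ggplot2::geom_vline(xintercept = cut, linetype = "dotted")
  }
  gg
}

#' Plot per-location estimates against angular distance from the VM
#'
#' Group-mean estimates (with +-1 SEM error bars) as a function of the
#' angular distance from the vertical meridian, split by visual field - the
#' standard performance-fields summary figure.
#'
#' @param estimates A `pf_estimates` table.
#' @param measure `"threshold"`, `"cutoff"`, or `"max_slope"`.
#' @return A ggplot object.
#' @export
plot_performance_field <- function(estimates,
                                   measure = c("threshold", "cutoff",
                                               "max_slope")) {
  measure <- match.arg(measure)
  vcol <- c(threshold = "threshold_cpd", cutoff = "cutoff_cpd",
            max_slope = "max_slope")[[measure]]
  d <- tibble::as_tibble(estimates) %>%
    dplyr::filter(!.data$degenerate) %>%
    dplyr::group_by(.data$condition, .data$visual_field,
                    .data$angular_distance_deg) %>%
    dplyr::summarise(
      mean = mean(.data[[vcol]]),
      sem = sd(.data[[vcol]]) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$angular_distance_deg,
                                  y = .data$mean,
                                  colour = .data$visual_field)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "Angular distance from vertical meridian (deg)",
                  y = switch(measure,
                             threshold = "SF threshold (cpd)",
                             cutoff = "SF cutoff (cpd)",
                             max_slope = "Maximum slope"),
                  colour = "Visual field") +
    ggplot2::theme_minimal()
}

#' Plot an angular-distance mixed-model fit
#'
#' Per-observer estimates (faint points), group means, and the model's
#' derived lines per visual-field/condition group.
#'
#' @param object A `pf_angular_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pf_angular_fit <- function(object, ...) {
  d <- object$data
  grp <- intersect(c("visual_field", "condition"), names(d))
  if (length(grp) == 0) {
    d$group <- "all"
  } else {
    d$group <- do.call(paste, c(d[grp], sep = " / "))
  }
  lines <- object$lines
  if (length(grp) == 0) {
    lines$group <- "all"
  } else {
    lines$group <- do.call(paste, c(lines[grp], sep = " / "))
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$angular_distance_deg,
                                  y = .data$y, colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.3, size = 1) +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 2.5) +
    ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(intercept = .data$intercept, slope = .data$slope,
                   colour = .data$group)
    ) +
    ggplot2::labs(x = "Angular distance from vertical meridian (deg)",
                  y = paste0("log10 ", object$response), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an accuracy-ratio curve
#'
#' @param object A `pf_ratio_curve` from [accuracy_ratio_by_sf()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pf_ratio_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sf_cpd, y = .data$ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ratio - .data$se,
                                          ymax = .data$ratio + .data$se,
                                          size = .data$n_observers),
                             fatten = 1) +
    ggplot2::scale_size_area(max_size = 3) +
    ggplot2::labs(x = "Spatial frequency (cpd)",
                  y = sprintf("%s accuracy ratio",
                              toupper(attr(object, "grouping") %||% "")),
                  size = "Observers") +
    ggplot2::theme_minimal()
}
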