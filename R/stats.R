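#' Cardinal-location asymmetry summaries (HVA and VMA)
#'
#' Summarises estimates at the four cardinal locations into the
#' horizontal-vertical anisotropy (HVA: horizontal-meridian mean divided by
#' vertical-meridian mean) and the vertical-meridian asymmetry (VMA: lower VM
#' divided by upper VM), per observer and at the group level. Per observer,
#' the HM value is the mean over the horizontal-meridian locations present
#' (left and right, or just the left after hemifield collapsing) and the VM
#' value the mean of the upper and lower VM. Observers missing a cardinal
#' estimate are dropped with a warning.
#'
#' @param estimates A `pf_estimates` table.
#' @param measure `"threshold"`, `"cutoff"`, or `"max_slope"`. Ratios are on
#'   the linear scale (cpd for the SF measures).
#'
#' @return An object of class `pf_asymmetry`: `observer_ratios` (per observer
#'   x condition: `hm`, `vm`, `uvm`, `lvm`, `hva_ratio`, `vma_ratio`) and
#'   `group` (per condition: means on the linear and log10 scales and the
#'   ratios of group means).
#' @export
cardinal_asymmetries <- function(estimates,
                                 measure = c("threshold", "cutoff", "max_slope")) {
  measure <- match.arg(measure)
  vcol <- c(threshold = "threshold_cpd", cutoff = "cutoff_cpd",
            max_slope = "max_slope")[[measure]]
  d <- tibble::as_tibble(estimates) %>%
    dplyr::filter(!.data$degenerate, !is.na(.data[[vcol]]),
                  .data$angular_distance_deg %in% c(0, 90)) %>%
    dplyr::mutate(value = .data[[vcol]])

  per_obs <- d %>%
    dplyr::group_by(.data$observer_id, .data$condition) %>%
    dplyr::summarise(
      hm = mean(.data$value[.data$angular_distance_deg == 90]),
      uvm = mean(.data$value[.data$polar_angle_deg == 90]),
      lvm = mean(.data$value[.data$polar_angle_deg == 270]),
      .groups = "drop"
    ) %>%
    dplyr::mutate(vm = (.data$uvm + .data$lvm) / 2)
  incomplete <- !is.finite(per_obs$hm) | !is.finite(per_obs$uvm) |
    !is.finite(per_obs$lvm)
  if (any(incomplete)) {
    dropped <- per_obs$observer_id[incomplete]
    warn(paste0("Dropping observer(s) missing cardinal estimates: ",
                paste(unique(dropped), collapse = ", ")))
    per_obs <- per_obs[!incomplete, ]
  }
  per_obs <- per_obs %>%
    dplyr::mutate(hva_ratio = .data$hm / .data$vm,
                  vma_ratio = .data$lvm / .data$uvm) %>%
    dplyr::select("observer_id", "condition", "hm", "vm", "uvm", "lvm",
                  "hva_ratio", "vma_ratio")

  group <- per_obs %>%
    dplyr::group_by(.data$condition) %>%
    dplyr::summarise(
      n_observers = dplyr::n(),
      hm_mean = mean(.data$hm), vm_mean = mean(.data$vm),
      uvm_mean = mean(.data$uvm), lvm_mean = mean(.data$lvm),
      hm_mean_log10 = mean(log10(.data$hm)),
      vm_mean_log10 = mean(log10(.data$vm)),
      uvm_mean_log10 = mean(log10(.data$uvm)),
      lvm_mean_log10 = mean(log10(.data$lvm)),
      hva_ratio_obs_mean = mean(.data$hva_ratio),
      vma_ratio_obs_mean = mean(.data$vma_ratio),
      .groups = "drop"
    ) %>%
    dplyr::mutate(hva_ratio = .data$hm_mean / .data$vm_mean,
                  vma_ratio = .data$lvm_mean / .data$uvm_mean)

  structure(list(observer_ratios = per_obs, group = group, measure = measure),
            class = "pf_asymmetry")
}

#' @method print pf_asymmetry
#' @export
print.pf_asymmetry <- function(x, ...) {
  cat(sprintf("<pf_asymmetry> measure: %s\n", x$measure))
  print(x$group)
  invisible(x)
}

#' @export
tidy.pf_asymmetry <- function(x, ...) {
  x$observer_ratios
}

#' @export
glance.pf_asymmetry <- function(x, ...) {
  x$group
}

#' Paired t test with Cohen's d
#'
#' @param x,y Paired per-observer values of equal length (>= 2).
#'
#' @return A one-row tibble: `method`, `statistic` (t), `df`, `p_value`,
#'   `effect_size` (Cohen's d = mean difference / SD of differences),
#'   `effect_size_type`, and `degenerate` (TRUE when the differences have
#'   zero variance).
#' @examples
#' paired_t_cohen(c(2, 3, 4), c(1, 1, 1))
#' @export
paired_t_cohen <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (sd(d) == 0) {
    m <- mean(d)
    return(tibble::tibble(
      method = "paired_t",
      statistic = if (m == 0) 0 else sign(m) * Inf,
      df = length(d) - 1,
      p_value = if (m == 0) 1 else 0,
      effect_size = if (m == 0) 0 else sign(m) * Inf,
      effect_size_type = "cohens_d",
      degenerate = TRUE
    ))
  }
  tt <- t.test(x, y, paired = TRUE)
  tibble::tibble(
    method = "paired_t",
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    effect_size = mean(d) / sd(d),
    effect_size_type = "cohens_d",
    degenerate = FALSE
  )
}

#' Pearson correlation with a t-based p value
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#'
#' @return A one-row tibble: `method`, `estimate` (r), `statistic` (t),
#'   `df`, `p_value`, `degenerate`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble::tibble(method = "pearson", estimate = NA_real_,
                          statistic = NA_real_, df = length(x) - 2,
                          p_value = NA_real_, degenerate = TRUE))
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(
    method = "pearson",
    estimate = unname(ct$estimate),
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = ct$p.value,
    degenerate = FALSE
  )
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Within-subject ANOVA for one or two fully crossed within-subject factors
#' on a complete balanced long table. Sums of squares come from the
#' univariate repeated-measures decomposition; sphericity is handled by
#' reporting the Greenhouse-Geisser epsilon (estimated from the sample
#' covariance of the within-subject cells) and the corrected degrees of
#' freedom and p value alongside the uncorrected ones. Two-level factors are
#' trivially spherical (epsilon = 1). Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data Long-format data frame.
#' @param value Name of the numeric response column.
#' @param subject Name of the subject identifier column.
#' @param within Character vector of one or two within-subject factor
#'   columns.
#'
#' @return A tibble with one row per within-subject effect: `effect`, `df1`,
#'   `df2`, `statistic` (F), `p_value`, `pes` (partial eta squared),
#'   `epsilon` (GG), `df1_gg`, `df2_gg`, `p_value_gg`.
#' @examples
#' d <- tidyr::expand_grid(s = factor(1:5), a = factor(1:3))
#' d$y <- rnorm(nrow(d)) + as.numeric(d$a)
#' rm_anova(d, "y", "s", "a")
#' @export
rm_anova <- function(data, value, subject, within) {
  stopifnot(length(within) %in% 1:2,
            all(c(value, subject, within) %in% names(data)))
  d <- tibble::as_tibble(data)[c(subject, within, value)]
  names(d) <- c(".subject", paste0(".w", seq_along(within)), ".value")
  counts <- d %>%
    dplyr::count(dplyr::across(dplyr::all_of(c(".subject",
                                               paste0(".w", seq_along(within))))))
  if (any(counts$n != 1) ||
      nrow(counts) != dplyr::n_distinct(d$.subject) *
        prod(vapply(within, function(w) dplyr::n_distinct(data[[w]]), 1))) {
    abort("Design must be complete and balanced: exactly one value per subject per cell.",
          class = "acuityfields_missing_cells")
  }
  wcols <- paste0(".w", seq_along(within))
  d <- d %>% dplyr::mutate(dplyr::across(dplyr::all_of(wcols), as.factor))
  idata <- d %>%
    dplyr::distinct(dplyr::across(dplyr::all_of(wcols))) %>%
    dplyr::arrange(dplyr::across(dplyr::all_of(wcols))) %>%
    as.data.frame()
  names(idata) <- within
  wide <- d %>%
    dplyr::arrange(dplyr::across(dplyr::all_of(c(".subject", wcols)))) %>%
    dplyr::group_by(.data$.subject) %>%
    dplyr::summarise(.cells = list(.data$.value), .groups = "drop")
  Y <- do.call(rbind, wide$.cells)
  mlm <- stats::lm(Y ~ 1)
  idesign <- as.formula(paste("~", paste(within, collapse = "*")))
  av <- car::Anova(mlm, idata = idata, idesign = idesign, type = "III")
  # Huynh-Feldt epsilon can exceed 1 and triggers a harmless warning; only
  # the Greenhouse-Geisser column is used downstream.
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  univ <- s$univariate.tests
  eff <- setdiff(rownames(univ), "(Intercept)")
  adj <- s$pval.adjustments

  res <- purrr::map_dfr(eff, function(e) {
    ss <- univ[e, "Sum Sq"]
    ess <- univ[e, "Error SS"]
    df1 <- univ[e, "num Df"]
    df2 <- univ[e, "den Df"]
    f <- univ[e, "F value"]
    p <- univ[e, "Pr(>F)"]
    if (!is.finite(f) && ss <= 1e-12) {
      f <- 0
      p <- 1
    }
    eps <- 1
    if (!is.null(adj) && e %in% rownames(adj)) {
      eps <- adj[e, "GG eps"]
    }
    # single-df effects are trivially spherical; car reports NaN there
    if (!is.finite(eps) || df1 < 2) eps <- 1
    p_gg <- if (f == 0) 1 else pf(f, eps * df1, eps * df2, lower.tail = FALSE)
    tibble::tibble(
      effect = e, df1 = df1, df2 = df2, statistic = f, p_value = p,
      pes = if (ss + ess > 0) ss / (ss + ess) else 0,
      epsilon = eps, df1_gg = eps * df1, df2_gg = eps * df2,
      p_value_gg = p_gg
    )
  })
  res
}

#' HVA/VMA accuracy ratios as a function of stimulus spatial frequency
#'
#' Computes, per spatial-frequency level, the group-mean ratio of raw
#' accuracies between location groups: horizontal over vertical meridian
#' (`grouping = "hva"`) or lower over upper vertical meridian
#' (`grouping = "vma"`). Only SF levels inside the dynamic range of the
#' psychometric functions are retained (group-mean accuracy pooled over the
#' contributing cardinal locations within `accuracy_range`), and levels with
#' fewer than `min_participants` contributing observers are dropped; the
#' number of contributing observers is reported per point.
#'
#' @param trials A trial table (typically hemifield-collapsed).
#' @param grouping `"hva"` or `"vma"`.
#' @param min_participants Minimum observers contributing to a retained SF
#'   level.
#' @param accuracy_range Dynamic-range bounds on the pooled group-mean
#'   accuracy.
#'
#' @return A tibble of class `pf_ratio_curve` with `sf_cpd`, `ratio`,
#'   `se`, and `n_observers`; empty (with a warning) when no level survives.
#' @export
accuracy_ratio_by_sf <- function(trials, grouping = c("hva", "vma"),
                                 min_participants = 4,
                                 accuracy_range = c(0.55, 0.95)) {
  grouping <- match.arg(grouping)
  info <- location_info(trials$polar_angle_deg)
  d <- tibble::as_tibble(trials)
  d$polar_angle_deg <- info$polar_angle_deg
  if (grouping == "hva") {
    d$side <- dplyr::case_when(
      info$angular_distance_deg == 90 ~ "num",
      info$polar_angle_deg %in% c(90, 270) ~ "den",
      TRUE ~ NA_character_
    )
  } else {
    d$side <- dplyr::case_when(
      info$polar_angle_deg == 270 ~ "num",
      info$polar_angle_deg == 90 ~ "den",
      TRUE ~ NA_character_
    )
  }
  d <- dplyr::filter(d, !is.na(.data$side))

  pooled <- d %>%
    dplyr::group_by(.data$sf_cpd) %>%
    dplyr::summarise(acc = mean(.data$correct), .groups = "drop") %>%
    dplyr::filter(.data$acc >= accuracy_range[1],
                  .data$acc <= accuracy_range[2])

  per_obs <- d %>%
    dplyr::filter(.data$sf_cpd %in% pooled$sf_cpd) %>%
    dplyr::group_by(.data$observer_id, .data$sf_cpd, .data$side) %>%
    dplyr::summarise(acc = mean(.data$correct), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "side", values_from = "acc") %>%
    dplyr::filter(!is.na(.data$num), !is.na(.data$den), .data$den > 0) %>%
    dplyr::mutate(ratio = .data$num / .data$den)

  curve <- per_obs %>%
    dplyr::group_by(.data$sf_cpd) %>%
    dplyr::summarise(
      ratio_mean = mean(.data$ratio),
      se = sd(.data$ratio) / sqrt(dplyr::n()),
      n_observers = dplyr::n(),
      .groups = "drop"
    ) %>%
    dplyr::filter(.data$n_observers >= min_participants) %>%
    dplyr::rename(ratio = "ratio_mean") %>%
    dplyr::arrange(.data$sf_cpd)
  if (nrow(curve) == 0) {
    warn(sprintf("No SF level retained for the %s accuracy-ratio curve.",
                 toupper(grouping)))
  }
  attr(curve, "grouping") <- grouping
  class(curve) <- c("pf_ratio_curve", class(curve))
  curve
}
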