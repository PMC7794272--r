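#' @export
tidy.pf_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    term = c("alpha", "beta", "gamma", "lambda"),
    estimate = c(p$alpha, p$beta, p$gamma, p$lambda)
  )
}

#' @export
glance.pf_fit <- function(x, ...) {
  tibble::tibble(
    nll = x$nll,
    converged = x$converged,
    degenerate = x$degenerate,
    n_trials = x$n_trials,
    n_sf_levels = nrow(x$aggregates)
  )
}
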