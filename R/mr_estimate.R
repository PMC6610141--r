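# The common result container: one estimated causal effect per row, with
# uncertainty, instrument-strength diagnostics and method provenance.

new_mr_estimate <- function(exposure, outcome, method, effect, se, n,
                            f_stat = NA_real_, cond_f = NA_real_) {
  effect <- unname(effect)
  se <- unname(se)
  f_stat <- unname(f_stat)
  cond_f <- unname(cond_f)
  z <- ifelse(se > 0, effect / se, NA_real_)
  pval <- z_pvalue(z)
  pval <- ifelse(!is.na(pval) & pval == 0, .Machine$double.xmin, pval)
  out <- tibble(
    exposure = exposure,
    outcome = outcome,
    method = method,
    effect = effect,
    se = se,
    ci_lower = effect - 1.96 * se,
    ci_upper = effect + 1.96 * se,
    pval = pval,
    n = n,
    f_stat = f_stat,
    cond_f = cond_f
  )
  class(out) <- c("mr_estimate", class(out))
  out
}

#' Combine MR estimates into one tidy table
#'
#' @param ... `mr_estimate` tibbles.
#' @return A single `mr_estimate` tibble.
#' @export
bind_mr_estimates <- function(...) {
  out <- dplyr::bind_rows(...)
  class(out) <- c("mr_estimate", class(out))
  out
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat("<mr_estimate>", nrow(x), "effect estimate(s)\n")
  NextMethod()
}

#' Tidy an MR estimate table into broom column conventions
#'
#' @param x An `mr_estimate` tibble.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high` plus `outcome` and `method`.
#' @method tidy mr_estimate
#' @export
tidy.mr_estimate <- function(x, ...) {
  tibble(
    term = x$exposure,
    outcome = x$outcome,
    method = x$method,
    estimate = x$effect,
    std.error = x$se,
    statistic = ifelse(x$se > 0, x$effect / x$se, NA_real_),
    p.value = x$pval,
    conf.low = x$ci_lower,
    conf.high = x$ci_upper
  )
}

#' One-row model summary of an MR estimate table
#'
#' @param x An `mr_estimate` tibble.
#' @param ... Unused.
#' @return A tibble with the sample size, method(s) and the weakest
#'   instrument-strength diagnostics in the table.
#' @method glance mr_estimate
#' @export
glance.mr_estimate <- function(x, ...) {
  tibble(
    n = max(x$n, na.rm = TRUE),
    methods = paste(unique(x$method), collapse = ", "),
    min_f_stat = suppressWarnings(min(x$f_stat, na.rm = TRUE)),
    min_cond_f = suppressWarnings(min(x$cond_f, na.rm = TRUE)),
    n_estimates = nrow(x)
  )
}

#' Forest-style plot of MR effect estimates
#'
#' @param object An `mr_estimate` tibble (typically several methods bound
#'   together).
#' @param ... Unused.
#' @return A ggplot object: point estimates with 95% confidence intervals,
#'   faceted by outcome when several are present.
#' @method autoplot mr_estimate
#' @export
autoplot.mr_estimate <- function(object, ...) {
  gg <- ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = .data$effect, y = interaction(.data$exposure, .data$method, sep = " / "),
      xmin = .data$ci_lower, xmax = .data$ci_upper, colour = .data$method
    )
  ) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange() +
    ggplot2::labs(
      x = "Effect (risk difference per unit exposure)", y = NULL,
      colour = "Method"
    ) +
    ggplot2::theme_minimal()
  if (length(unique(object$outcome)) > 1) {
    gg <- gg + ggplot2::facet_wrap(ggplot2::vars(.data$outcome))
  }
  gg
}
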