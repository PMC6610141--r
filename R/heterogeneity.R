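# Heterogeneity diagnostics for summary-data MR: the modified Cochran Q with
# per-SNP contributions, and one-shot outlier removal with refit.

#' Modified Cochran Q for (multivariable) summary MR
#'
#' Heterogeneity statistic whose per-SNP weights account for uncertainty in
#' the SNP-exposure associations as well as the SNP-outcome association:
#' \deqn{q_j = w_j (\hat\Gamma_j - \hat\beta_1\hat\pi_{1j} -
#'   \hat\beta_2\hat\pi_{2j})^2, \quad
#'   w_j = 1/(se_{\Gamma j}^2 + \hat\beta_1^2 se_{\pi 1 j}^2 +
#'   \hat\beta_2^2 se_{\pi 2 j}^2).}
#' The total Q is referred to a chi-squared distribution with L - (number of
#' exposures) degrees of freedom; each per-SNP contribution is referred to
#' chi-squared with 1 df, flagging potentially pleiotropic outliers. When no
#' fitted coefficients are supplied they are estimated internally by
#' iteratively reweighted least squares: the betas and the Q weights are
#' updated in turn until convergence, so the reported Q is evaluated at
#' coefficients consistent with its own weights.
#'
#' @param data A harmonised summary dataset.
#' @param fitted Optional numeric vector of fitted causal effects (length 1
#'   for univariable, 2 for multivariable). Default: estimated internally.
#' @param exposures `"both"` (default, multivariable), `"edu"` or `"cog"`.
#' @param alpha Per-SNP significance level used to flag outliers.
#' @return An object of class `q_report`: list with `q_total`, `df`, `pval`,
#'   `per_snp` (tibble of `snp_id`, `q`, `pval`), `removed_snps` (ids with
#'   per-SNP p < alpha), `estimates` (coefficients at which Q was evaluated)
#'   and `alpha`. With df = 0 (just-identified) the global p-value is `NA` and
#'   flagged.
#' @examples
#' p <- sim_params(n_snps_edu = 20, n_snps_cog = 10, seed = 6)
#' s <- simulate_two_sample_summary(p, 2000, 2000)
#' modified_q(s)
#' @export
modified_q <- function(data, fitted = NULL, exposures = c("both", "edu", "cog"),
                       alpha = 0.05) {
  exposures <- match.arg(exposures)
  multivariable <- exposures == "both"
  check_summary_data(data, need_pi2 = multivariable || exposures == "cog")
  check_number(alpha, "alpha", 0, 1)
  L <- nrow(data)
  k <- if (multivariable) 2L else 1L
  if (multivariable) {
    D <- cbind(data$pi1_hat, data$pi2_hat)
    SE <- cbind(data$se_pi1, data$se_pi2)
  } else {
    cols <- exposure_cols(exposures)
    D <- cbind(data[[cols[["pi"]]]])
    SE <- cbind(data[[cols[["se"]]]])
  }
  gamma <- data$gamma_hat

  q_weights <- function(beta) {
    1 / (data$se_gamma^2 + drop(SE^2 %*% beta^2))
  }
  if (is.null(fitted)) {
    beta <- if (multivariable) {
      mvmr_ivw(data)$effect
    } else {
      ivw_univariable(data, exposures)$effect
    }
    for (it in seq_len(100)) {
      w <- q_weights(beta)
      beta_new <- drop(solve(
        crossprod(D * sqrt(w)),
        crossprod(D, w * gamma)
      ))
      if (max(abs(beta_new - beta)) < 1e-10) {
        beta <- beta_new
        break
      }
      beta <- beta_new
    }
  } else {
    if (length(fitted) != k) {
      abort(sprintf("`fitted` must have length %d.", k))
    }
    beta <- as.numeric(fitted)
  }

  w <- q_weights(beta)
  resid <- gamma - drop(D %*% beta)
  q_j <- w * resid^2
  q_total <- sum(q_j)
  df <- L - k
  pval <- if (df > 0) pchisq(q_total, df, lower.tail = FALSE) else NA_real_
  if (df <= 0) {
    warn("Q has zero degrees of freedom (just-identified fit); global p-value undefined.")
  }
  per_snp <- tibble(
    snp_id = data$snp_id,
    q = q_j,
    pval = pchisq(q_j, 1, lower.tail = FALSE)
  )
  structure(
    list(
      q_total = q_total, df = df, pval = pval,
      per_snp = per_snp,
      removed_snps = per_snp$snp_id[per_snp$pval < alpha],
      estimates = beta, alpha = alpha
    ),
    class = "q_report"
  )
}

#' @export
print.q_report <- function(x, ...) {
  cat("<q_report>\n")
  cat(sprintf(
    "  Q = %.2f on %d df (p = %s)\n", x$q_total, x$df,
    ifelse(is.na(x$pval), "NA", format.pval(x$pval, digits = 3))
  ))
  cat(sprintf(
    "  %d of %d SNPs flagged at per-SNP p < %g\n",
    length(x$removed_snps), nrow(x$per_snp), x$alpha
  ))
  invisible(x)
}

#' Per-SNP heterogeneity contribution plot
#'
#' @param object A `q_report`.
#' @param ... Unused.
#' @return A ggplot of per-SNP Q contributions with the chi-squared(1)
#'   threshold at the report's alpha; flagged SNPs are highlighted.
#' @method autoplot q_report
#' @export
autoplot.q_report <- function(object, ...) {
  d <- object$per_snp
  d$flagged <- d$snp_id %in% object$removed_snps
  thr <- stats::qchisq(1 - object$alpha, 1)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$snp_id, -.data$q), y = .data$q,
    fill = .data$flagged
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "SNP (by contribution)", y = "Q contribution",
      fill = sprintf("p < %g", object$alpha)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' One-shot heterogeneity outlier removal and refit
#'
#' Removes every SNP whose individual Q contribution is significant at
#' `alpha`, in a single pass (no iteration), then refits the IVW model on the
#' remaining SNPs — a sensitivity analysis for pleiotropic outliers.
#'
#' @inheritParams modified_q
#' @param alpha Per-SNP removal threshold (default 0.05); `alpha = 0` removes
#'   nothing.
#' @return A list with `removed` (SNP ids), `fit` (refitted `mr_estimate`),
#'   `q_before` and `q_after` (`q_report`s), and `data` (the retained subset).
#' @examples
#' p <- sim_params(n_snps_edu = 20, n_snps_cog = 10, seed = 9)
#' s <- simulate_two_sample_summary(p, 2000, 2000)
#' remove_outliers_and_refit(s)$removed
#' @export
remove_outliers_and_refit <- function(data, alpha = 0.05,
                                      exposures = c("both", "edu", "cog")) {
  exposures <- match.arg(exposures)
  q_before <- modified_q(data, exposures = exposures, alpha = alpha)
  removed <- q_before$removed_snps
  keep <- !data$snp_id %in% removed
  if (!any(keep)) {
    abort("Outlier removal excluded every SNP; nothing left to refit.")
  }
  kept_data <- data[keep, , drop = FALSE]
  fit <- if (exposures == "both") {
    mvmr_ivw(kept_data)
  } else {
    ivw_univariable(kept_data, exposures)
  }
  q_after <- if (nrow(kept_data) > (if (exposures == "both") 2 else 1)) {
    modified_q(kept_data, exposures = exposures, alpha = alpha)
  } else {
    NULL
  }
  list(
    removed = removed, fit = fit,
    q_before = q_before, q_after = q_after,
    data = kept_data
  )
}
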