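# Two-sample summary-data MR: Wald ratios, univariable IVW, multivariable
# IVW, MR-Egger.

exposure_cols <- function(exposure = c("edu", "cog")) {
  exposure <- match.arg(exposure)
  if (exposure == "edu") {
    c(pi = "pi1_hat", se = "se_pi1")
  } else {
    c(pi = "pi2_hat", se = "se_pi2")
  }
}

check_summary_data <- function(data, need_pi2 = FALSE) {
  need <- c("snp_id", "gamma_hat", "se_gamma", "pi1_hat", "se_pi1")
  if (need_pi2) need <- c(need, "pi2_hat", "se_pi2")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "Summary dataset lacks column(s): %s.", paste(missing, collapse = ", ")
    ))
  }
  if (!all(data$se_gamma > 0)) abort("All outcome SEs must be positive.")
  if ("harmonised" %in% names(data) && !all(data$harmonised)) {
    abort("Summary data must be harmonised before estimation.")
  }
  invisible(data)
}

summary_outcome_label <- function(data) {
  attr(data, "outcome") %||% "outcome"
}

#' Single-SNP Wald ratio
#'
#' The per-SNP causal estimate: SNP-outcome association divided by
#' SNP-exposure association, with a first-order delta-method standard error
#' that propagates uncertainty in both associations.
#'
#' @param gamma_hat,se_gamma SNP-outcome association and its SE.
#' @param pi_hat,se_pi SNP-exposure association and its SE.
#' @return A tibble with `ratio` and `se` (vectorised over SNPs). Weak SNPs
#'   (|pi_hat| < 3 se_pi) trigger a warning.
#' @examples
#' wald_ratio(0.2, 0.01, 0.4, 0)
#' @export
wald_ratio <- function(gamma_hat, se_gamma, pi_hat, se_pi) {
  if (any(pi_hat == 0)) {
    abort("Wald ratio undefined for pi_hat = 0.")
  }
  weak <- abs(pi_hat) < 3 * se_pi
  if (any(weak)) {
    warn(sprintf(
      "%d SNP(s) have |exposure association| < 3 SEs; Wald ratios will be unstable.",
      sum(weak)
    ))
  }
  ratio <- gamma_hat / pi_hat
  se <- sqrt(se_gamma^2 / pi_hat^2 + gamma_hat^2 * se_pi^2 / pi_hat^4)
  tibble(ratio = ratio, se = se)
}

ivw_wls <- function(D, gamma, w, overdispersion) {
  XtWX <- crossprod(D * sqrt(w))
  beta <- solve(XtWX, crossprod(D, w * gamma))
  resid <- gamma - drop(D %*% beta)
  V <- solve(XtWX)
  df <- length(gamma) - ncol(D)
  phi <- 1
  if (overdispersion && df > 0) {
    phi <- max(1, sum(w * resid^2) / df)
  }
  list(coef = drop(beta), vcov = V * phi, resid = resid, phi = phi)
}

#' Univariable inverse-variance-weighted MR estimate
#'
#' Weighted regression of the SNP-outcome associations on the SNP-exposure
#' associations through the origin, weights 1/se_gamma^2 — the meta-analytic
#' combination of per-SNP Wald ratios. With one SNP it equals the Wald ratio.
#'
#' @param data A harmonised summary dataset (see
#'   [simulate_two_sample_summary()] for the column layout).
#' @param exposure `"edu"` (uses `pi1_hat`) or `"cog"` (uses `pi2_hat`).
#' @param overdispersion If `TRUE`, inflate SEs multiplicatively by the
#'   residual dispersion when it exceeds 1 (default `FALSE`: fixed-effect
#'   standard errors matching the plain weighted regression).
#' @return An `mr_estimate` row, method `"IVW"`; `n` is the number of SNPs.
#' @examples
#' p <- sim_params(n_snps_edu = 20, n_snps_cog = 5, seed = 4)
#' s <- simulate_two_sample_summary(p, 2000, 2000)
#' ivw_univariable(s, "edu")
#' @export
ivw_univariable <- function(data, exposure = c("edu", "cog"),
                            overdispersion = FALSE) {
  exposure <- match.arg(exposure)
  check_summary_data(data, need_pi2 = exposure == "cog")
  L <- nrow(data)
  if (L == 0) abort("Summary dataset has no SNPs.")
  cols <- exposure_cols(exposure)
  pi_hat <- data[[cols[["pi"]]]]
  w <- 1 / data$se_gamma^2
  fit <- ivw_wls(cbind(pi_hat), data$gamma_hat, w, overdispersion)
  new_mr_estimate(
    exposure = exposure, outcome = summary_outcome_label(data),
    method = "IVW", effect = fit$coef[1], se = sqrt(fit$vcov[1, 1]), n = L
  )
}

#' Multivariable inverse-variance-weighted MR
#'
#' Fits the no-intercept weighted regression of the SNP-outcome associations
#' on both SNP-exposure associations,
#' \deqn{\hat\Gamma_j = \beta_1 \hat\pi_{1j} + \beta_2 \hat\pi_{2j} + v_j,}
#' weights 1/se_gamma^2, returning the direct effects of education and
#' cognitive ability jointly.
#'
#' @inheritParams ivw_univariable
#' @return An `mr_estimate` tibble with two rows (`edu`, `cog`), method
#'   `"IVW-MV"`. Collinear exposure associations or a degenerate (all-zero)
#'   exposure column are errors.
#' @examples
#' p <- sim_params(n_snps_edu = 20, n_snps_cog = 10, seed = 4)
#' s <- simulate_two_sample_summary(p, 2000, 2000)
#' mvmr_ivw(s)
#' @export
mvmr_ivw <- function(data, overdispersion = FALSE) {
  check_summary_data(data, need_pi2 = TRUE)
  L <- nrow(data)
  if (L < 2) abort("Multivariable IVW needs at least 2 SNPs.")
  D <- cbind(data$pi1_hat, data$pi2_hat)
  if (all(D[, 1] == 0) || all(D[, 2] == 0)) {
    abort("An exposure association column is identically zero; fit the univariable model instead.")
  }
  # with L = 2 the sample correlation of two points is always +-1, so test
  # invertibility of the design instead
  collinear <- if (L > 2) {
    abs(stats::cor(D[, 1], D[, 2])) > 0.999
  } else {
    abs(det(crossprod(D))) < 1e-24 * sum(D^2)^2
  }
  if (collinear) {
    abort("Exposure associations are collinear across SNPs (conditionally weak instruments).")
  }
  w <- 1 / data$se_gamma^2
  fit <- ivw_wls(D, data$gamma_hat, w, overdispersion)
  new_mr_estimate(
    exposure = c("edu", "cog"), outcome = summary_outcome_label(data),
    method = "IVW-MV", effect = fit$coef, se = sqrt(diag(fit$vcov)), n = L
  )
}

#' MR-Egger regression (univariable or multivariable)
#'
#' The IVW regression with an unconstrained intercept. Under the InSIDE
#' assumption (instrument strength independent of direct effects) the
#' intercept estimates the average directional pleiotropy and the slope is a
#' pleiotropy-robust causal estimate. SNPs are first oriented so the chosen
#' exposure's association is non-negative, since the intercept is not
#' invariant to allele orientation.
#'
#' @inheritParams ivw_univariable
#' @param multivariable If `TRUE` (default), regress on both exposure
#'   associations (requires >= 4 SNPs); otherwise on the selected exposure
#'   only (requires >= 3 SNPs).
#' @param orient_by Exposure whose associations are made non-negative
#'   (default `"edu"`, or the selected exposure in the univariable fit).
#' @return A list with `estimates` (an `mr_estimate` tibble, method
#'   `"MR-Egger"`) and `intercept` (tibble with `effect`, `se`, `ci_lower`,
#'   `ci_upper`, `pval`).
#' @examples
#' p <- sim_params(n_snps_edu = 20, n_snps_cog = 10, seed = 8)
#' s <- simulate_two_sample_summary(p, 2000, 2000)
#' mr_egger(s, multivariable = FALSE, exposure = "edu")$intercept
#' @export
mr_egger <- function(data, multivariable = TRUE, exposure = c("edu", "cog"),
                     orient_by = NULL, overdispersion = FALSE) {
  exposure <- match.arg(exposure)
  check_summary_data(data, need_pi2 = multivariable || exposure == "cog")
  L <- nrow(data)
  min_L <- if (multivariable) 4 else 3
  if (L < min_L) {
    abort(sprintf(
      "MR-Egger needs at least %d SNPs (%d supplied): the regression is underdetermined.",
      min_L, L
    ))
  }
  orient_by <- orient_by %||% if (multivariable) "edu" else exposure
  ocol <- exposure_cols(orient_by)[["pi"]]
  flip <- ifelse(data[[ocol]] < 0, -1, 1)
  gamma <- data$gamma_hat * flip
  pi1 <- data$pi1_hat * flip
  w <- 1 / data$se_gamma^2
  if (multivariable) {
    pi2 <- data$pi2_hat * flip
    D <- cbind(`(Intercept)` = 1, pi1, pi2)
    labels <- c("edu", "cog")
  } else {
    pix <- data[[exposure_cols(exposure)[["pi"]]]] * flip
    D <- cbind(`(Intercept)` = 1, pix)
    labels <- exposure
  }
  fit <- ivw_wls(D, gamma, w, overdispersion)
  k <- ncol(D)
  slopes <- new_mr_estimate(
    exposure = labels, outcome = summary_outcome_label(data),
    method = "MR-Egger", effect = fit$coef[2:k],
    se = sqrt(diag(fit$vcov)[2:k]), n = L
  )
  i_se <- sqrt(fit$vcov[1, 1])
  intercept <- tibble(
    effect = fit$coef[1], se = i_se,
    ci_lower = fit$coef[1] - 1.96 * i_se,
    ci_upper = fit$coef[1] + 1.96 * i_se,
    pval = z_pvalue(fit$coef[1] / i_se)
  )
  list(estimates = slopes, intercept = intercept)
}

#' Convert a log-odds effect to an odds ratio with 95% CI
#'
#' @param effect Effect(s) on the log-odds scale.
#' @param se Standard error(s) on the log-odds scale.
#' @return A tibble with `effect`, `se`, `or`, `or_lower`, `or_upper`.
#' @examples
#' to_odds_ratio(log(0.658), 0.07)
#' @export
to_odds_ratio <- function(effect, se) {
  tibble(
    effect = effect, se = se,
    or = exp(effect),
    or_lower = exp(effect - 1.96 * se),
    or_upper = exp(effect + 1.96 * se)
  )
}
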