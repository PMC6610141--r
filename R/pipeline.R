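# End-to-end orchestration: full individual-level and summary-level analyses
# and the empirical power calculator. These functions are the programmatic
# entry points; each emitted table row is traceable to one estimator call.

default_covariate_names <- function(data, n_pcs) {
  pcs <- paste0("pc", seq_len(n_pcs))
  pcs <- pcs[pcs %in% names(data)]
  c("age", "sex", "year_of_birth", "sex_x_year_of_birth", pcs)
}

prepare_analysis_data <- function(cohort_obj, n_pcs) {
  d <- cohort_obj$cohort
  cov_block <- build_covariates(d, n_pcs = n_pcs)
  d$sex_x_year_of_birth <- cov_block$sex_x_year_of_birth
  d$score_edu <- compute_prs(cohort_obj$dosages, cohort_obj$panel, "edu")
  d$score_cog <- compute_prs(cohort_obj$dosages, cohort_obj$panel, "cog")
  d
}

#' Run the full individual-level analysis
#'
#' For each requested smoking outcome, computes the observational OLS
#' estimates, the two univariable MR estimates (each exposure instrumented by
#' its own polygenic score), and the multivariable MR estimates with
#' first-stage and conditional F diagnostics, all adjusted for age, sex, year
#' of birth, the sex-by-year-of-birth interaction and the leading genetic
#' principal components. The cessation outcome is analysed among ever smokers
#' only. Effects for education are additionally reported per SD of years of
#' education.
#'
#' @param x A [sim_params()] object (a cohort is simulated) or an `mr_cohort`.
#' @param outcomes Subset of `c("current", "ever", "former")`.
#' @param n_pcs Number of genetic principal components in the adjustment set.
#' @param weights Optional analysis weights: column name or numeric vector
#'   aligned with the cohort.
#' @return A list of class `mr_report`: `estimates` (one `mr_estimate` tibble
#'   over all outcomes and methods), `sd_scaled` (per-SD education effects per
#'   outcome and method), and `config` (what was run, including the seed when
#'   simulated).
#' @examples
#' rep <- run_individual_analysis(
#'   sim_params(n_individuals = 2000, seed = 10),
#'   outcomes = "ever", n_pcs = 2
#' )
#' rep$estimates
#' @export
run_individual_analysis <- function(x,
                                    outcomes = c("current", "ever", "former"),
                                    n_pcs = 10,
                                    weights = NULL) {
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  cohort_obj <- if (inherits(x, "sim_params")) simulate_cohort(x) else x
  stopifnot(inherits(cohort_obj, "mr_cohort"))
  n_pcs <- min(n_pcs, cohort_obj$params$n_pcs)
  d <- prepare_analysis_data(cohort_obj, n_pcs)
  covs <- default_covariate_names(d, n_pcs)
  exposures <- c("edu_years", "cog_score")
  scores <- c("score_edu", "score_cog")

  one_outcome <- function(oc) {
    ycol <- paste0("smoke_", oc)
    dd <- if (oc == "former") d[d$smoke_ever == 1, , drop = FALSE] else d
    est <- bind_mr_estimates(
      ols_estimate(dd, ycol, exposures, covs, weights),
      tsls_univariable(dd, ycol, "edu_years", "score_edu", covs, weights),
      tsls_univariable(dd, ycol, "cog_score", "score_cog", covs, weights),
      tsls_multivariable(dd, ycol, exposures, scores, covs, weights)
    )
    est
  }
  estimates <- bind_mr_estimates(lapply(outcomes, one_outcome))

  edu_sd <- sd(d$edu_years)
  edu_rows <- estimates[estimates$exposure == "edu_years", ]
  sd_scaled <- dplyr::bind_cols(
    tibble(outcome = edu_rows$outcome, method = edu_rows$method),
    sd_scale(edu_rows$effect, edu_sd)
  )

  structure(
    list(
      estimates = estimates,
      sd_scaled = sd_scaled,
      config = list(
        outcomes = outcomes, n_pcs = n_pcs,
        weighted = !is.null(weights),
        simulated = inherits(x, "sim_params"),
        seed = if (inherits(x, "sim_params")) x$seed else cohort_obj$params$seed,
        n = nrow(cohort_obj$cohort)
      )
    ),
    class = "mr_report"
  )
}

#' @export
print.mr_report <- function(x, ...) {
  cat("<mr_report> individual-level MR analysis\n")
  cat(sprintf(
    "  n = %s; outcomes: %s; %d PCs%s\n",
    format(x$config$n, big.mark = ","),
    paste(x$config$outcomes, collapse = ", "),
    x$config$n_pcs,
    if (x$config$weighted) "; weighted" else ""
  ))
  print(as_tibble(x$estimates), n = nrow(x$estimates))
  invisible(x)
}

#' Run the full summary-level analysis
#'
#' Computes univariable IVW for each exposure, multivariable IVW, MR-Egger
#' (univariable for the first exposure and multivariable), the modified
#' Cochran Q report, and the one-shot outlier-removal sensitivity refit. When
#' the outcome associations are on the log-odds scale, odds-ratio columns are
#' appended.
#'
#' @param data A harmonised summary dataset, or a [sim_params()] object (a
#'   dataset is simulated with `n_gwas`).
#' @param n_gwas Named numeric `c(exposure = , outcome = )` used only when
#'   simulating.
#' @param scale Outcome association scale when simulating (`"rd"` or
#'   `"logodds"`).
#' @param outlier_alpha Per-SNP Q threshold for the sensitivity refit.
#' @return A list of class `summary_report`: `estimates` (all methods bound,
#'   with OR columns when on the log-odds scale), `egger_intercepts`,
#'   `q_report`, `outlier_refit`, `config`.
#' @examples
#' rep <- run_summary_analysis(
#'   sim_params(n_snps_edu = 20, n_snps_cog = 8, seed = 14),
#'   n_gwas = c(exposure = 2000, outcome = 2000)
#' )
#' rep$estimates
#' @export
run_summary_analysis <- function(data,
                                 n_gwas = c(exposure = 20000, outcome = 20000),
                                 scale = c("rd", "logodds"),
                                 outlier_alpha = 0.05) {
  scale <- match.arg(scale)
  if (inherits(data, "sim_params")) {
    data <- simulate_two_sample_summary(
      data, n_gwas[["exposure"]], n_gwas[["outcome"]],
      scale = scale
    )
  }
  check_summary_data(data, need_pi2 = FALSE)
  has_pi2 <- "pi2_hat" %in% names(data) && !all(data$pi2_hat == 0)
  data_scale <- attr(data, "scale") %||% scale

  est <- list(ivw_univariable(data, "edu"))
  eg_int <- list()
  if (has_pi2) {
    est <- c(est, list(
      ivw_univariable(data, "cog"),
      mvmr_ivw(data)
    ))
    eg_uni <- mr_egger(data, multivariable = FALSE, exposure = "edu")
    eg_mv <- mr_egger(data, multivariable = TRUE)
    est <- c(est, list(eg_uni$estimates, eg_mv$estimates))
    eg_int <- list(
      univariable = eg_uni$intercept,
      multivariable = eg_mv$intercept
    )
    qrep <- modified_q(data, exposures = "both", alpha = outlier_alpha)
    refit <- remove_outliers_and_refit(data, outlier_alpha, "both")
  } else {
    eg_uni <- mr_egger(data, multivariable = FALSE, exposure = "edu")
    est <- c(est, list(eg_uni$estimates))
    eg_int <- list(univariable = eg_uni$intercept)
    qrep <- modified_q(data, exposures = "edu", alpha = outlier_alpha)
    refit <- remove_outliers_and_refit(data, outlier_alpha, "edu")
  }
  estimates <- bind_mr_estimates(est)
  if (identical(data_scale, "logodds")) {
    ors <- to_odds_ratio(estimates$effect, estimates$se)
    estimates$or <- ors$or
    estimates$or_lower <- ors$or_lower
    estimates$or_upper <- ors$or_upper
  }

  structure(
    list(
      estimates = estimates,
      egger_intercepts = eg_int,
      q_report = qrep,
      outlier_refit = refit,
      config = list(
        n_snps = nrow(data), scale = data_scale,
        multivariable = has_pi2, outlier_alpha = outlier_alpha
      )
    ),
    class = "summary_report"
  )
}

#' @export
print.summary_report <- function(x, ...) {
  cat("<summary_report> two-sample summary MR analysis\n")
  cat(sprintf(
    "  L = %d SNPs; scale: %s; %s\n",
    x$config$n_snps, x$config$scale,
    if (x$config$multivariable) "univariable + multivariable" else "univariable"
  ))
  print(as_tibble(x$estimates), n = nrow(x$estimates))
  print(x$q_report)
  invisible(x)
}

#' Empirical power by simulation
#'
#' Estimates the power of the univariable education MR analysis to detect a
#' hypothesised risk difference at a given sample size, as the fraction of
#' simulated replicates in which the effect is detected at p < 0.05, with its
#' binomial Monte-Carlo standard error. This replaces a closed-form power
#' formula with the generative model itself.
#'
#' @param params Baseline [sim_params()]; `beta1` is overridden by `effect`
#'   and `n_individuals` by `n` in each replicate.
#' @param effect Hypothesised direct effect of education (risk difference per
#'   year).
#' @param n Sample size per replicate.
#' @param replicates Number of simulation replicates (at least 100).
#' @param alpha Detection threshold (default 0.05).
#' @return A one-row tibble: `power`, `mc_se`, `replicates`, `n`, `effect`.
#' @examples
#' \donttest{
#' estimate_power_by_simulation(
#'   sim_params(seed = 30), effect = 0, n = 2000, replicates = 100
#' )
#' }
#' @export
estimate_power_by_simulation <- function(params, effect, n, replicates,
                                         alpha = 0.05) {
  stopifnot(inherits(params, "sim_params"))
  check_number(replicates, "replicates", lower = 100)
  check_number(alpha, "alpha", 0, 1)
  hits <- vapply(seq_len(replicates), function(r) {
    q <- params
    q$beta1 <- effect
    q$n_individuals <- n
    q$seed <- substream_seed(params$seed, "replicate") + r
    class(q) <- "sim_params"
    cc <- simulate_cohort(q)
    d <- cc$cohort
    d$score_edu <- compute_prs(cc$dosages, cc$panel, "edu")
    est <- tsls_univariable(d, "smoke_ever", "edu_years", "score_edu")
    est$pval < alpha
  }, logical(1))
  power <- mean(hits)
  tibble(
    power = power,
    mc_se = sqrt(power * (1 - power) / replicates),
    replicates = replicates, n = n, effect = effect
  )
}
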