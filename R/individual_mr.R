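# Individual-level estimation: observational OLS, univariable and
# multivariable two-stage IV with polygenic-score instruments, first-stage
# and conditional F diagnostics, SD scaling, and census re-weighting.

get_columns <- function(data, cols, what) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s column(s) not found in `data`: %s.",
      what, paste(missing, collapse = ", ")
    ))
  }
  m <- as.matrix(data[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    abort(sprintf("%s columns contain missing values; complete cases only.", what))
  }
  m
}

resolve_weights <- function(data, weights) {
  if (is.null(weights)) {
    return(rep(1, nrow(data)))
  }
  w <- if (is.character(weights)) {
    drop(get_columns(data, weights, "Weight"))
  } else {
    as.numeric(weights)
  }
  if (length(w) != nrow(data) || any(!is.finite(w)) || any(w <= 0)) {
    abort("Analysis weights must be positive, finite, one per row.")
  }
  w
}

covariate_design <- function(data, covariates) {
  if (is.null(covariates) || length(covariates) == 0) {
    return(matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)")))
  }
  W <- cbind(`(Intercept)` = 1, get_columns(data, covariates, "Covariate"))
  qx <- qr(W)
  if (qx$rank < ncol(W)) {
    dropped <- colnames(W)[qx$pivot[(qx$rank + 1):ncol(W)]]
    abort(sprintf(
      "Covariates are collinear; offending column(s): %s.",
      paste(dropped, collapse = ", ")
    ))
  }
  W
}

wls_rss <- function(X, y, w) {
  fit <- stats::lm.wfit(x = X, y = y, w = w)
  sum(w * fit$residuals^2)
}

# Partial F test of the instrument block Z in y ~ Z + W (weighted).
partial_f <- function(y, Z, W, w, num_df = ncol(Z)) {
  n <- length(y)
  rss0 <- wls_rss(W, y, w)
  rss1 <- wls_rss(cbind(Z, W), y, w)
  den_df <- n - ncol(Z) - ncol(W)
  ((rss0 - rss1) / num_df) / (rss1 / den_df)
}

# Just-/over-identified linear IV with heteroskedasticity-robust variance.
# Endogenous regressors first; the covariate block (including intercept) is
# its own instrument. Rows are scaled by sqrt(w) for weighted estimation.
iv_fit <- function(y, X_endog, Z_instr, W, w) {
  sw <- sqrt(w)
  X <- cbind(X_endog, W) * sw
  Z <- cbind(Z_instr, W) * sw
  ys <- y * sw
  k <- ncol(X)
  if (ncol(Z) == k) {
    A <- crossprod(Z, X)
    Ainv <- tryCatch(solve(A), error = function(e) {
      abort("Instrument/exposure cross-moment matrix is numerically singular.")
    })
    beta <- Ainv %*% crossprod(Z, ys)
  } else {
    # over-identified: 2SLS with first-stage projection through a stable QR
    PZX <- stats::lm.fit(Z, X)$fitted.values
    if (is.null(dim(PZX))) PZX <- matrix(PZX, ncol = 1)
    A <- crossprod(PZX, X)
    Ainv <- tryCatch(solve(A), error = function(e) {
      abort("Instrument/exposure cross-moment matrix is numerically singular.")
    })
    beta <- Ainv %*% crossprod(PZX, ys)
    Z <- PZX
  }
  e <- drop(ys - X %*% beta)
  meat <- crossprod(Z * e)
  V <- Ainv %*% meat %*% t(Ainv)
  list(coef = drop(beta), vcov = V, residuals = e)
}

#' Observational (OLS) estimates of exposure effects
#'
#' Weighted linear-probability regression of a binary smoking outcome on the
#' exposures and the covariate adjustment set, with heteroskedasticity-robust
#' (sandwich) standard errors — the observational benchmark against which the
#' MR estimates are compared.
#'
#' @param data Data frame of complete cases.
#' @param outcome Name of the binary outcome column.
#' @param exposures Character vector of exposure column names.
#' @param covariates Character vector of adjustment columns (default none).
#' @param weights Optional positive analysis weights: a column name or a
#'   numeric vector.
#' @return An `mr_estimate` tibble with one row per exposure, method `"OLS"`.
#' @examples
#' cc <- simulate_cohort(sim_params(n_individuals = 2000, seed = 11))
#' ols_estimate(cc$cohort, "smoke_ever", c("edu_years", "cog_score"),
#'   covariates = c("age", "sex")
#' )
#' @export
ols_estimate <- function(data, outcome, exposures, covariates = NULL,
                         weights = NULL) {
  y <- drop(get_columns(data, outcome, "Outcome"))
  X_exp <- get_columns(data, exposures, "Exposure")
  W <- covariate_design(data, covariates)
  w <- resolve_weights(data, weights)
  X <- cbind(X_exp, W)
  if (qr(X)$rank < ncol(X)) {
    abort("Exposures and covariates are collinear.")
  }
  degenerate <- var(y) == 0
  if (degenerate) {
    warn("Outcome has no variance; OLS estimates are degenerate (effects 0, SE 0).")
  }
  fit <- lm(y ~ X - 1, weights = w)
  V <- sandwich::vcovHC(fit, type = "HC1")
  idx <- seq_along(exposures)
  se <- sqrt(pmax(diag(V)[idx], 0))
  new_mr_estimate(
    exposure = exposures, outcome = outcome, method = "OLS",
    effect = unname(coef(fit)[idx]), se = unname(se), n = length(y)
  )
}

#' Univariable Mendelian randomisation by two-stage least squares
#'
#' Instruments a single exposure with its polygenic score and estimates the
#' (total) causal effect on a binary outcome on the risk-difference scale.
#' The model is just-identified, so the estimate equals the covariance ratio
#' cov(z, y)/cov(z, x) after residualising on the covariates. Standard errors
#' come from the instrumental-variable sandwich formula (residuals evaluated
#' at the observed exposure, not the first-stage prediction), which is the
#' correct variance for generated second-stage regressors.
#'
#' @inheritParams ols_estimate
#' @param exposure Name of the exposure column.
#' @param instrument Name of the polygenic-score column.
#' @return An `mr_estimate` row, method `"MR-uni"`, with the first-stage F
#'   statistic in `f_stat`. An F below 10 (the conventional weak-instrument
#'   threshold) triggers a warning.
#' @examples
#' cc <- simulate_cohort(sim_params(n_individuals = 3000, seed = 21))
#' d <- cc$cohort
#' d$score_edu <- compute_prs(cc$dosages, cc$panel, "edu")
#' tsls_univariable(d, "smoke_ever", "edu_years", "score_edu")
#' @export
tsls_univariable <- function(data, outcome, exposure, instrument,
                             covariates = NULL, weights = NULL) {
  y <- drop(get_columns(data, outcome, "Outcome"))
  x <- get_columns(data, exposure, "Exposure")
  z <- get_columns(data, instrument, "Instrument")
  W <- covariate_design(data, covariates)
  w <- resolve_weights(data, weights)
  if (var(drop(z)) == 0) {
    abort("Instrument has no variance.")
  }
  fs <- stats::lm.wfit(x = cbind(z, W), y = drop(x), w = w)
  if (abs(fs$coefficients[1]) < 1e-12) {
    abort("First-stage coefficient of the instrument is zero; the IV estimate is undefined.")
  }
  f_stat <- partial_f(drop(x), z, W, w)
  if (f_stat < 10) {
    warn(sprintf(
      "First-stage F = %.2f is below the conventional value of 10 used to indicate a strong instrument.",
      f_stat
    ))
  }
  fit <- iv_fit(y, x, z, W, w)
  new_mr_estimate(
    exposure = exposure, outcome = outcome, method = "MR-uni",
    effect = fit$coef[1], se = sqrt(fit$vcov[1, 1]), n = length(y),
    f_stat = f_stat
  )
}

#' Multivariable Mendelian randomisation by two-stage least squares
#'
#' Estimates the direct effects of two exposures jointly: each exposure is
#' predicted from both polygenic scores and the covariates, and the outcome is
#' regressed on the two predictions plus covariates. Equivalently (and as
#' implemented) a linear IV fit with two endogenous regressors and two
#' instruments. Reports per-exposure first-stage F (both instruments jointly)
#' and the Sanderson-Windmeijer conditional F, which measures the instruments'
#' ability to predict each exposure over and above the other.
#'
#' @inheritParams ols_estimate
#' @param exposures Character vector of the two exposure columns.
#' @param instruments Character vector of the two score columns.
#' @return An `mr_estimate` tibble with one row per exposure, method
#'   `"MR-multi"`. A conditional F below 10 triggers a warning; score
#'   correlation above 0.999 is an error.
#' @examples
#' cc <- simulate_cohort(sim_params(n_individuals = 3000, seed = 22))
#' d <- cc$cohort
#' d$score_edu <- compute_prs(cc$dosages, cc$panel, "edu")
#' d$score_cog <- compute_prs(cc$dosages, cc$panel, "cog")
#' tsls_multivariable(
#'   d, "smoke_ever", c("edu_years", "cog_score"),
#'   c("score_edu", "score_cog")
#' )
#' @export
tsls_multivariable <- function(data, outcome, exposures, instruments,
                               covariates = NULL, weights = NULL) {
  if (length(exposures) != 2 || length(instruments) != 2) {
    abort("`exposures` and `instruments` must each name two columns.")
  }
  y <- drop(get_columns(data, outcome, "Outcome"))
  X <- get_columns(data, exposures, "Exposure")
  Z <- get_columns(data, instruments, "Instrument")
  W <- covariate_design(data, covariates)
  w <- resolve_weights(data, weights)
  if (abs(stats::cor(Z[, 1], Z[, 2])) > 0.999) {
    abort("Instrument scores are collinear (|correlation| > 0.999).")
  }
  f_stats <- vapply(
    seq_len(2),
    function(j) partial_f(X[, j], Z, W, w),
    numeric(1)
  )
  cf <- conditional_f(
    data, exposures, instruments,
    covariates = covariates, weights = weights
  )
  if (any(cf$cond_f < 10)) {
    warn(sprintf(
      "Conditional F below 10 for %s; multivariable estimates may suffer weak-instrument bias.",
      paste(cf$exposure[cf$cond_f < 10], collapse = ", ")
    ))
  }
  fit <- iv_fit(y, X, Z, W, w)
  new_mr_estimate(
    exposure = exposures, outcome = outcome, method = "MR-multi",
    effect = fit$coef[1:2], se = sqrt(diag(fit$vcov)[1:2]), n = length(y),
    f_stat = f_stats, cond_f = cf$cond_f
  )
}

#' Sanderson-Windmeijer conditional F statistics
#'
#' Instrument strength for each exposure conditional on the other: the target
#' exposure is regressed (by IV) on the other exposure using all instruments,
#' and the F statistic of the instruments' joint significance in predicting
#' the residual is computed with numerator degrees of freedom L - kx + 1
#' (L instruments, kx exposures). With a single exposure this reduces exactly
#' to the standard first-stage F, which pins the degrees-of-freedom scaling.
#' Values above 10 conventionally indicate that the instruments uniquely
#' predict each exposure.
#'
#' @inheritParams ols_estimate
#' @param exposures One or two exposure column names.
#' @param instruments Instrument column names; at least as many as exposures.
#' @return A tibble with columns `exposure` and `cond_f`.
#' @examples
#' cc <- simulate_cohort(sim_params(n_individuals = 3000, seed = 23))
#' d <- cc$cohort
#' d$score_edu <- compute_prs(cc$dosages, cc$panel, "edu")
#' conditional_f(d, "edu_years", "score_edu")
#' @export
conditional_f <- function(data, exposures, instruments, covariates = NULL,
                          weights = NULL) {
  kx <- length(exposures)
  L <- length(instruments)
  if (L < kx) {
    abort("Order condition violated: fewer instruments than exposures.")
  }
  X <- get_columns(data, exposures, "Exposure")
  Z <- get_columns(data, instruments, "Instrument")
  W <- covariate_design(data, covariates)
  w <- resolve_weights(data, weights)
  n <- nrow(X)
  num_df <- L - kx + 1
  den_df <- n - L - ncol(W)
  cond_f <- vapply(seq_len(kx), function(j) {
    if (kx == 1) {
      return(partial_f(X[, 1], Z, W, w))
    }
    others <- X[, -j, drop = FALSE]
    ivf <- iv_fit(X[, j], others, Z, W, w)
    r <- X[, j] - drop(cbind(others, W) %*% ivf$coef)
    rss0 <- wls_rss(W, r, w)
    rss1 <- wls_rss(cbind(Z, W), r, w)
    ((rss0 - rss1) / num_df) / (rss1 / den_df)
  }, numeric(1))
  tibble(exposure = exposures, cond_f = cond_f)
}

#' Rescale a per-unit risk difference to a per-SD risk difference
#'
#' Converts an effect per unit of exposure (e.g. per year of education) into
#' the effect of a one-standard-deviation change, with the absolute percentage
#' form (1 decimal place, half-up) used in narrative reporting.
#'
#' @param effect_per_unit Risk difference per unit exposure (vectorised).
#' @param sd_of_exposure Standard deviation of the exposure in the same units.
#' @return A tibble with `effect_per_unit`, `sd_of_exposure`, `effect_per_sd`
#'   and `percent` (= 100 x |effect_per_sd|, rounded to 1 dp).
#' @examples
#' sd_scale(-0.026, 2.4) # per-SD effect -0.0624, i.e. a 6.2% decrease
#' @export
sd_scale <- function(effect_per_unit, sd_of_exposure) {
  if (any(sd_of_exposure <= 0)) {
    abort("`sd_of_exposure` must be positive.")
  }
  per_sd <- effect_per_unit * sd_of_exposure
  tibble(
    effect_per_unit = effect_per_unit,
    sd_of_exposure = sd_of_exposure,
    effect_per_sd = per_sd,
    percent = round_half_up(100 * abs(per_sd), 1)
  )
}

#' Post-stratification weights from census proportions
#'
#' Weights each education stratum by the ratio of its population share (e.g.
#' from census data) to its share in the analysis sample, so that weighted
#' stratum frequencies reproduce the population distribution — the standard
#' correction for selective participation on education.
#'
#' @param sample_strata,population_strata Named numeric vectors of stratum
#'   proportions over the same strata, each summing to 1.
#' @return A tibble with `stratum`, `sample_prop`, `population_prop`,
#'   `weight` (= population / sample).
#' @examples
#' selection_weights(
#'   c(low = 0.2, mid = 0.4, high = 0.4),
#'   c(low = 0.4, mid = 0.4, high = 0.2)
#' )
#' @export
selection_weights <- function(sample_strata, population_strata) {
  if (is.null(names(sample_strata)) || is.null(names(population_strata)) ||
      !setequal(names(sample_strata), names(population_strata))) {
    abort("Sample and population strata must share the same names.")
  }
  population_strata <- population_strata[names(sample_strata)]
  for (p in list(sample_strata, population_strata)) {
    if (abs(sum(p) - 1) > 1e-6 || any(p < 0)) {
      abort("Stratum proportions must be non-negative and sum to 1.")
    }
  }
  if (any(sample_strata == 0 & population_strata > 0)) {
    abort("A stratum with nonzero population mass is empty in the sample.")
  }
  tibble(
    stratum = names(sample_strata),
    sample_prop = unname(sample_strata),
    population_prop = unname(population_strata),
    weight = unname(ifelse(sample_strata > 0,
      population_strata / sample_strata, 0
    ))
  )
}
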