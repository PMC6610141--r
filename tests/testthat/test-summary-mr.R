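test_that("Wald ratios match hand calculations and the delta-method SE", {
  expect_equal(quiet(wald_ratio(0.5, 0.1, 1.0, 0.01))$ratio, 0.5)
  wr <- wald_ratio(0.2, 0.01, 0.4, 0)
  expect_equal(wr$ratio, 0.5)
  expect_equal(wr$se, 0.01 / 0.4)
  expect_error(wald_ratio(0.1, 0.01, 0, 0.01), "undefined")
  expect_warning(wald_ratio(0.1, 0.01, 0.01, 0.01), "unstable")
})

test_that("the delta-method SE agrees with a parametric bootstrap", {
  gamma <- 0.3
  se_g <- 0.02
  pi <- 0.5
  se_p <- 0.03
  wr <- wald_ratio(gamma, se_g, pi, se_p)
  boot <- withr::with_seed(
    1,
    rnorm(10000, gamma, se_g) / rnorm(10000, pi, se_p)
  )
  expect_equal(wr$se, sd(boot), tolerance = 0.1)
})

test_that("IVW limiting cases: single SNP and equal-weight mean", {
  d1 <- tibble::tibble(
    snp_id = "rs1", pi1_hat = 0.4, se_pi1 = 0.01,
    gamma_hat = 0.2, se_gamma = 0.05, harmonised = TRUE
  )
  est <- ivw_univariable(d1, "edu")
  expect_equal(est$effect, 0.5)
  expect_equal(est$se, 0.05 / 0.4)
  d2 <- tibble::tibble(
    snp_id = c("rs1", "rs2"), pi1_hat = c(0.3, 0.3), se_pi1 = 0.01,
    gamma_hat = c(0.12, 0.18), se_gamma = 0.05, harmonised = TRUE
  )
  est2 <- ivw_univariable(d2, "edu")
  expect_equal(est2$effect, mean(d2$gamma_hat / d2$pi1_hat))
  expect_error(ivw_univariable(d1[0, ], "edu"), "no SNPs")
})

test_that("IVW is null-calibrated on simulated null summary data", {
  s <- analytic_summary(L = 100, beta1 = 0, seed = 3)
  est <- ivw_univariable(s, "edu")
  expect_lt(abs(est$effect), 3 * est$se)
})

test_that("multivariable IVW equals the weighted-least-squares closed form", {
  for (seed in 1:10) {
    s <- analytic_summary(L = 25, beta1 = -0.09, beta2 = 0.12, seed = seed)
    est <- mvmr_ivw(s)
    # independent oracle: explicit matrix WLS
    D <- cbind(s$pi1_hat, s$pi2_hat)
    Wm <- diag(1 / s$se_gamma^2)
    beta <- solve(t(D) %*% Wm %*% D) %*% t(D) %*% Wm %*% s$gamma_hat
    V <- solve(t(D) %*% Wm %*% D)
    expect_equal(est$effect, drop(beta), tolerance = 1e-10)
    expect_equal(est$se, sqrt(diag(V)), tolerance = 1e-10)
  }
})

test_that("just-identified multivariable IVW solves the 2x2 system exactly", {
  s <- analytic_summary(L = 2, beta1 = -0.1, beta2 = 0.2, seed = 5)
  est <- mvmr_ivw(s)
  D <- cbind(s$pi1_hat, s$pi2_hat)
  expect_equal(drop(D %*% est$effect), s$gamma_hat, tolerance = 1e-10)
})

test_that("degenerate and collinear exposure columns are rejected", {
  s <- analytic_summary(L = 10, beta1 = 0.1, seed = 6)
  s$pi2_hat <- 0
  expect_error(mvmr_ivw(s), "identically zero")
  s$pi2_hat <- 2 * s$pi1_hat
  expect_error(mvmr_ivw(s), "collinear")
})

test_that("scale equivariance: rescaling one exposure rescales only its effect", {
  s <- analytic_summary(L = 30, beta1 = -0.09, beta2 = 0.12, seed = 7)
  base <- mvmr_ivw(s)
  s2 <- s
  s2$pi1_hat <- 10 * s2$pi1_hat
  s2$se_pi1 <- 10 * s2$se_pi1
  scaled <- mvmr_ivw(s2)
  expect_equal(scaled$effect[1], base$effect[1] / 10, tolerance = 1e-10)
  expect_equal(scaled$effect[2], base$effect[2], tolerance = 1e-10)
})

test_that("multivariable IVW recovers generating effects from simulated GWAS", {
  # moderate replicate count; the acceptance suite carries the deep version
  res <- sapply(1:40, function(r) {
    p <- summary_params(
      seed = 4400 + r, n_snps_edu = 10, n_snps_cog = 5,
      beta1 = -0.09, beta2 = 0.12, edu_sd = 1.2, baseline_prevalence = 0.5,
      confounder_effects = c(edu = 0.5, cog = 0.3, outcome = 0.05)
    )
    s <- quiet(simulate_two_sample_summary(p, 20000, 20000))
    mvmr_ivw(s)$effect
  })
  mc_se <- apply(res, 1, sd) / sqrt(ncol(res))
  expect_lt(abs(mean(res[1, ]) - (-0.09)), 2 * mc_se[1])
  expect_lt(abs(mean(res[2, ]) - 0.12), 2 * mc_se[2])
})

test_that("MR-Egger order conditions and null intercept behave as documented", {
  expect_error(
    mr_egger(analytic_summary(L = 2, beta1 = 0.1, seed = 8),
      multivariable = FALSE
    ),
    "at least 3"
  )
  expect_error(
    mr_egger(analytic_summary(L = 3, beta1 = 0.1, seed = 8),
      multivariable = TRUE
    ),
    "at least 4"
  )
  s <- analytic_summary(L = 50, beta1 = -0.09, beta2 = 0.12, seed = 9)
  eg <- mr_egger(s, multivariable = TRUE)
  expect_lt(abs(eg$intercept$effect), 3 * eg$intercept$se)
  expect_lt(abs(eg$estimates$effect[1] - (-0.09)), 3 * eg$estimates$se[1])
})

test_that("Egger corrects directional pleiotropy that biases IVW", {
  # InSIDE holds: a constant pleiotropic intercept independent of strength
  s <- analytic_summary(
    L = 60, beta1 = -0.09, intercept = 0.004,
    se_gamma = 0.003, se_pi = 0.002, seed = 10
  )
  ivw <- ivw_univariable(s, "edu")
  eg <- mr_egger(s, multivariable = FALSE, exposure = "edu")
  expect_gt(abs(ivw$effect - (-0.09)), 3 * ivw$se)
  expect_lt(abs(eg$estimates$effect - (-0.09)), 3 * eg$estimates$se)
  expect_gt(abs(eg$intercept$effect), 2 * eg$intercept$se)
})

test_that("Egger detects generator-planted directional pleiotropy", {
  p <- summary_params(
    seed = 31, n_snps_edu = 40, n_snps_cog = 8,
    pleiotropy = c(mean = 0.01, sd = 0.003)
  )
  s <- quiet(simulate_two_sample_summary(p, 50000, 50000))
  # univariable education analysis uses the education-significant SNPs
  s <- s[abs(s$pi1_hat / s$se_pi1) > 5.45, ]
  ivw <- ivw_univariable(s, "edu")
  eg <- mr_egger(s, multivariable = FALSE, exposure = "edu")
  expect_gt(abs(ivw$effect - p$beta1), 3 * ivw$se)
  expect_gt(eg$intercept$effect, 2 * eg$intercept$se)
  expect_lt(abs(eg$estimates$effect - p$beta1), 3 * eg$estimates$se)
})

test_that("odds-ratio conversion is a log-scale round trip", {
  or <- to_odds_ratio(log(0.658), 0.075)
  expect_equal(or$or, 0.658, tolerance = 1e-12)
  or0 <- to_odds_ratio(0, 0.1)
  expect_equal(or0$or, 1)
  # CI symmetric on the log scale: endpoints multiply to exp(2 * effect)
  expect_equal(or$or_lower * or$or_upper, exp(2 * log(0.658)),
    tolerance = 1e-12
  )
})
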