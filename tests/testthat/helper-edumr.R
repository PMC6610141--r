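# Shared fixtures: small simulated cohorts and quiet wrappers. Everything is
# generated in code at test time; no stored data.

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

small_params <- function(n = 2000, seed = 1, ...) {
  sim_params(n_individuals = n, seed = seed, ...)
}

# Cohort with scores and the interaction column attached, ready for the
# individual-level estimators.
scored_cohort <- function(params) {
  cc <- quiet(simulate_cohort(params))
  d <- cc$cohort
  d$score_edu <- compute_prs(cc$dosages, cc$panel, "edu")
  d$score_cog <- compute_prs(cc$dosages, cc$panel, "cog")
  d$sex_x_year_of_birth <- d$sex * d$year_of_birth
  list(data = d, cohort = cc)
}

# Summary-experiment parameter sets use per-SNP instrument strength at the
# genome-wide-significance level (per-SNP F well above 30), as the pruned
# significant SNPs feeding a real two-sample analysis would have.
summary_params <- function(seed, n_snps_edu = 30, n_snps_cog = 10, ...) {
  sim_params(
    n_snps_edu = n_snps_edu, n_snps_cog = n_snps_cog,
    r2_edu = 0.15, r2_cog = 0.05, seed = seed, ...
  )
}

# Analytic summary-data generator used as an independent route for estimator
# checks: draws directly from the measurement model rather than from cohorts.
analytic_summary <- function(L, beta1, beta2 = 0, se_gamma = 0.005,
                             se_pi = 0.005, pi_sd = 0.1, intercept = 0,
                             seed = 1) {
  withr::with_seed(seed, {
    pi1 <- rnorm(L, 0, pi_sd)
    pi2 <- rnorm(L, 0, pi_sd)
    tibble::tibble(
      snp_id = sprintf("rs%04d", seq_len(L)),
      pi1_hat = pi1 + rnorm(L, 0, se_pi), se_pi1 = se_pi,
      pi2_hat = pi2 + rnorm(L, 0, se_pi), se_pi2 = se_pi,
      # directional pleiotropy acts on the trait-increasing allele, so the
      # planted intercept is aligned with the orientation Egger will apply
      gamma_hat = intercept * sign(pi1) + beta1 * pi1 + beta2 * pi2 +
        rnorm(L, 0, se_gamma),
      se_gamma = se_gamma,
      harmonised = TRUE
    )
  })
}
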