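#' Simulation parameters for the causal smoking DAGs
#'
#' Bundles every structural coefficient of the generating causal diagrams used
#' by [simulate_cohort()] and [simulate_two_sample_summary()]: the direct
#' effects of educational attainment and cognitive ability on smoking, the two
#' alternative mediation structures (education affecting cognition, or
#' cognition affecting education — at most one may be active), latent
#' confounding, directional pleiotropy, dynastic effects through parental
#' education, and a participation (selection) model.
#'
#' The defaults emulate the cohort the estimators were designed for: about
#' 120,050 individuals; years of education with standard deviation 2.4 around a
#' mean of 18.3 years; a standardized cognitive score; smoking initiation
#' prevalence near 43.8% and cessation (former among ever) near 82.4%, which
#' together give a current-smoking prevalence near 7.7%; and polygenic-score
#' instruments explaining ~0.46% (education, 74 SNPs) and ~0.74% (cognition,
#' 18 SNPs) of exposure variance, so that first-stage F statistics at the
#' default sample size land in the several hundreds.
#'
#' @param n_individuals Number of individuals in a simulated cohort.
#' @param n_snps_edu,n_snps_cog Number of SNPs with direct effects on education
#'   and on cognitive ability.
#' @param maf_range Length-2 numeric, the range of minor-allele frequencies;
#'   must lie within (0.01, 0.5).
#' @param beta1 Direct effect of education on smoking initiation
#'   (risk difference per year of education).
#' @param beta2 Direct effect of cognitive ability on smoking initiation
#'   (risk difference per SD of the cognitive score).
#' @param alpha_E Effect of education on cognitive ability (SD per year);
#'   nonzero selects the education-to-cognition mediation diagram.
#' @param alpha_CA Effect of cognitive ability on education (years per SD);
#'   nonzero selects the cognition-to-education mediation diagram. At most one
#'   of `alpha_E`, `alpha_CA` may be nonzero.
#' @param confounder_effects Named numeric of loadings of a latent standard
#'   normal confounder U on `edu` (years), `cog` (SD) and `outcome`
#'   (probability).
#' @param pleiotropy Named numeric `c(mean = , sd = )`: distribution of per-SNP
#'   direct effects on the outcome. A nonzero mean encodes directional
#'   pleiotropy.
#' @param dynastic_effect Effect of mid-parental education (years, centered) on
#'   offspring smoking not mediated by offspring education. Nonzero switches
#'   the generator to explicit parental genotypes with Mendelian transmission
#'   of one allele per parent per SNP.
#' @param selection_model Named numeric `c(intercept = , edu = , smoking = )`:
#'   logistic participation propensity used by [apply_selection()].
#' @param baseline_prevalence Intercept probability of smoking initiation.
#' @param baseline_cessation Intercept probability of being a former smoker
#'   among ever smokers.
#' @param r2_edu,r2_cog Variance in each exposure explained by its SNP score.
#' @param edu_mean,edu_sd Mean and SD of years of education.
#' @param n_pcs Number of (pure-noise) genetic principal component columns.
#' @param sex_effect Risk difference between sexes for smoking initiation,
#'   included so covariate adjustment is exercised by a real (if exogenous)
#'   association.
#' @param seed Integer root seed. All random streams of the generator are
#'   derived from it deterministically, so identical parameters and seed give
#'   bit-identical output.
#'
#' @return A list of class `sim_params`.
#' @examples
#' p <- sim_params(n_individuals = 1000, seed = 7)
#' p$beta1
#' @export
sim_params <- function(n_individuals = 120050,
                       n_snps_edu = 74,
                       n_snps_cog = 18,
                       maf_range = c(0.05, 0.45),
                       beta1 = -0.04,
                       beta2 = 0,
                       alpha_E = 0,
                       alpha_CA = 0,
                       confounder_effects = c(edu = 0.8, cog = 0.3, outcome = 0.08),
                       pleiotropy = c(mean = 0, sd = 0),
                       dynastic_effect = 0,
                       selection_model = c(intercept = 0, edu = 0, smoking = 0),
                       baseline_prevalence = 0.438,
                       baseline_cessation = 0.824,
                       r2_edu = 0.0046,
                       r2_cog = 0.0074,
                       edu_mean = 18.3,
                       edu_sd = 2.4,
                       n_pcs = 10,
                       sex_effect = 0.04,
                       seed = 1L) {
  params <- list(
    n_individuals = n_individuals, n_snps_edu = n_snps_edu,
    n_snps_cog = n_snps_cog, maf_range = maf_range, beta1 = beta1,
    beta2 = beta2, alpha_E = alpha_E, alpha_CA = alpha_CA,
    confounder_effects = confounder_effects, pleiotropy = pleiotropy,
    dynastic_effect = dynastic_effect, selection_model = selection_model,
    baseline_prevalence = baseline_prevalence,
    baseline_cessation = baseline_cessation,
    r2_edu = r2_edu, r2_cog = r2_cog, edu_mean = edu_mean, edu_sd = edu_sd,
    n_pcs = n_pcs, sex_effect = sex_effect, seed = seed
  )
  class(params) <- "sim_params"
  validate_sim_params(params)
}

validate_sim_params <- function(p) {
  check_number(p$n_individuals, "n_individuals", lower = 2)
  check_number(p$n_snps_edu, "n_snps_edu", lower = 1)
  check_number(p$n_snps_cog, "n_snps_cog", lower = 1)
  if (length(p$maf_range) != 2 || p$maf_range[1] > p$maf_range[2]) {
    abort("`maf_range` must be an increasing pair of allele frequencies.")
  }
  if (p$maf_range[1] <= 0.01 || p$maf_range[2] >= 0.5) {
    abort("`maf_range` must lie strictly within (0.01, 0.5).")
  }
  if (p$alpha_E != 0 && p$alpha_CA != 0) {
    abort(paste(
      "At most one of `alpha_E` and `alpha_CA` may be nonzero:",
      "the two mediation diagrams are alternatives, not a cycle."
    ))
  }
  for (nm in c("edu", "cog", "outcome")) {
    if (!nm %in% names(p$confounder_effects)) {
      abort(sprintf("`confounder_effects` must contain '%s'.", nm))
    }
  }
  if (!all(c("mean", "sd") %in% names(p$pleiotropy)) || p$pleiotropy[["sd"]] < 0) {
    abort("`pleiotropy` must be c(mean = , sd = ) with sd >= 0.")
  }
  if (!all(c("intercept", "edu", "smoking") %in% names(p$selection_model))) {
    abort("`selection_model` must contain intercept, edu and smoking.")
  }
  check_number(p$baseline_prevalence, "baseline_prevalence", 0, 1)
  check_number(p$baseline_cessation, "baseline_cessation", 0, 1)
  check_number(p$r2_edu, "r2_edu", 0, 0.5)
  check_number(p$r2_cog, "r2_cog", 0, 0.5)
  check_number(p$edu_sd, "edu_sd", lower = 1e-8)
  check_number(p$n_pcs, "n_pcs", lower = 0)
  check_number(p$seed, "seed")
  p
}

#' @export
print.sim_params <- function(x, ...) {
  dag <- if (x$alpha_E != 0) {
    sprintf("education -> cognition (alpha_E = %g)", x$alpha_E)
  } else if (x$alpha_CA != 0) {
    sprintf("cognition -> education (alpha_CA = %g)", x$alpha_CA)
  } else {
    "no mediation between exposures"
  }
  cat("<sim_params>\n")
  cat(sprintf("  n = %s; SNPs: %d education + %d cognition\n",
              format(x$n_individuals, big.mark = ","),
              x$n_snps_edu, x$n_snps_cog))
  cat(sprintf("  direct effects: beta1 = %g (per year), beta2 = %g (per SD)\n",
              x$beta1, x$beta2))
  cat("  DAG:", dag, "\n")
  cat(sprintf("  pleiotropy mean %g sd %g; dynastic %g; seed %s\n",
              x$pleiotropy[["mean"]], x$pleiotropy[["sd"]],
              x$dynastic_effect, format(x$seed)))
  invisible(x)
}
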