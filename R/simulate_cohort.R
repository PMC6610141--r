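#' Simulate an individual-level cohort under an explicit causal diagram
#'
#' Generates SNP dosages, covariates, two correlated continuous exposures
#' (years of education and a standardized cognitive score), and three nested
#' binary smoking outcomes (current, ever, former-among-ever) from a
#' linear-probability structural model. The generating SNP weights are
#' returned, so instruments are known and every downstream estimator can be
#' checked by parameter recovery.
#'
#' The structural equations are, with `U` a latent standard-normal confounder
#' and centered genetic scores `g_E`, `g_C`:
#' \deqn{E = \mu_E + g_E + \alpha_{CA} C + c_E U + e_E}
#' \deqn{C = g_C + \alpha_E (E - \mu_E) + c_C U + e_C}
#' \deqn{P(ever) = p_0 + \beta_1 (E - \mu_E) + \beta_2 C + c_S U + pleio + dyn}
#' with probabilities clamped to \[0, 1\]. Cessation among ever smokers uses
#' intercept `baseline_cessation` and coefficients `-(beta1, beta2)/2`, so
#' education increases quitting when it decreases initiation. Current smoker =
#' ever smoker and not former. Only the equation selected by the active
#' mediation parameter is used; residual variances are chosen so the exposures
#' hit their target marginal variances when the structural contributions leave
#' room (otherwise a 5% noise floor applies and the realized SD exceeds the
#' target).
#'
#' When `dynastic_effect != 0`, parental genotypes are generated first and each
#' offspring dosage is built by transmitting one allele per parent per SNP;
#' mid-parental education (computed from parental genotype) then enters the
#' offspring outcome directly.
#'
#' @param params A [sim_params()] object.
#' @param panel Optional pre-built generating panel (as returned in the
#'   `panel` element), so several independent samples — e.g. the exposure and
#'   outcome GWAS of a two-sample design — share the same SNPs and weights.
#'   By default a fresh panel is drawn from the parameter seed.
#' @return A list of class `mr_cohort` with elements `cohort` (tibble of
#'   covariates, exposures, outcomes and analysis weights), `dosages`
#'   (n x m integer matrix, columns named by SNP id), `panel` (tibble of
#'   generating SNP weights in GWAS-summary layout), `params`, and `meta`
#'   (clamp fractions and realized prevalences).
#' @examples
#' cc <- simulate_cohort(sim_params(n_individuals = 500, seed = 3))
#' cc$cohort
#' @export
simulate_cohort <- function(params, panel = NULL) {
  stopifnot(inherits(params, "sim_params"))
  validate_sim_params(params)
  p <- params
  n <- as.integer(p$n_individuals)
  m1 <- as.integer(p$n_snps_edu)
  m2 <- as.integer(p$n_snps_cog)
  m <- m1 + m2

  if (is.null(panel)) {
    panel <- with_seed(substream_seed(p$seed, "dosages"), make_true_panel(p))
  }
  stopifnot(nrow(panel) == m)

  if (p$dynastic_effect != 0) {
    fam <- with_seed(
      substream_seed(p$seed, "parents"),
      draw_dynastic_genotypes(n, panel$maf)
    )
    G <- fam$offspring
  } else {
    G <- with_seed(
      substream_seed(p$seed, "dosages") + 1L,
      draw_dosages(n, panel$maf)
    )
    fam <- NULL
  }
  colnames(G) <- panel$snp_id

  U <- with_seed(substream_seed(p$seed, "confounder"), rnorm(n))

  # centered genetic score contributions
  centering <- 2 * panel$maf
  Gc <- sweep(G, 2, centering)
  g_edu <- drop(Gc %*% panel$weight_edu)
  g_cog <- drop(Gc %*% panel$weight_cog)

  ce <- p$confounder_effects[["edu"]]
  cc <- p$confounder_effects[["cog"]]
  cs <- p$confounder_effects[["outcome"]]
  var_edu <- p$edu_sd^2
  var_cog <- 1

  noise_var <- function(target, structural) {
    floor_var <- 0.05 * target
    v <- target - structural
    if (v < floor_var) {
      inform(paste(
        "Structural variance exceeds the marginal target for an exposure;",
        "using the 5% noise floor, the realized SD will exceed the target."
      ))
      v <- floor_var
    }
    v
  }

  if (p$alpha_CA != 0) {
    # cognition -> education diagram
    v_cog <- noise_var(var_cog, p$r2_cog * var_cog + cc^2)
    cog <- g_cog + cc * U +
      with_seed(substream_seed(p$seed, "cog"), rnorm(n, sd = sqrt(v_cog)))
    v_edu <- noise_var(
      var_edu,
      p$r2_edu * var_edu + ce^2 + p$alpha_CA^2 * var_cog
    )
    edu <- p$edu_mean + g_edu + p$alpha_CA * cog + ce * U +
      with_seed(substream_seed(p$seed, "edu"), rnorm(n, sd = sqrt(v_edu)))
  } else {
    v_edu <- noise_var(var_edu, p$r2_edu * var_edu + ce^2)
    edu <- p$edu_mean + g_edu + ce * U +
      with_seed(substream_seed(p$seed, "edu"), rnorm(n, sd = sqrt(v_edu)))
    v_cog <- noise_var(
      var_cog,
      p$r2_cog * var_cog + cc^2 + p$alpha_E^2 * var_edu
    )
    cog <- g_cog + p$alpha_E * (edu - p$edu_mean) + cc * U +
      with_seed(substream_seed(p$seed, "cog"), rnorm(n, sd = sqrt(v_cog)))
  }

  pleio_term <- 0
  if (p$pleiotropy[["sd"]] > 0 || p$pleiotropy[["mean"]] != 0) {
    # direct effects are oriented on each SNP's trait-increasing allele, so a
    # nonzero mean is directional pleiotropy surviving allele re-orientation
    snp_sign <- sign(panel$weight_edu + panel$weight_cog)
    a <- with_seed(
      substream_seed(p$seed, "dosages") + 2L,
      rnorm(m, mean = p$pleiotropy[["mean"]], sd = p$pleiotropy[["sd"]])
    )
    pleio_term <- drop(Gc %*% (a * snp_sign))
  }

  dyn_term <- 0
  if (!is.null(fam)) {
    noise_p <- with_seed(
      substream_seed(p$seed, "parents") + 1L,
      matrix(rnorm(2 * n, sd = sqrt(v_edu)), n, 2)
    )
    edu_mother <- parental_education(fam$mother, panel, p, noise_p[, 1])
    edu_father <- parental_education(fam$father, panel, p, noise_p[, 2])
    dyn_term <- p$dynastic_effect * ((edu_mother + edu_father) / 2 - p$edu_mean)
  }

  cov_seed <- substream_seed(p$seed, "covariates")
  covars <- with_seed(cov_seed, {
    age <- sample(40:69, n, replace = TRUE)
    recruit_year <- sample(2006:2010, n, replace = TRUE)
    sex <- rbinom(n, 1, 0.5)
    pcs <- if (p$n_pcs > 0) {
      matrix(rnorm(n * p$n_pcs), n,
        dimnames = list(NULL, paste0("pc", seq_len(p$n_pcs)))
      )
    } else {
      NULL
    }
    list(age = age, sex = sex, year_of_birth = recruit_year - age, pcs = pcs)
  })

  edu_c <- edu - p$edu_mean
  linpred <- p$beta1 * edu_c + p$beta2 * cog + cs * U + pleio_term + dyn_term +
    p$sex_effect * (covars$sex - 0.5)
  p_ever <- p$baseline_prevalence + linpred
  p_cess <- p$baseline_cessation - 0.5 * (p$beta1 * edu_c + p$beta2 * cog) -
    0.5 * cs * U
  clamp_frac <- mean(p_ever < 0 | p_ever > 1 | p_cess < 0 | p_cess > 1)
  if (clamp_frac > 0.01) {
    warn(sprintf(
      "Outcome probability clamp activated for %.1f%% of individuals; structural coefficients push probabilities outside [0, 1].",
      100 * clamp_frac
    ))
  }
  p_ever <- pmin(pmax(p_ever, 0), 1)
  p_cess <- pmin(pmax(p_cess, 0), 1)

  outc <- with_seed(substream_seed(p$seed, "outcome"), {
    ever <- rbinom(n, 1, p_ever)
    former <- rep(NA_integer_, n)
    former[ever == 1] <- rbinom(sum(ever == 1), 1, p_cess[ever == 1])
    list(ever = ever, former = former)
  })
  smoke_ever <- outc$ever
  smoke_former <- outc$former
  smoke_current <- ifelse(smoke_ever == 1L, 1L - smoke_former, 0L)

  cohort <- tibble(
    id = seq_len(n),
    age = covars$age,
    sex = covars$sex,
    year_of_birth = covars$year_of_birth,
    edu_years = edu,
    cog_score = cog,
    smoke_current = smoke_current,
    smoke_ever = smoke_ever,
    smoke_former = smoke_former,
    weight = 1
  )
  if (!is.null(covars$pcs)) {
    cohort <- dplyr::bind_cols(cohort, as_tibble(covars$pcs))
  }

  out <- list(
    cohort = cohort,
    dosages = G,
    panel = panel,
    params = p,
    meta = list(
      clamp_fraction = clamp_frac,
      prevalence = c(
        current = mean(smoke_current),
        ever = mean(smoke_ever),
        former_among_ever = mean(smoke_former[smoke_ever == 1])
      ),
      confounder = U
    )
  )
  class(out) <- "mr_cohort"
  out
}

#' @export
print.mr_cohort <- function(x, ...) {
  cat("<mr_cohort>\n")
  cat(sprintf(
    "  %s individuals, %d SNPs (%d education + %d cognition)\n",
    format(nrow(x$cohort), big.mark = ","), ncol(x$dosages),
    x$params$n_snps_edu, x$params$n_snps_cog
  ))
  pv <- x$meta$prevalence
  cat(sprintf(
    "  prevalence: current %.1f%%, ever %.1f%%, former|ever %.1f%%\n",
    100 * pv[["current"]], 100 * pv[["ever"]], 100 * pv[["former_among_ever"]]
  ))
  invisible(x)
}

# SNP panel with generating weights scaled so each score explains its target
# share of exposure variance. Alleles are drawn non-palindromic so strand is
# unambiguous in simulated data.
make_true_panel <- function(p) {
  m1 <- as.integer(p$n_snps_edu)
  m2 <- as.integer(p$n_snps_cog)
  m <- m1 + m2
  maf <- runif(m, p$maf_range[1], p$maf_range[2])
  het <- 2 * maf * (1 - maf)

  scale_weights <- function(raw, het, target_var) {
    if (target_var <= 0) return(raw * 0)
    raw * sqrt(target_var / sum(het * raw^2))
  }
  w_edu <- rep(0, m)
  w_cog <- rep(0, m)
  idx_edu <- seq_len(m1)
  idx_cog <- m1 + seq_len(m2)
  w_edu[idx_edu] <- scale_weights(rnorm(m1), het[idx_edu], p$r2_edu * p$edu_sd^2)
  w_cog[idx_cog] <- scale_weights(rnorm(m2), het[idx_cog], p$r2_cog * 1)

  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  eff <- sample(bases, m, replace = TRUE)
  oth <- vapply(eff, function(b) {
    sample(setdiff(bases, c(b, comp[[b]])), 1)
  }, character(1))

  tibble(
    snp_id = sprintf("rs%05d", seq_len(m)),
    effect_allele = eff,
    other_allele = unname(oth),
    maf = maf,
    weight_edu = w_edu,
    weight_cog = w_cog,
    pval_edu = ifelse(w_edu != 0, 1e-8, 1),
    pval_cog = ifelse(w_cog != 0, 1e-8, 1)
  )
}

draw_dosages <- function(n, maf) {
  m <- length(maf)
  matrix(rbinom(n * m, 2L, rep(maf, each = n)), nrow = n, ncol = m)
}

# Explicit parent -> offspring transmission: one allele per parent per SNP,
# transmitted with probability dosage/2. Parental education is computed from
# parental genotype with the same weights plus independent noise.
draw_dynastic_genotypes <- function(n, maf) {
  m <- length(maf)
  Gm <- draw_dosages(n, maf)
  Gf <- draw_dosages(n, maf)
  transmit <- function(Gp) {
    matrix(rbinom(n * m, 1L, as.vector(Gp) / 2), nrow = n, ncol = m)
  }
  offspring <- transmit(Gm) + transmit(Gf)
  list(offspring = offspring, mother = Gm, father = Gf)
}

# Parental education used by the dynastic path: genetic part + noise only,
# evaluated lazily inside simulate_cohort where weights are known.
parental_education <- function(Gp, panel, p, noise) {
  centering <- 2 * panel$maf
  g <- drop(sweep(Gp, 2, centering) %*% panel$weight_edu)
  p$edu_mean + g + noise
}
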