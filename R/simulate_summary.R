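#' Simulate two-sample GWAS summary statistics
#'
#' Draws three mutually independent cohorts from the same generating diagram —
#' one for the education GWAS, one for the cognition GWAS, one for the outcome
#' GWAS — and computes per-SNP marginal association coefficients and standard
#' errors by single-SNP regression in each. The non-overlap between samples
#' mirrors the two-sample design in which exposure and outcome associations
#' come from disjoint studies.
#'
#' @param params A [sim_params()] object; its seed drives three disjoint
#'   random streams, one per GWAS sample.
#' @param n_gwas_exposure Sample size of each exposure GWAS.
#' @param n_gwas_outcome Sample size of the outcome GWAS.
#' @param scale `"rd"` for linear (risk-difference) outcome associations, or
#'   `"logodds"` for per-SNP logistic regressions.
#' @param outcome Which smoking phenotype the outcome GWAS measures. For
#'   `"former"` the outcome sample is restricted to ever smokers.
#' @return A tibble of class `summary_dataset` with columns `snp_id`,
#'   `effect_allele`, `other_allele`, `pi1_hat`, `se_pi1`, `pi2_hat`, `se_pi2`,
#'   `gamma_hat`, `se_gamma`, `harmonised`; attributes `n_exposure`,
#'   `n_outcome`, `scale`, `outcome`. SNPs monomorphic in any sample are
#'   excluded with a message.
#' @examples
#' p <- sim_params(n_snps_edu = 5, n_snps_cog = 3, seed = 2)
#' simulate_two_sample_summary(p, n_gwas_exposure = 500, n_gwas_outcome = 500)
#' @export
simulate_two_sample_summary <- function(params,
                                        n_gwas_exposure,
                                        n_gwas_outcome,
                                        scale = c("rd", "logodds"),
                                        outcome = c("ever", "current", "former")) {
  stopifnot(inherits(params, "sim_params"))
  scale <- match.arg(scale)
  outcome <- match.arg(outcome)
  check_number(n_gwas_exposure, "n_gwas_exposure", lower = 10)
  check_number(n_gwas_outcome, "n_gwas_outcome", lower = 10)

  sample_params <- function(stream, n) {
    q <- params
    q$n_individuals <- n
    q$seed <- substream_seed(params$seed, stream)
    class(q) <- "sim_params"
    q
  }
  shared_panel <- with_seed(
    substream_seed(params$seed, "dosages"),
    make_true_panel(params)
  )
  edu_cc <- simulate_cohort(sample_params("gwas_exposure1", n_gwas_exposure),
    panel = shared_panel
  )
  cog_cc <- simulate_cohort(sample_params("gwas_exposure2", n_gwas_exposure),
    panel = shared_panel
  )
  out_cc <- simulate_cohort(sample_params("gwas_outcome", n_gwas_outcome),
    panel = shared_panel
  )

  y_out <- switch(outcome,
    ever = out_cc$cohort$smoke_ever,
    current = out_cc$cohort$smoke_current,
    former = out_cc$cohort$smoke_former
  )
  G_out <- out_cc$dosages
  if (outcome == "former") {
    keep <- !is.na(y_out)
    y_out <- y_out[keep]
    G_out <- G_out[keep, , drop = FALSE]
  }

  a1 <- marginal_assoc_linear(edu_cc$cohort$edu_years, edu_cc$dosages)
  a2 <- marginal_assoc_linear(cog_cc$cohort$cog_score, cog_cc$dosages)
  a3 <- if (scale == "rd") {
    marginal_assoc_linear(y_out, G_out)
  } else {
    marginal_assoc_logistic(y_out, G_out)
  }

  poly <- !(a1$monomorphic | a2$monomorphic | a3$monomorphic)
  if (any(!poly)) {
    inform(sprintf(
      "Excluded %d SNP(s) monomorphic in at least one simulated sample.",
      sum(!poly)
    ))
  }

  panel <- edu_cc$panel
  out <- tibble(
    snp_id = panel$snp_id,
    effect_allele = panel$effect_allele,
    other_allele = panel$other_allele,
    pi1_hat = a1$beta, se_pi1 = a1$se,
    pi2_hat = a2$beta, se_pi2 = a2$se,
    gamma_hat = a3$beta, se_gamma = a3$se,
    pval_pi1 = a1$pval, pval_pi2 = a2$pval, pval_gamma = a3$pval,
    harmonised = TRUE
  )[poly, ]
  structure(
    out,
    class = c("summary_dataset", class(out)),
    n_exposure = n_gwas_exposure,
    n_outcome = length(y_out),
    scale = scale,
    outcome = outcome,
    params = params
  )
}

# Vectorised per-SNP simple linear regression with intercept:
# beta_j = Sxy/Sxx, se^2 = (Syy - beta^2 Sxx) / ((n - 2) Sxx).
marginal_assoc_linear <- function(y, G) {
  n <- length(y)
  yc <- y - mean(y)
  mu <- unname(colMeans(G))
  sxx <- unname(colSums(G^2)) - n * mu^2
  mono <- sxx <= 0
  sxx[mono] <- NA_real_
  sxy <- unname(drop(crossprod(G, yc)))
  beta <- sxy / sxx
  syy <- sum(yc^2)
  sse <- pmax(syy - beta^2 * sxx, 0)
  se <- sqrt(sse / ((n - 2) * sxx))
  tval <- beta / se
  list(
    beta = beta, se = se,
    pval = 2 * pt(-abs(tval), df = n - 2),
    monomorphic = mono
  )
}

# Vectorised per-SNP logistic regression (intercept + dosage) by Newton
# iteration run in parallel across SNPs; each SNP has its own 2x2 Fisher
# information solved in closed form.
marginal_assoc_logistic <- function(y, G, iter = 12L) {
  n <- length(y)
  m <- ncol(G)
  mu <- colMeans(G)
  sxx <- colSums(G^2) - n * mu^2
  mono <- sxx <= 0
  a <- rep(stats::qlogis(pmin(pmax(mean(y), 1e-6), 1 - 1e-6)), m)
  b <- rep(0, m)
  for (it in seq_len(iter)) {
    eta <- outer(rep(1, n), a) + sweep(G, 2, b, `*`)
    pr <- plogis(eta)
    w <- pr * (1 - pr)
    r <- y - pr
    u1 <- colSums(r)
    u2 <- colSums(r * G)
    i11 <- colSums(w)
    i12 <- colSums(w * G)
    i22 <- colSums(w * G^2)
    det <- i11 * i22 - i12^2
    det[det <= 0 | mono] <- NA_real_
    da <- (i22 * u1 - i12 * u2) / det
    db <- (i11 * u2 - i12 * u1) / det
    a <- a + da
    b <- b + db
    if (all(abs(c(da, db)) < 1e-10, na.rm = TRUE)) break
  }
  eta <- outer(rep(1, n), a) + sweep(G, 2, b, `*`)
  pr <- plogis(eta)
  w <- pr * (1 - pr)
  i11 <- colSums(w)
  i12 <- colSums(w * G)
  i22 <- colSums(w * G^2)
  det <- i11 * i22 - i12^2
  det[det <= 0 | mono] <- NA_real_
  se <- sqrt(i11 / det)
  list(
    beta = unname(b), se = unname(se), pval = unname(z_pvalue(b / se)),
    monomorphic = unname(mono | !is.finite(b))
  )
}

#' Apply a participation (selection) filter to a simulated cohort
#'
#' Individuals are retained with a probability that is logistic in centered
#' years of education and current smoking status, emulating self-selection
#' into a volunteer cohort. Conditioning on such participation opens a
#' collider path between education and smoking, so associations in the
#' selected subset can differ from the full cohort; the returned participation
#' probabilities are the ground truth needed to test re-weighting.
#'
#' @param cohort An `mr_cohort` from [simulate_cohort()].
#' @param params A [sim_params()] whose `selection_model` supplies
#'   `c(intercept = , edu = , smoking = )` on the log-odds scale. With all
#'   coefficients zero every individual has the same retention probability and
#'   selection is uniform.
#' @return A list with `cohort` (the selected `mr_cohort`), `prob` (the
#'   participation probability of every individual in the input), and `kept`
#'   (logical index).
#' @examples
#' cc <- simulate_cohort(sim_params(n_individuals = 400, seed = 5))
#' sel <- apply_selection(cc, sim_params(
#'   n_individuals = 400,
#'   selection_model = c(intercept = 0.5, edu = 0.2, smoking = -0.5)
#' ))
#' @export
apply_selection <- function(cohort, params) {
  stopifnot(inherits(cohort, "mr_cohort"), inherits(params, "sim_params"))
  sm <- params$selection_model
  edu_c <- cohort$cohort$edu_years - params$edu_mean
  eta <- sm[["intercept"]] + sm[["edu"]] * edu_c +
    sm[["smoking"]] * cohort$cohort$smoke_current
  prob <- plogis(eta)
  kept <- with_seed(
    substream_seed(params$seed, "selection"),
    rbinom(length(prob), 1, prob) == 1
  )
  if (!any(kept)) {
    abort("Selection removed every individual; relax the selection model.")
  }
  out <- cohort
  out$cohort <- cohort$cohort[kept, , drop = FALSE]
  out$dosages <- cohort$dosages[kept, , drop = FALSE]
  out$meta$confounder <- cohort$meta$confounder[kept]
  out$meta$prevalence <- c(
    current = mean(out$cohort$smoke_current),
    ever = mean(out$cohort$smoke_ever),
    former_among_ever = mean(
      out$cohort$smoke_former[out$cohort$smoke_ever == 1]
    )
  )
  list(cohort = out, prob = prob, kept = kept)
}
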