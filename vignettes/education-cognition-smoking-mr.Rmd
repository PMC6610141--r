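---
title: "Estimating direct effects of education and cognition on smoking with multivariable Mendelian randomisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating direct effects of education and cognition on smoking with multivariable Mendelian randomisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edumr)
```

## The scientific problem

Educational attainment and general cognitive ability are strongly correlated,
and both are observationally associated with smoking. The question this
package addresses is whether more years of education reduce smoking *per se*,
or whether the association is driven by cognitive ability acting on both.
Mendelian randomisation (MR) approaches this as an instrumental-variable
problem: genetic variants associated with an exposure are randomly allocated
at conception, so — under the instrumental-variable assumptions of relevance
(IV1), independence from confounders (IV2) and exclusion (IV3) — they can
identify causal effects free of the confounding that contaminates
observational regressions.

Univariable MR of one exposure estimates its **total** effect. If cognition
mediates part of education's effect (education → cognition → smoking, with
mediation slope $\alpha_E$), the univariable education estimate converges to
$\beta_1 + \alpha_E\beta_2$, where $\beta_1,\beta_2$ are the direct effects of
education and cognition on smoking. Symmetrically, if education mediates
cognition's effect ($\alpha_{CA}$: cognition → education), univariable
cognition MR estimates $\beta_2 + \alpha_{CA}\beta_1$. Multivariable MR
(MVMR) instruments both exposures jointly and estimates the **direct**
effects $(\beta_1, \beta_2)$ without needing to know which mediation diagram
is true.

## Estimators

### Individual level

Outcomes are binary smoking phenotypes (current smoker; ever smoker; former
smoker among ever smokers), modelled with a linear probability model so that
effects are risk differences — per year of education and per SD of the
cognitive score. `ols_estimate()` gives the observational benchmark.
`tsls_univariable()` and `tsls_multivariable()` implement two-stage least
squares with polygenic scores as instruments: each exposure is predicted from
the score(s) and the controls (age, sex, year of birth, sex × year of birth,
leading genetic principal components), and the outcome is regressed on the
predictions. Standard errors come from the heteroskedasticity-robust
instrumental-variable sandwich formula, with residuals evaluated at the
*observed* exposures — the naive second-stage OLS variance is wrong for
generated regressors, and linear-probability residuals are intrinsically
heteroskedastic, so robust IV variances are the default and only option.

Instrument strength is reported two ways. The first-stage partial F tests the
instruments jointly in each exposure's first stage. The Sanderson–Windmeijer
conditional F asks the sharper question for MVMR: can the instruments predict
each exposure *over and above* the other exposure? `conditional_f()`
instruments the other exposure, takes the residual of the target exposure
from that fit, and F-tests the instruments against the residual with
numerator degrees of freedom $L - k_x + 1$ ($L$ instruments, $k_x$
exposures). The scaling is pinned by an exact reduction: with one exposure
the statistic *equals* the standard first-stage partial F (a unit test
asserts this against `anova()`). Values above 10 are conventionally taken as
adequate; highly correlated instrument scores can make the conditional F
collapse while every unconditional F stays large, and the test suite
demonstrates this monotone collapse on a collinearity grid.

### Summary level

Two-sample summary-data MR regresses per-SNP outcome associations
$\hat\Gamma_j$ on exposure associations, with inverse-variance weights
$1/se^2_{\Gamma j}$:

$$\hat\Gamma_j = \beta_1\hat\pi_{1j} + \beta_2\hat\pi_{2j} + v_j$$

through the origin (`ivw_univariable()`, `mvmr_ivw()`). Fixed-effect
(dispersion 1) standard errors are the default so that the estimator is
exactly the stated weighted regression; a multiplicative overdispersion
inflation (`overdispersion = TRUE`) is available when residual heterogeneity
exceeds 1. `mr_egger()` adds an unconstrained intercept, which under the
InSIDE assumption estimates average directional pleiotropy; because the
intercept is not invariant to allele orientation, SNPs are first oriented so
the chosen exposure's association is non-negative.

`modified_q()` computes the heterogeneity statistic whose weights propagate
exposure-association uncertainty,
$w_j = 1/(se_{\Gamma j}^2 + \hat\beta_1^2 se_{\pi_1 j}^2 + \hat\beta_2^2
se_{\pi_2 j}^2)$, referred to $\chi^2_{L-k}$, with per-SNP contributions on
$\chi^2_1$. When no coefficients are supplied they are estimated by
iteratively reweighted least squares so the reported Q is evaluated at
coefficients consistent with its own weights. The exact weight form is not
uniquely fixed by convention; this package pins its choice by calibration —
under a no-pleiotropy generator with $L = 100$ the test suite requires mean
$Q \approx 98$ and a 5% rejection rate. `remove_outliers_and_refit()` is
deliberately one-shot (remove per-SNP $p < \alpha$, refit once, no
iteration), matching the usual sensitivity-analysis practice.

## The synthetic-data generator

`simulate_cohort()` draws from an explicit structural model so that every
estimator can be validated by parameter recovery:

* dosages are binomial(2, MAF) with MAFs uniform on `maf_range`; no linkage
  disequilibrium is simulated (a user-supplied correlation matrix drives
  pruning instead);
* a latent standard-normal confounder $U$ loads on education, cognition and
  the outcome;
* education is years-scaled (mean 18.3, SD 2.4) and the cognitive score is
  standardized; at most one mediation path ($\alpha_E$ or $\alpha_{CA}$) may
  be active;
* smoking initiation is Bernoulli with a linear probability
  (baseline 43.8%), cessation among initiators likewise (baseline 82.4%,
  coefficients $-\tfrac12(\beta_1,\beta_2)$ so education promotes quitting
  when it deters starting), and current smoking is the consistent derived
  state — prevalences land near 43.8%, 82.4% and 7.7%;
* default score strength ($r^2$ 0.46% education / 0.74% cognition over
  74 + 18 SNPs) is tuned so first-stage F at the default cohort size of
  120,050 lands in the several hundreds, the regime the individual-level
  analysis operates in; the exposure variance each score explains is not a
  published quantity, so these values are a design choice pinned by the F
  statistics they imply;
* optional directional pleiotropy gives each SNP a direct outcome effect on
  its trait-increasing allele (so the mean survives re-orientation);
  optional dynastic effects generate parental genotypes explicitly, transmit
  one allele per parent per SNP, and let mid-parental education act on the
  offspring outcome directly; `apply_selection()` retains individuals with
  probability logistic in education and current smoking, creating collider
  distortion for the re-weighting tools to correct.

All randomness flows from one root seed through fixed named sub-streams, so
identical parameters give bit-identical output.

**Validity envelope.** A linear probability model can push probabilities
outside $[0,1]$; the generator clamps and warns when more than 1% of
individuals are affected. Parameter-recovery experiments are meaningful only
inside this envelope — with large risk differences (e.g. $-0.09$ per year at
education SD 2.4) clamping attenuates every downstream estimate, which is a
property of the generating model, not of the estimators. Recovery tests for
large effects therefore use an exposure scale at which the linear model
holds (education SD 1.2, baseline 0.5).

**Instrument strength in summary experiments.** Real two-sample analyses use
genome-wide-significant SNPs, which by the significance threshold have
per-SNP F above ~30. Emulating that at desk-scale GWAS sample sizes
(n = 20,000) requires concentrating score $r^2$ (0.15 education / 0.05
cognition in the summary experiments); at the individual-level defaults the
per-SNP F would be near 1, a regime real summary MR never operates in, where
the fitted IVW coefficients visibly overfit exposure noise and the Q
statistic deflates.

**What passing tests do and do not show.** The generator has no LD, no
population structure (PC columns are pure noise), no missingness, no
measurement error in phenotypes, and linear structural equations. Passing
recovery and calibration tests shows the estimators are correct under the
assumed diagrams; it does not certify behaviour under model violations real
cohorts exhibit.

## Numerical and design choices

* Robust (HC1/sandwich) covariances everywhere at the individual level;
  2SLS solves use QR projections, not explicit inverses, so mixed covariate
  scales (year-of-birth vs. score units) remain well-conditioned.
* Probabilities/percentages print to 1 decimal with half-up rounding
  (`round_half_up()`), the convention of epidemiological tables; effects
  print to 3 decimals in report files.
* Greedy LD pruning ranks by ascending p-value with lexicographic SNP-id
  tie-breaks (deterministic; the spec of a pruning order is a choice — by
  p-value is the standard clumping-free reading, and the output is maximal
  under it).
* Palindromic (A/T, C/G) SNPs are dropped at harmonisation by default
  (safest for sign integrity without allele-frequency checks);
  `palindromic = "keep"` assumes same-strand data. Harmonisation dropping
  more than 20% of overlapping SNPs is an error, catching build mismatches.
* Adjustment uses 10 genetic PCs by default (`n_pcs` is a knob): the
  analysis convention this mirrors states ten in its methods text and forty
  in its table notes; both are supported, the methods text wins as default.
* Multivariable Egger orientation follows the first-listed exposure. When
  the panel mixes SNPs selected for either exposure, the block with true
  zero associations for the orienting exposure makes the intercept slightly
  anticonservative (a known orientation fragility, visible in our
  calibration experiments at about +0.4 SE); the univariable Egger on its
  own exposure-significant panel is calibrated, and that is the
  configuration the coverage test certifies.
* The empirical power tool replaces a closed-form power formula with the
  generative model itself: the fraction of replicates detecting the
  hypothesised effect at $p < 0.05$, with a binomial Monte-Carlo SE.

## Validation problem sizes

The deep validation suite uses: 200 replicates at n = 20,000 for parameter
recovery under each mediation diagram; 500 replicates of L = 100 SNP
two-sample datasets (GWAS n = 20,000) for Q calibration and 500 for Egger
intercept coverage; 300 replicates at n = 10,000 for the size of the power
calculator; and 100 replicates at n = 100,000 for the mediation-signature
rate. These sizes keep Monte-Carlo error well below the tolerances asserted
while remaining single-CPU friendly.

## A worked mediation example

```{r example, eval = FALSE}
p <- sim_params(
  n_individuals = 50000, beta1 = -0.04, beta2 = 0, alpha_CA = 2, seed = 1
)
rep <- run_individual_analysis(p, outcomes = "ever", n_pcs = 10)
rep$estimates
```

Under this diagram cognition affects smoking only through education:
univariable cognition MR shows a clear negative total effect
($\beta_2 + \alpha_{CA}\beta_1 = -0.08$ per SD), while the multivariable
cognition estimate is attenuated toward zero and the education estimate
stays at its direct value — the signature separating "education matters per
se" from "cognition drives both".

## Known limitations

Within-family designs, LD-aware IVW, weighted-median/mode estimators,
Steiger filtering, logistic IV at the individual level and sample-overlap
corrections are out of scope. The linear-probability outcome model is a
modelling choice matched to risk-difference reporting; odds-ratio output is
available on the summary-data track via per-SNP logistic associations and
`to_odds_ratio()`.
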