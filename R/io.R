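# Plain-text interchange: GWAS-summary-style TSVs, cohort tables, dosage
# matrices and report tables.

gwas_cols <- c("SNP", "effect_allele", "other_allele", "beta", "se", "pval", "N")

#' Read GWAS summary statistics from a tab-delimited file
#'
#' Expects the conventional column layout `SNP`, `effect_allele`,
#' `other_allele`, `beta`, `se`, `pval`, `N`.
#'
#' @param path File path.
#' @return A tibble with those columns.
#' @export
read_gwas_tsv <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(
    SNP = readr::col_character(),
    effect_allele = readr::col_character(),
    other_allele = readr::col_character(),
    .default = readr::col_double()
  ))
  missing <- setdiff(gwas_cols, names(d))
  if (length(missing) > 0) {
    abort(sprintf(
      "GWAS file %s lacks column(s): %s.", path, paste(missing, collapse = ", ")
    ))
  }
  d
}

#' Write GWAS summary statistics to a tab-delimited file
#'
#' @param data Tibble with columns `SNP`, `effect_allele`, `other_allele`,
#'   `beta`, `se`, `pval`, `N`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gwas_tsv <- function(data, path) {
  missing <- setdiff(gwas_cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("Data lacks column(s): %s.", paste(missing, collapse = ", ")))
  }
  readr::write_tsv(data[, gwas_cols], path)
  invisible(path)
}

#' Export a simulated panel as per-exposure GWAS summary files
#'
#' Writes the generating weights of an `mr_cohort` panel in the GWAS-summary
#' dialect, one file per exposure, so the simulated instrument set can be fed
#' back through the same readers as real data.
#'
#' @param cohort_obj An `mr_cohort`.
#' @param dir Output directory (created if needed).
#' @param n Reported GWAS sample size column.
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_panel_gwas <- function(cohort_obj, dir, n = nrow(cohort_obj$cohort)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- cohort_obj$panel
  paths <- c(
    edu = file.path(dir, "panel_edu.tsv"),
    cog = file.path(dir, "panel_cog.tsv")
  )
  for (exp in c("edu", "cog")) {
    w <- panel[[paste0("weight_", exp)]]
    keep <- w != 0
    write_gwas_tsv(tibble(
      SNP = panel$snp_id[keep],
      effect_allele = panel$effect_allele[keep],
      other_allele = panel$other_allele[keep],
      beta = w[keep],
      se = abs(w[keep]) / 6,
      pval = panel[[paste0("pval_", exp)]][keep],
      N = n
    ), paths[[exp]])
  }
  invisible(paths)
}

#' Write a simulated cohort to plain-text files
#'
#' The phenotype/covariate table goes to `cohort.tsv` and the dosage matrix to
#' `dosages.tsv` (individuals x SNPs, header row of SNP ids).
#'
#' @param cohort_obj An `mr_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort_obj, dir) {
  stopifnot(inherits(cohort_obj, "mr_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(cohort_obj$cohort, file.path(dir, "cohort.tsv"))
  readr::write_tsv(
    as_tibble(cohort_obj$dosages),
    file.path(dir, "dosages.tsv")
  )
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `cohort.tsv` and `dosages.tsv`.
#' @return A list with `cohort` (tibble) and `dosages` (matrix).
#' @export
read_cohort <- function(dir) {
  cohort <- readr::read_tsv(
    file.path(dir, "cohort.tsv"),
    col_types = readr::cols()
  )
  dosages <- as.matrix(readr::read_tsv(
    file.path(dir, "dosages.tsv"),
    col_types = readr::cols(.default = readr::col_double())
  ))
  list(cohort = cohort, dosages = dosages)
}

#' Write an individual-level MR report as a results table
#'
#' Emits a tab-delimited table with the columns of the standard presentation:
#' effect, SE, 95% CI, p-value, F and conditional F, per outcome, exposure
#' and method (effects to 3 decimal places).
#'
#' @param report An `mr_report` from [run_individual_analysis()].
#' @param path Output file path.
#' @return The formatted tibble, invisibly.
#' @export
write_mr_report <- function(report, path) {
  stopifnot(inherits(report, "mr_report"))
  e <- report$estimates
  out <- tibble(
    outcome = e$outcome,
    exposure = e$exposure,
    method = e$method,
    effect = round(e$effect, 3),
    se = signif(e$se, 3),
    ci95 = sprintf("%.3f, %.3f", e$ci_lower, e$ci_upper),
    pval = signif(e$pval, 3),
    f_stat = round(e$f_stat, 2),
    cond_f = round(e$cond_f, 2)
  )
  readr::write_tsv(out, path)
  invisible(out)
}
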