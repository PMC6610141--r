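# Polygenic-score instruments: allele harmonisation, weighted score
# computation, greedy LD pruning.

ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) {
  ALLELE_COMPLEMENT[a1] == a2
}

#' Harmonise a SNP weight panel to a cohort's allele coding
#'
#' Aligns the effect/other allele coding of a weight panel with the coding
#' used for the cohort dosages. Where the panel's alleles are swapped relative
#' to the cohort, the weight signs are flipped (equivalent to reading dosage
#' as 2 - d, up to a constant shift of the score). Strand flips (allele
#' complements) are recognised; strand-ambiguous palindromic SNPs (A/T, C/G)
#' are dropped by default because their orientation cannot be inferred without
#' allele frequencies. Incompatible allele pairs are dropped with a log entry.
#'
#' @param panel A SNP panel tibble with `snp_id`, `effect_allele`,
#'   `other_allele` and weight columns (`weight_edu`, `weight_cog`, or any
#'   column starting with `weight`).
#' @param cohort_alleles Tibble with `snp_id`, `effect_allele`, `other_allele`
#'   giving the cohort's dosage coding.
#' @param palindromic `"drop"` (default) or `"keep"` — keep assumes the two
#'   datasets are on the same strand.
#' @param max_drop_frac Error if more than this fraction of overlapping SNPs
#'   is dropped (default 0.2).
#' @return List with `panel` (aligned, in cohort coding, flagged
#'   `harmonised = TRUE`) and `log` (tibble of `snp_id`, `action` in
#'   `same`, `swap`, `strand_flip`, `strand_swap`, `drop_palindromic`,
#'   `drop_incompatible`, `proxy_substitution`).
#' @examples
#' panel <- tibble::tibble(
#'   snp_id = "rs1", effect_allele = "A", other_allele = "C", weight_edu = 0.1
#' )
#' coh <- tibble::tibble(snp_id = "rs1", effect_allele = "C", other_allele = "A")
#' harmonise_alleles(panel, coh)$panel$weight_edu # -0.1
#' @export
harmonise_alleles <- function(panel, cohort_alleles,
                              palindromic = c("drop", "keep"),
                              max_drop_frac = 0.2) {
  palindromic <- match.arg(palindromic)
  shared <- intersect(panel$snp_id, cohort_alleles$snp_id)
  if (length(shared) == 0) {
    abort("No overlapping SNP ids between panel and cohort.")
  }
  pan <- panel[match(shared, panel$snp_id), , drop = FALSE]
  coh <- cohort_alleles[match(shared, cohort_alleles$snp_id), , drop = FALSE]
  wcols <- grep("^weight", names(pan), value = TRUE)

  pe <- toupper(pan$effect_allele)
  po <- toupper(pan$other_allele)
  ce <- toupper(coh$effect_allele)
  co <- toupper(coh$other_allele)
  bad_base <- !(pe %in% names(ALLELE_COMPLEMENT)) |
    !(po %in% names(ALLELE_COMPLEMENT))

  action <- dplyr::case_when(
    bad_base ~ "drop_incompatible",
    is_palindromic(pe, po) & palindromic == "drop" ~ "drop_palindromic",
    pe == ce & po == co ~ "same",
    pe == co & po == ce ~ "swap",
    ALLELE_COMPLEMENT[pe] == ce & ALLELE_COMPLEMENT[po] == co ~ "strand_flip",
    ALLELE_COMPLEMENT[pe] == co & ALLELE_COMPLEMENT[po] == ce ~ "strand_swap",
    TRUE ~ "drop_incompatible"
  )

  flip <- action %in% c("swap", "strand_swap")
  keep <- !action %in% c("drop_palindromic", "drop_incompatible")
  dropped_frac <- mean(!keep)
  if (dropped_frac > max_drop_frac) {
    abort(sprintf(
      "Harmonisation dropped %.0f%% of overlapping SNPs (> %.0f%% allowed); check that the two datasets use compatible builds.",
      100 * dropped_frac, 100 * max_drop_frac
    ))
  }

  aligned <- pan
  aligned$effect_allele <- ce
  aligned$other_allele <- co
  for (w in wcols) {
    aligned[[w]] <- ifelse(flip, -aligned[[w]], aligned[[w]])
  }
  aligned <- aligned[keep, , drop = FALSE]
  aligned$harmonised <- TRUE

  log <- tibble(snp_id = shared, action = action)
  list(panel = aligned, log = log)
}

#' Record a proxy substitution in a harmonisation log
#'
#' When an instrument SNP is unavailable in the target data and a perfect-LD
#' proxy is used instead, the substitution is recorded as a log entry so the
#' provenance of every score component is explicit.
#'
#' @param log A harmonisation log tibble (`snp_id`, `action`).
#' @param original,proxy SNP ids.
#' @return The log with a `proxy_substitution` row appended (the proxy id is
#'   recorded in a `note` column).
#' @export
log_proxy_substitution <- function(log, original, proxy) {
  if (!"note" %in% names(log)) log$note <- NA_character_
  dplyr::bind_rows(log, tibble(
    snp_id = original, action = "proxy_substitution",
    note = sprintf("substituted by perfect-LD proxy %s", proxy)
  ))
}

#' Compute a weighted polygenic score
#'
#' The score for individual i is the weighted count of effect alleles,
#' `sum_j w_j d_ij`, with weights taken from the harmonised panel.
#'
#' @param dosages Numeric matrix (individuals x SNPs) with SNP ids as column
#'   names; values in \[0, 2\], no missing entries.
#' @param panel Harmonised SNP panel containing the weight column.
#' @param which `"edu"` or `"cog"`, selecting `weight_edu` or `weight_cog`.
#' @return Numeric score vector of length `nrow(dosages)`.
#' @examples
#' G <- matrix(c(0, 1, 2, 1), 2, 2, dimnames = list(NULL, c("rs1", "rs2")))
#' pan <- tibble::tibble(snp_id = c("rs1", "rs2"), weight_edu = c(0.5, -1))
#' compute_prs(G, pan, "edu")
#' @export
compute_prs <- function(dosages, panel, which = c("edu", "cog")) {
  which <- match.arg(which)
  wcol <- paste0("weight_", which)
  if (!wcol %in% names(panel)) {
    abort(sprintf("Panel lacks column '%s'.", wcol))
  }
  missing <- setdiff(panel$snp_id, colnames(dosages))
  if (length(missing) > 0) {
    abort(sprintf(
      "Dosage matrix lacks panel SNP(s): %s.",
      paste(head(missing, 10), collapse = ", ")
    ))
  }
  D <- dosages[, panel$snp_id, drop = FALSE]
  if (anyNA(D)) {
    abort("Missing dosages are not supported; imputation is out of scope.")
  }
  drop(D %*% panel[[wcol]])
}

#' Greedy LD pruning of a SNP panel
#'
#' Orders SNPs by ascending association p-value (ties broken by lexicographic
#' SNP id) and keeps a SNP if and only if its squared correlation with every
#' SNP already kept is at or below the threshold. The kept set is maximal for
#' this ordering: no excluded SNP could be added back without violating the
#' threshold.
#'
#' @param panel SNP panel tibble with `snp_id` and the p-value column for the
#'   chosen ranking.
#' @param r2_threshold Maximum allowed pairwise squared correlation
#'   (default 0.001).
#' @param rank_by `"edu"`, `"cog"`, or `"min"` (the smaller of the two
#'   p-values per SNP, used when pruning a combined panel).
#' @param ld_corr Symmetric correlation matrix r with unit diagonal, with
#'   dimnames covering every panel SNP; defaults to
#'   `attr(panel, "ld_corr")`.
#' @return Character vector of kept SNP ids (in the ranked order).
#' @examples
#' pan <- tibble::tibble(snp_id = c("rs1", "rs2"), pval_edu = c(1e-10, 1e-4))
#' r <- matrix(c(1, 1, 1, 1), 2, dimnames = list(pan$snp_id, pan$snp_id))
#' ld_prune(pan, 0.001, "edu", r) # only rs1 survives
#' @export
ld_prune <- function(panel, r2_threshold = 0.001,
                     rank_by = c("edu", "cog", "min"),
                     ld_corr = attr(panel, "ld_corr")) {
  rank_by <- match.arg(rank_by)
  if (is.null(ld_corr)) {
    abort("`ld_corr` is required: supply it or attach it as attr(panel, 'ld_corr').")
  }
  ids <- panel$snp_id
  if (!all(ids %in% rownames(ld_corr)) || !all(ids %in% colnames(ld_corr))) {
    abort("`ld_corr` must have row/column names covering every panel SNP.")
  }
  R <- ld_corr[ids, ids, drop = FALSE]
  if (max(abs(R - t(R))) > 1e-8 || any(abs(diag(R) - 1) > 1e-8)) {
    abort("`ld_corr` must be symmetric with unit diagonal.")
  }
  pval <- switch(rank_by,
    edu = panel$pval_edu,
    cog = panel$pval_cog,
    min = pmin(panel$pval_edu, panel$pval_cog, na.rm = TRUE)
  )
  if (is.null(pval) || anyNA(pval)) {
    abort("Ranking p-values are missing for some SNPs.")
  }
  ord <- order(pval, ids)
  kept <- character(0)
  for (i in ord) {
    if (length(kept) == 0 ||
        all(R[ids[i], kept]^2 <= r2_threshold)) {
      kept <- c(kept, ids[i])
    }
  }
  kept
}
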