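# Deterministic phenotype construction: qualification -> years mapping,
# cognitive-score standardization, smoking-variable derivation, covariate
# assembly.

#' The qualification-to-years mapping
#'
#' Highest reported educational qualification mapped to the age at which that
#' education would typically be completed, the convention used to turn a
#' six-category qualification variable into continuous years of education.
#' The map is shipped as a plain-text data file so it round-trips through
#' serialization.
#'
#' @return A tibble with columns `qualification` and `years`.
#' @examples
#' qualification_map()
#' @export
qualification_map <- function() {
  path <- system.file("extdata", "qualification_years.tsv", package = "edumr")
  readr::read_tsv(path, col_types = readr::cols(
    qualification = readr::col_character(),
    years = readr::col_integer()
  ))
}

normalise_label <- function(x) {
  x <- tolower(trimws(x))
  gsub("\\s+", " ", x)
}

#' Convert highest qualification to age completed education
#'
#' @param label Character vector of qualification labels; matching is
#'   case-insensitive and whitespace-tolerant.
#' @param map The qualification map, by default [qualification_map()].
#' @return Integer vector of ages (years) at completion of education.
#' @examples
#' qualification_to_years(c("None", "College or University degree"))
#' @export
qualification_to_years <- function(label, map = qualification_map()) {
  key <- normalise_label(map$qualification)
  idx <- match(normalise_label(label), key)
  if (anyNA(idx)) {
    bad <- unique(label[is.na(idx)])
    abort(sprintf(
      "Unknown qualification label(s): %s. Valid categories: %s.",
      paste(sQuote(bad), collapse = ", "),
      paste(sQuote(map$qualification), collapse = ", ")
    ))
  }
  map$years[idx]
}

#' Standardize a cognitive test score
#'
#' Centers and scales a raw test score to mean 0 and standard deviation 1,
#' the scale on which per-SD effects of cognitive ability are reported.
#'
#' @param raw Numeric vector with at least two distinct values and no missing
#'   entries (missing data are handled by the upstream complete-case filter).
#' @return Numeric vector with mean 0 and SD 1.
#' @examples
#' standardize_score(c(2, 4, 6, 8))
#' @export
standardize_score <- function(raw) {
  if (anyNA(raw)) {
    abort("`raw` contains missing values; apply the complete-case filter first.")
  }
  s <- sd(raw)
  if (!is.finite(s) || s == 0 || length(unique(raw)) < 2) {
    abort("Cannot standardize a constant score vector.")
  }
  (raw - mean(raw)) / s
}

#' Derive the three smoking phenotypes
#'
#' Builds the nested smoking outcomes from two questionnaire flags: a
#' current-smoker indicator, an ever-smoker (initiation) indicator, and — only
#' among ever smokers — a cessation indicator equal to 1 for former smokers.
#'
#' @param current_flag,ever_flag Binary (0/1 or logical) vectors of the same
#'   length. A current smoker must be an ever smoker; violations are an error
#'   listing the offending rows.
#' @return A list with `smoke_current`, `smoke_ever`, `smoke_former` (NA for
#'   never smokers) and `summary`, a one-row tibble of counts and percentages
#'   (1 decimal place, half-up).
#' @examples
#' derive_smoking_phenotypes(c(0, 1, 0, 0), c(1, 1, 0, 1))$summary
#' @export
derive_smoking_phenotypes <- function(current_flag, ever_flag) {
  current <- as.integer(current_flag)
  ever <- as.integer(ever_flag)
  if (length(current) != length(ever)) {
    abort("`current_flag` and `ever_flag` must have the same length.")
  }
  if (anyNA(current) || anyNA(ever) ||
      !all(current %in% 0:1) || !all(ever %in% 0:1)) {
    abort("Smoking flags must be binary with no missing values.")
  }
  bad <- which(current == 1L & ever == 0L)
  if (length(bad) > 0) {
    abort(sprintf(
      "Current smokers who never smoked at rows: %s.",
      paste(head(bad, 20), collapse = ", ")
    ))
  }
  former <- ifelse(ever == 1L, 1L - current, NA_integer_)
  n <- length(ever)
  n_current <- sum(current)
  n_ever <- sum(ever)
  n_former <- sum(former == 1L, na.rm = TRUE)
  summary <- tibble(
    n = n,
    n_current = n_current,
    pct_current = round_half_up(100 * n_current / n, 1),
    n_ever = n_ever,
    pct_ever = round_half_up(100 * n_ever / n, 1),
    n_former = n_former,
    pct_former_among_ever = if (n_ever > 0) {
      round_half_up(100 * n_former / n_ever, 1)
    } else {
      NA_real_
    }
  )
  list(
    smoke_current = current,
    smoke_ever = ever,
    smoke_former = former,
    summary = summary
  )
}

#' Assemble the covariate design block
#'
#' Builds the standard adjustment set: age, sex, year of birth, a
#' sex-by-year-of-birth interaction (to absorb secular change in smoking
#' patterns that differs between sexes), and the first `n_pcs` genetic
#' principal components.
#'
#' @param data A data frame with columns `age`, `sex`, `year_of_birth` and
#'   principal components named `pc1`, `pc2`, ....
#' @param n_pcs Number of principal components to include (default 10).
#' @return A tibble of covariate columns with full column rank after adding an
#'   intercept; rank deficiency is an error naming the collinear columns.
#' @examples
#' d <- tibble::tibble(
#'   age = c(40, 50, 60, 45), sex = c(0, 1, 0, 1),
#'   year_of_birth = c(1968, 1958, 1948, 1963), pc1 = rnorm(4)
#' )
#' build_covariates(d, n_pcs = 1)
#' @export
build_covariates <- function(data, n_pcs = 10) {
  for (nm in c("age", "sex", "year_of_birth")) {
    if (!nm %in% names(data)) abort(sprintf("`data` lacks column '%s'.", nm))
  }
  check_number(n_pcs, "n_pcs", lower = 0)
  pc_names <- paste0("pc", seq_len(n_pcs))
  if (n_pcs > 0 && !all(pc_names %in% names(data))) {
    missing <- setdiff(pc_names, names(data))
    abort(sprintf(
      "Requested %d PCs but column(s) %s are absent.",
      n_pcs, paste(missing, collapse = ", ")
    ))
  }
  out <- tibble(
    age = as.numeric(data$age),
    sex = as.numeric(data$sex),
    year_of_birth = as.numeric(data$year_of_birth),
    sex_x_year_of_birth = as.numeric(data$sex) * as.numeric(data$year_of_birth)
  )
  if (n_pcs > 0) {
    out <- dplyr::bind_cols(out, as_tibble(data[, pc_names, drop = FALSE]))
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(out))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    abort(sprintf(
      "Covariate block is rank deficient; collinear column(s): %s.",
      paste(dropped, collapse = ", ")
    ))
  }
  out
}
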