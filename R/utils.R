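# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Percentages in reports are rounded half-up (5 rounds away from zero), the
#' convention used in epidemiological tables, rather than R's default
#' round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(0.45, 1) # 0.5, where round() gives 0.4
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Derive a reproducible sub-seed for a named random stream from a root seed.
# The rule is a fixed affine hash modulo 2^31 - 1 so all randomness flows from
# one root integer and streams for different purposes never collide.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(
    dosages = 11L, confounder = 23L, edu = 37L, cog = 41L, outcome = 53L,
    covariates = 67L, parents = 71L, selection = 83L, weights = 89L,
    gwas_exposure1 = 101L, gwas_exposure2 = 107L, gwas_outcome = 109L,
    replicate = 127L
  )
  off <- offsets[[stream]]
  # double arithmetic stays exact below 2^53; reduce before integer coercion
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + off * 9973) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Two-sided p-value from a z statistic.
z_pvalue <- function(z) 2 * pnorm(-abs(z))

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}
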