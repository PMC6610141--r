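make_panel <- function(n = 6, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    snp_id = sprintf("rs%02d", seq_len(n)),
    effect_allele = c("A", "C", "G", "T", "A", "C")[seq_len(n)],
    other_allele = c("C", "A", "T", "G", "G", "T")[seq_len(n)],
    weight_edu = rnorm(n),
    weight_cog = rnorm(n),
    pval_edu = runif(n),
    pval_cog = runif(n)
  ))
}

test_that("harmonisation keeps identical coding unchanged with an empty flip log", {
  pan <- make_panel()
  coh <- pan[, c("snp_id", "effect_allele", "other_allele")]
  h <- harmonise_alleles(pan, coh)
  expect_equal(h$panel$weight_edu, pan$weight_edu)
  expect_true(all(h$log$action == "same"))
})

test_that("swapped and strand-flipped alleles are aligned correctly", {
  pan <- make_panel()
  coh <- pan[, c("snp_id", "effect_allele", "other_allele")]
  # swap alleles for SNP 1: weight must flip sign
  coh$effect_allele[1] <- pan$other_allele[1]
  coh$other_allele[1] <- pan$effect_allele[1]
  # strand flip (complement, same orientation) for SNP 2: weight unchanged
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  coh$effect_allele[2] <- comp[[pan$effect_allele[2]]]
  coh$other_allele[2] <- comp[[pan$other_allele[2]]]
  h <- harmonise_alleles(pan, coh)
  expect_equal(h$panel$weight_edu[1], -pan$weight_edu[1])
  expect_equal(h$panel$weight_edu[2], pan$weight_edu[2])
  expect_identical(h$log$action[1:2], c("swap", "strand_flip"))
  # aligned panel is in cohort coding
  expect_identical(h$panel$effect_allele, coh$effect_allele)
})

test_that("palindromic SNPs are dropped by default and kept on request", {
  pan <- make_panel()
  pan$effect_allele[3] <- "A"
  pan$other_allele[3] <- "T"
  coh <- pan[, c("snp_id", "effect_allele", "other_allele")]
  h <- harmonise_alleles(pan, coh)
  expect_false("rs03" %in% h$panel$snp_id)
  expect_identical(h$log$action[3], "drop_palindromic")
  h2 <- harmonise_alleles(pan, coh, palindromic = "keep")
  expect_true("rs03" %in% h2$panel$snp_id)
})

test_that("incompatible pairs are dropped and excessive loss is an error", {
  pan <- make_panel()
  coh <- pan[, c("snp_id", "effect_allele", "other_allele")]
  coh$effect_allele[4] <- "A"
  coh$other_allele[4] <- "G" # panel has T/G: not a match, swap or complement
  h <- harmonise_alleles(pan, coh, max_drop_frac = 0.5)
  expect_identical(h$log$action[4], "drop_incompatible")
  expect_error(harmonise_alleles(pan, coh, max_drop_frac = 0.1), "dropped")
})

test_that("harmonisation is an involution", {
  pan <- make_panel()
  coh <- pan[, c("snp_id", "effect_allele", "other_allele")]
  coh$effect_allele[1] <- pan$other_allele[1]
  coh$other_allele[1] <- pan$effect_allele[1]
  once <- harmonise_alleles(pan, coh)$panel
  twice <- harmonise_alleles(once, coh)
  expect_equal(twice$panel$weight_edu, once$weight_edu)
  expect_true(all(twice$log$action == "same"))
})

test_that("proxy substitutions are recorded in the log", {
  h <- harmonise_alleles(
    make_panel(),
    make_panel()[, c("snp_id", "effect_allele", "other_allele")]
  )
  log2 <- log_proxy_substitution(h$log, "rs01", "rs99")
  expect_identical(log2$action[nrow(log2)], "proxy_substitution")
  expect_match(log2$note[nrow(log2)], "rs99")
})

test_that("polygenic scores equal the brute-force weighted allele count", {
  withr::with_seed(42, {
    G <- matrix(rbinom(50 * 20, 2, 0.3), 50, 20,
      dimnames = list(NULL, sprintf("rs%02d", 1:20))
    )
    pan <- tibble::tibble(
      snp_id = sprintf("rs%02d", 1:20),
      weight_edu = rnorm(20), weight_cog = rnorm(20)
    )
  })
  score <- compute_prs(G, pan, "edu")
  brute <- numeric(50)
  for (i in 1:50) {
    for (j in 1:20) brute[i] <- brute[i] + pan$weight_edu[j] * G[i, j]
  }
  expect_equal(score, brute, tolerance = 1e-12)
  # edge cases and linearity
  expect_equal(compute_prs(G * 0, pan, "edu"), rep(0, 50))
  G1 <- matrix(2, 1, 1, dimnames = list(NULL, "rs01"))
  expect_equal(
    compute_prs(G1, pan[1, ], "edu"),
    2 * pan$weight_edu[1]
  )
  pan2 <- pan
  pan2$weight_edu <- pan$weight_edu + pan$weight_cog
  expect_equal(
    compute_prs(G, pan2, "edu"),
    compute_prs(G, pan, "edu") + compute_prs(G, pan, "cog"),
    tolerance = 1e-12
  )
  Gna <- G
  Gna[1, 1] <- NA
  expect_error(compute_prs(Gna, pan, "edu"), "Missing")
})

test_that("greedy LD pruning matches an independent brute-force implementation", {
  withr::with_seed(7, {
    n <- 30
    ids <- sprintf("rs%02d", 1:n)
    A <- matrix(rnorm(n * 3), n, 3)
    S <- tcrossprod(A) + diag(n) * 0.5
    R <- stats::cov2cor(S)
    dimnames(R) <- list(ids, ids)
    pan <- tibble::tibble(
      snp_id = ids, pval_edu = runif(n), pval_cog = runif(n)
    )
  })
  thr <- 0.1
  kept <- ld_prune(pan, thr, "edu", R)
  # brute force: same greedy rule written independently
  ord <- pan$snp_id[order(pan$pval_edu, pan$snp_id)]
  expected <- character(0)
  for (id in ord) {
    ok <- TRUE
    for (k in expected) if (R[id, k]^2 > thr) ok <- FALSE
    if (ok) expected <- c(expected, id)
  }
  expect_identical(kept, expected)
  # maximality: every excluded SNP conflicts with some kept SNP
  for (id in setdiff(ids, kept)) {
    expect_true(any(R[id, kept]^2 > thr))
  }
})

test_that("pruning handles the degenerate correlation cases", {
  pan <- tibble::tibble(
    snp_id = c("rs1", "rs2"), pval_edu = c(1e-10, 1e-4), pval_cog = c(1, 1)
  )
  R0 <- diag(2)
  dimnames(R0) <- list(pan$snp_id, pan$snp_id)
  expect_identical(sort(ld_prune(pan, 0.001, "edu", R0)), c("rs1", "rs2"))
  R1 <- matrix(1, 2, 2, dimnames = list(pan$snp_id, pan$snp_id))
  expect_identical(ld_prune(pan, 0.001, "edu", R1), "rs1")
  expect_error(ld_prune(pan, 0.001, "edu"), "ld_corr")
  Rbad <- R0
  Rbad[1, 2] <- 0.5
  expect_error(ld_prune(pan, 0.001, "edu", Rbad), "symmetric")
})
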