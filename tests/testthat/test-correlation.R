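test_that("exact linear relationships give r = 1 / r = -1 with the right tiers", {
  a <- matrix(c(1, 2, 3, 4), nrow = 1, dimnames = list("x", paste0("s", 1:4)))
  b <- matrix(c(2, 4, 6, 8), nrow = 1, dimnames = list("y", paste0("s", 1:4)))
  res <- correlate_pairs(a, b)
  expect_equal(res$r, 1)
  expect_equal(res$tier, "very_strong")
  expect_true(res$significant)
  expect_true(res$ci_low <= res$r && res$r <= res$ci_high)

  res_neg <- correlate_pairs(a, -a)
  expect_equal(res_neg$r, -1)
  expect_equal(res_neg$tier, "very_strong")
})

test_that("r is invariant under positive affine maps and flips sign under negation", {
  set.seed(20)
  x <- matrix(rnorm(12), nrow = 1, dimnames = list("x", paste0("s", 1:12)))
  y <- matrix(rnorm(12), nrow = 1, dimnames = list("y", paste0("s", 1:12)))
  r0 <- correlate_pairs(x, y)$r
  expect_equal(correlate_pairs(3.7 * x + 2, y)$r, r0)
  expect_equal(correlate_pairs(x, 0.1 * y - 5)$r, r0)
  expect_equal(correlate_pairs(-x, y)$r, -r0)
})

test_that("strength tiers respect the 0.70 and 0.85 thresholds exactly at the boundaries", {
  expect_equal(correlation_tier(c(0.69, 0.70, 0.84, 0.85, -0.85, -0.7, 0.999)),
               c("none", "strong", "strong", "very_strong", "very_strong",
                 "strong", "very_strong"))
  expect_true(is.na(correlation_tier(NA_real_)))
})

test_that("too-few samples and zero variance are flagged, not computed", {
  a <- matrix(c(1, 2), nrow = 1, dimnames = list("x", c("s1", "s2")))
  res <- correlate_pairs(a, a)
  expect_true(is.na(res$r))
  expect_equal(res$flag, "n_too_small")

  cst <- matrix(rep(5, 5), nrow = 1, dimnames = list("c", paste0("s", 1:5)))
  var5 <- matrix(rnorm(5), nrow = 1, dimnames = list("v", paste0("s", 1:5)))
  res2 <- correlate_pairs(cst, var5)
  expect_equal(res2$flag, "zero_variance")
  expect_true(is.na(res2$r))
})

test_that("a planted latent-factor pair is estimated inside the n = 30 envelope", {
  b <- synthesize_bundle(groups = c("control", "AD3"), n_subjects = 10,
                         n_replicates = 3, n_correlation_pairs = 2,
                         n_flip_pairs = 0, correlation_r = 0.9, seed = 23)
  m <- quant_matrix(b$quant)
  cp <- b$truth$correlation_pairs
  for (i in seq_len(nrow(cp))) {
    res <- correlate_pairs(m[cp$peptide_a[i], , drop = FALSE],
                           m[cp$peptide_b[i], , drop = FALSE],
                           b$design, cp$group[i])
    expect_gt(res$r, 0.75)
    expect_lt(res$r, 0.97)
    expect_true(res$significant)
  }
})

test_that("the heatmap table filters on |r| and reversals need significance in both groups", {
  # hand-built sign flip: same peptides, opposite correlation per group
  design <- make_study_design(groups = c("control", "AD3"),
                              n_subjects = 6, n_replicates = 1)
  set.seed(25)
  n <- 6
  z <- rnorm(n); e <- rnorm(n, sd = 0.2)
  flipped <- matrix(0, nrow = 2, ncol = 12,
                    dimnames = list(c("pepA", "pepB"), design$sample_id))
  ctrl <- design$group == "control"
  flipped["pepA", ctrl] <- z
  flipped["pepB", ctrl] <- z + e          # strong positive in control
  z2 <- rnorm(n); e2 <- rnorm(n, sd = 0.2)
  flipped["pepA", !ctrl] <- z2
  flipped["pepB", !ctrl] <- -z2 + e2      # strong negative in AD3
  noise <- matrix(rnorm(24, sd = 1), nrow = 2, ncol = 12,
                  dimnames = list(c("pepC", "pepD"), design$sample_id))
  mat <- rbind(flipped, noise)
  heat <- peptide_heatmap_table(mat, mat, design, c("control", "AD3"))
  rev <- heat$reversals
  expect_true(any(rev$feature_a == "pepA" & rev$feature_b == "pepB"))
  # self-pairs never appear in the reversal report
  expect_false(any(rev$feature_a == rev$feature_b))
  # table keeps only pairs reaching |r| > 0.5 somewhere
  key <- paste(heat$table$feature_a, heat$table$feature_b)
  for (k in unique(key)) {
    expect_true(any(abs(heat$table$r[key == k]) > 0.5, na.rm = TRUE))
  }
})

test_that("requesting an unknown group fails loudly", {
  design <- make_study_design(groups = c("control", "AD3"),
                              n_subjects = 3, n_replicates = 1)
  mat <- matrix(rnorm(12), nrow = 2,
                dimnames = list(c("a", "b"), design$sample_id))
  expect_error(peptide_heatmap_table(mat, mat, design,
                                     c("control", "AD9")), "AD9")
})

test_that("cross-compartment partition and correlations match set algebra", {
  design <- make_study_design(groups = c("control", "AD3"),
                              n_subjects = 4, n_replicates = 1,
                              fraction = "bEV")
  set.seed(27)
  common <- matrix(rpois(3 * 8, 30), nrow = 3,
                   dimnames = list(paste0("C", 1:3), design$sample_id))
  a_only <- matrix(rpois(2 * 8, 10), nrow = 2,
                   dimnames = list(paste0("A", 1:2), design$sample_id))
  b_only <- matrix(rpois(1 * 8, 10), nrow = 1,
                   dimnames = list("B1", design$sample_id))
  mat_a <- rbind(common, a_only, B1 = rep(0, 8))
  mat_b <- rbind(common + 1, A1 = rep(0, 8), A2 = rep(0, 8), b_only)
  res <- cross_compartment_correlation(mat_a, mat_b, design)
  expect_setequal(res$partition$common, paste0("C", 1:3))
  expect_setequal(res$partition$a_only, paste0("A", 1:2))
  expect_equal(res$partition$n_b_only, 1)
  # identical values (plus a constant) across compartments: r = 1
  expect_equal(res$correlations$r, rep(1, 3))
})

test_that("a planted anti-correlated compartment pair is strongly negative", {
  design <- make_study_design(groups = "control", n_subjects = 9,
                              n_replicates = 1)
  set.seed(29)
  x <- rnorm(9, 50, 10)
  mat_a <- matrix(x, nrow = 1, dimnames = list("P", design$sample_id))
  mat_b <- matrix(100 - x + rnorm(9, sd = 2), nrow = 1,
                  dimnames = list("P", design$sample_id))
  res <- cross_compartment_correlation(mat_a, mat_b, design)
  expect_lt(res$correlations$r, -0.7)
  expect_true(res$correlations$significant)
  expect_true(res$correlations$negative_significant)
})

test_that("correlation tables are bit-identical across recomputation", {
  b <- small_bundle(seed = 31)
  m <- quant_matrix(b$quant)[1:10, ]
  h1 <- peptide_heatmap_table(m, m, b$design, c("control", "AD3"))
  h2 <- peptide_heatmap_table(m, m, b$design, c("control", "AD3"))
  expect_identical(h1, h2)
})
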