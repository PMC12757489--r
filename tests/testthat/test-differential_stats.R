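planted_profiles <- function(n = 40, noise = 1, seed = 1) {
  set.seed(seed)
  stages <- 6
  up <- t(replicate(n / 2, seq(0, 5) * 2 + rnorm(stages, sd = noise)))
  dn <- t(replicate(n / 2, seq(5, 0) * 2 + rnorm(stages, sd = noise)))
  prof <- rbind(up, dn)
  rownames(prof) <- sprintf("p%02d", seq_len(n))
  colnames(prof) <- c("control", "AD3", "AD4", "AD5", "AD6", "VaD")
  list(profiles = prof, family = rep(1:2, each = n / 2))
}

test_that("fuzzy memberships are a partition and the objective never increases", {
  pp <- planted_profiles(seed = 2)
  fit <- fuzzy_cluster(pp$profiles, n_clusters = 2, seed = 3)
  expect_true(all(abs(rowSums(fit$memberships) - 1) < 1e-9))
  expect_true(all(diff(fit$objective) <= 1e-8))
  expect_true(fit$fpc >= 0.5 && fit$fpc <= 1)
})

test_that("fuzzy c-means recovers planted trend families", {
  pp <- planted_profiles(seed = 4)
  fit <- fuzzy_cluster(pp$profiles, n_clusters = 2, seed = 4)
  a <- fit$assignments
  agree <- max(mean((a$cluster == 1) == (pp$family == 1)),
               mean((a$cluster == 2) == (pp$family == 1)))
  expect_gte(agree, 0.95)
  expect_gte(mean(a$retained), 0.95)
})

test_that("automatic k selection maximizes the partition coefficient", {
  pp <- planted_profiles(noise = 0.5, seed = 6)
  fit <- fuzzy_cluster(pp$profiles, n_clusters = NULL, seed = 5,
                       k_range = 2:4)
  expect_equal(fit$k, 2)  # two planted families
})

test_that("duplicated profiles give symmetric memberships near 0.5", {
  prof <- matrix(rep(c(1, 2, 3, 4, 5, 6), 10), nrow = 10, byrow = TRUE)
  rownames(prof) <- paste0("f", 1:10)
  fit <- fuzzy_cluster(prof, n_clusters = 2, seed = 1)
  expect_true(all(abs(fit$assignments$membership - 0.5) < 1e-6))
})

test_that("degenerate k requests are rejected", {
  pp <- planted_profiles(n = 4, seed = 1)
  expect_error(fuzzy_cluster(pp$profiles, n_clusters = 4), "smaller")
  expect_error(fuzzy_cluster(pp$profiles, n_clusters = 1), ">= 2")
})

test_that("our fuzzy c-means agrees with an independent implementation", {
  pp <- planted_profiles(seed = 8)
  fit <- fuzzy_cluster(pp$profiles, n_clusters = 2, seed = 7)
  ext <- e1071::cmeans(fit$standardized, centers = 2, m = 2,
                       iter.max = 300)
  # same hard partition up to label permutation
  ours <- fit$assignments$cluster
  theirs <- as.integer(ext$cluster)
  agree <- max(mean(ours == theirs), mean(ours == (3L - theirs)))
  expect_equal(agree, 1)
  # same converged centers up to row permutation
  ord_ours <- fit$centers[order(fit$centers[, 1]), ]
  ord_theirs <- ext$centers[order(ext$centers[, 1]), ]
  expect_equal(unname(ord_ours), unname(ord_theirs), tolerance = 1e-3)
})

test_that("isoform splitting partitions a symbol by cluster with deterministic subscripts", {
  assignments <- data.frame(
    feature = paste0("P", 1:6),
    cluster = c(1, 2, 3, 4, 1, 1),
    membership = 0.9, retained = TRUE, stringsAsFactors = FALSE)
  symbols <- setNames(c(rep("DnaK", 4), "AhcY", "TufA"),
                      assignments$feature)
  first_means <- setNames(c(40, 10, 30, 20, 5, 5), assignments$feature)
  iso <- split_isoforms(assignments, symbols, first_means)
  dn <- iso[iso$gene_symbol == "DnaK", ]
  expect_setequal(dn$isoform_label,
                  c("DnaK_1", "DnaK_2", "DnaK_3", "DnaK_4"))
  # subscripts ordered by descending first-stage mean: P1 > P3 > P4 > P2
  expect_equal(dn$isoform_label[dn$feature == "P1"], "DnaK_1")
  expect_equal(dn$isoform_label[dn$feature == "P3"], "DnaK_2")
  expect_equal(dn$isoform_label[dn$feature == "P2"], "DnaK_4")
  # single-member symbols keep the bare symbol
  expect_equal(iso$isoform_label[iso$feature == "P5"], "AhcY")

  # relabeling clusters permutes nothing in the output labels
  relabeled <- assignments
  relabeled$cluster <- c(4, 3, 2, 1, 4, 4)[match(assignments$cluster,
                                                 c(1, 2, 3, 4))]
  iso2 <- split_isoforms(relabeled, symbols, first_means)
  expect_equal(iso2$isoform_label, iso$isoform_label)
})

test_that("Bonferroni adjustment multiplies by the contrast-family size", {
  set.seed(10)
  design <- make_study_design(groups = c("control", "AD3", "AD4"),
                              n_subjects = 4, n_replicates = 1)
  mat <- matrix(rnorm(2 * nrow(design), 10), nrow = 2,
                dimnames = list(c("A", "B"), design$sample_id))
  res <- run_group_tests(mat, design, "anova_bonferroni")
  con <- res[res$contrast != "omnibus" & res$feature == "A", ]
  expect_equal(nrow(con), 3)  # choose(3, 2)
  expect_equal(con$p_adj, pmin(1, con$p * 3))
  expect_true(all(res$p_adj >= res$p - 1e-12))
})

test_that("a feature with identical values everywhere is flagged degenerate with p = 1", {
  design <- make_study_design(groups = c("control", "AD3"), n_subjects = 3,
                              n_replicates = 1)
  mat <- matrix(1, nrow = 1, ncol = nrow(design),
                dimnames = list("flat", design$sample_id))
  res <- run_group_tests(mat, design, "anova_bonferroni")
  expect_true(all(res$degenerate))
  expect_true(all(res$p == 1))
  expect_false(any(res$significant))
})

test_that("results are invariant to feature and sample order", {
  set.seed(12)
  design <- make_study_design(groups = c("control", "AD3", "AD4"),
                              n_subjects = 3, n_replicates = 2)
  mat <- matrix(rpois(4 * nrow(design), 20), nrow = 4,
                dimnames = list(paste0("P", 1:4), design$sample_id))
  res1 <- run_group_tests(mat, design, "anova_bonferroni")
  perm_f <- c(3, 1, 4, 2)
  perm_s <- sample(ncol(mat))
  res2 <- run_group_tests(mat[perm_f, perm_s], design, "anova_bonferroni")
  key <- function(r) r[order(r$feature, r$contrast),
                       c("feature", "contrast", "statistic", "p")]
  expect_equal(`rownames<-`(key(res1), NULL), `rownames<-`(key(res2), NULL))
})

test_that("Fisher's LSD reports raw pairwise p only after a significant omnibus", {
  set.seed(14)
  design <- make_study_design(groups = c("control", "AD3", "AD4"),
                              n_subjects = 4, n_replicates = 1)
  null_mat <- matrix(rnorm(nrow(design), 10), nrow = 1,
                     dimnames = list("nullp", design$sample_id))
  strong <- matrix(c(rnorm(4, 0), rnorm(4, 30), rnorm(4, 60)), nrow = 1,
                   dimnames = list("strong", design$sample_id))
  res <- run_group_tests(rbind(null_mat, strong), design,
                         "anova_fisher_lsd")
  con <- res[res$contrast != "omnibus", ]
  # protected: non-significant omnibus blunts contrasts
  omni_null <- res$p[res$feature == "nullp" & res$contrast == "omnibus"]
  if (omni_null > 0.05) {
    expect_true(all(con$p_adj[con$feature == "nullp"] == 1))
  }
  # significant omnibus passes raw p through unadjusted
  expect_equal(con$p_adj[con$feature == "strong"],
               con$p[con$feature == "strong"])
})

test_that("rank-based and two-way variants run and keep the tier system consistent", {
  set.seed(16)
  design <- make_study_design(groups = c("control", "AD3", "AD4"),
                              n_subjects = 3, n_replicates = 3)
  mat <- matrix(rpois(3 * nrow(design), 25), nrow = 3,
                dimnames = list(paste0("P", 1:3), design$sample_id))
  for (tg in c("kruskal_ranks", "two_way_anova_bonferroni")) {
    res <- run_group_tests(mat, design, tg)
    expect_true(all(res$tier %in% c("ns", "p<=0.05", "p<=0.01",
                                    "p<=0.001")))
    expect_true(all(res$p_adj[res$tier == "ns"] > 0.05 |
                      res$degenerate[res$tier == "ns"]))
  }
})

test_that("dementia categories recover the planted trend semantics", {
  b <- small_bundle(seed = 7, dropout_rate = 0)
  pr <- bundle_protein_matrix(b)
  res <- run_group_tests(pr$mat, b$design, "anova_bonferroni")
  profiles <- group_mean_matrix(pr$mat, b$design,
                                group_order = unique(b$design$group))
  pres <- presence_by_condition(pr$attrib, zero_fill(b$quant), b$design,
                                level = "protein")
  cats <- classify_dementia_category(res, profiles, pres)
  lk <- setNames(cats$category, cats$feature)
  tr <- b$truth$protein_trends[names(lk)]
  expect_true(all(lk[tr == "vad_only"] == "VaD"))
  expect_true(all(lk[tr == "up_with_stage"] == "AD_progression"))
  expect_true(all(lk[tr == "down_with_stage"] == "AD_progression"))
  expect_true(mean(lk[tr == "flat"] == "none") >= 0.8)
})
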