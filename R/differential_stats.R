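# Stage-wise modulation analysis: fuzzy c-means trend clustering, isoform
# splitting by gene symbol, ANOVA-family tests with multiplicity control,
# and dementia-category assignment.

#' Fuzzy c-means clustering of abundance profiles
#'
#' Classic fuzzy c-means on per-feature z-scored group profiles:
#' alternating membership/centroid updates until the maximum centroid shift
#' falls below `tol` or `max_iter` iterations. Features whose maximum
#' membership is below `threshold` (default 0.5, the partition-coefficient
#' cutoff used for retaining proteins) are flagged unretained. When
#' `n_clusters` is `NULL`, k is chosen over `k_range` by maximizing the
#' fuzzy partition coefficient.
#'
#' @param profiles feature x condition matrix (e.g. protein x group means).
#' @param n_clusters number of clusters, or `NULL` to select automatically.
#' @param m fuzzifier (default 2).
#' @param seed RNG seed for centroid initialization.
#' @param threshold retention threshold on maximum membership.
#' @param standardize z-score rows before clustering (default `TRUE`).
#' @param tol,max_iter convergence controls.
#' @param k_range candidate k values for automatic selection.
#' @return object of class `fcm`: list with `assignments` (feature,
#'   cluster, membership, retained), `memberships` (feature x k matrix),
#'   `centers`, `objective` (per-iteration objective values,
#'   non-increasing), `k`, `fpc` (fuzzy partition coefficient).
#' @export
fuzzy_cluster <- function(profiles, n_clusters = NULL, m = 2, seed = 1L,
                          threshold = 0.5, standardize = TRUE, tol = 1e-6,
                          max_iter = 300L, k_range = 2:8) {
  stopifnot(is.matrix(profiles), m > 1)
  x <- profiles
  if (standardize) {
    x <- t(apply(profiles, 1, function(row) {
      s <- stats::sd(row)
      if (!is.finite(s) || s == 0) rep(0, length(row))
      else (row - mean(row)) / s
    }))
    dimnames(x) <- dimnames(profiles)
  }
  n <- nrow(x)
  if (is.null(n_clusters)) {
    ks <- k_range[k_range < n]
    if (length(ks) == 0) stop("too few features for any candidate k")
    fits <- lapply(ks, function(k) .fcm_fit(x, k, m, seed, tol, max_iter))
    fpcs <- vapply(fits, `[[`, 0, "fpc")
    fit <- fits[[which.max(fpcs)]]
  } else {
    if (n_clusters >= n) stop("n_clusters must be smaller than the number of features")
    if (n_clusters < 2) stop("n_clusters must be >= 2")
    fit <- .fcm_fit(x, n_clusters, m, seed, tol, max_iter)
  }
  u <- fit$memberships
  best <- max.col(u, ties.method = "first")
  assignments <- data.frame(
    feature = rownames(x),
    cluster = best,
    membership = u[cbind(seq_len(n), best)],
    stringsAsFactors = FALSE)
  assignments$retained <- assignments$membership >= threshold
  structure(list(assignments = assignments, memberships = u,
                 centers = fit$centers, objective = fit$objective,
                 k = ncol(u), fpc = fit$fpc, standardized = x),
            class = "fcm")
}

# one fuzzy c-means run; memberships initialized from a seeded Dirichlet-ish
# draw so runs are reproducible
.fcm_fit <- function(x, k, m, seed, tol, max_iter) {
  set.seed(seed)
  n <- nrow(x)
  u <- matrix(stats::runif(n * k), n, k)
  u <- u / rowSums(u)
  centers_old <- matrix(Inf, k, ncol(x))
  objective <- numeric(0)
  for (iter in seq_len(max_iter)) {
    um <- u^m
    centers <- (t(um) %*% x) / colSums(um)
    d2 <- outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    d2[d2 < 0] <- 0
    objective <- c(objective, sum(um * d2))
    zero <- d2 < .Machine$double.eps
    pow <- d2^(-1 / (m - 1))
    u <- pow / rowSums(pow)
    if (any(zero)) {
      for (i in which(rowSums(zero) > 0)) {
        u[i, ] <- as.numeric(zero[i, ]) / sum(zero[i, ])
      }
    }
    shift <- max(abs(centers - centers_old))
    centers_old <- centers
    if (shift < tol) break
  }
  list(memberships = u, centers = centers, objective = objective,
       fpc = mean(rowSums(u^2)))
}

#' @export
print.fcm <- function(x, ...) {
  cat(sprintf("fuzzy c-means: k = %d, FPC = %.3f, %d/%d features retained (membership >= 0.5)\n",
              x$k, x$fpc, sum(x$assignments$retained),
              nrow(x$assignments)))
  invisible(x)
}

#' Split gene symbols into isoforms by cluster membership
#'
#' Proteins sharing a gene symbol but falling into different abundance-trend
#' clusters are treated as distinct isoforms (e.g. a chaperone encoded by
#' many taxa whose variants are modulated differently with disease stage).
#' Within a symbol, subscript indices are assigned in descending order of
#' the clusters' mean first-condition abundance, which makes labels
#' deterministic under cluster relabeling.
#'
#' @param fcm_fit an `fcm` object (or its `assignments` data.frame).
#' @param gene_symbols named character vector, names = feature ids.
#' @param first_stage_means named numeric vector of first-condition means
#'   (names = feature ids), used for deterministic subscript ordering.
#' @return data.frame: `feature`, `gene_symbol`, `cluster`,
#'   `isoform_label`. Symbols with a single member keep the bare symbol.
#' @export
split_isoforms <- function(fcm_fit, gene_symbols, first_stage_means) {
  assignments <- if (inherits(fcm_fit, "fcm")) fcm_fit$assignments
                 else fcm_fit
  df <- data.frame(feature = assignments$feature,
                   cluster = assignments$cluster,
                   gene_symbol = gene_symbols[assignments$feature],
                   stringsAsFactors = FALSE)
  df$first_mean <- first_stage_means[df$feature]
  out <- lapply(split(df, df$gene_symbol), function(sub) {
    clusters <- unique(sub$cluster)
    if (nrow(sub) == 1 || length(clusters) == 1) {
      sub$isoform_label <- sub$gene_symbol
      return(sub)
    }
    cl_mean <- vapply(clusters, function(cl)
      mean(sub$first_mean[sub$cluster == cl]), 0)
    ord <- clusters[order(-cl_mean, clusters)]
    sub$isoform_label <- paste0(sub$gene_symbol, "_",
                                match(sub$cluster, ord))
    sub
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("feature", "gene_symbol", "cluster", "isoform_label")]
}

.TIERS <- c("ns", "p<=0.05", "p<=0.01", "p<=0.001")

.p_tier <- function(p) {
  ifelse(is.na(p), "ns",
         ifelse(p <= 0.001, "p<=0.001",
                ifelse(p <= 0.01, "p<=0.01",
                       ifelse(p <= 0.05, "p<=0.05", "ns"))))
}

# pairwise pooled-variance t statistics from group means and a shared MSE
.pooled_pairwise <- function(means, ns, mse, df_err, adjust) {
  gs <- names(means)
  combs <- utils::combn(gs, 2)
  n_c <- ncol(combs)
  res <- data.frame(contrast = paste(combs[1, ], "vs", combs[2, ]),
                    statistic = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n_c)) {
    a <- combs[1, i]; b <- combs[2, i]
    se <- sqrt(mse * (1 / ns[a] + 1 / ns[b]))
    tstat <- if (se > 0) (means[a] - means[b]) / se else 0
    res$statistic[i] <- tstat
    res$p[i] <- 2 * stats::pt(-abs(tstat), df_err)
  }
  res$p_adj <- if (adjust == "bonferroni") pmin(1, res$p * n_c) else res$p
  res
}

#' Group-comparison tests per feature
#'
#' Runs one of four test variants per feature over the study groups:
#' \describe{
#'   \item{anova_bonferroni}{one-way ANOVA omnibus plus all pairwise
#'     pooled-variance t contrasts, Bonferroni-adjusted within the
#'     feature's contrast family.}
#'   \item{anova_fisher_lsd}{one-way ANOVA omnibus; pairwise contrasts
#'     reported unadjusted and only meaningful after a significant omnibus
#'     (protected LSD).}
#'   \item{kruskal_ranks}{one-way ANOVA on ranks (Kruskal-Wallis omnibus)
#'     with pairwise pooled-variance contrasts on the rank-transformed
#'     values.}
#'   \item{two_way_anova_bonferroni}{two-way ANOVA with factors group and
#'     replicate batch on replicate-level data; group contrasts use the
#'     model MSE, Bonferroni-adjusted.}
#' }
#' Technical replicates are averaged within subject first (except for the
#' two-way variant, which needs the replicate factor). Features whose
#' values are identical everywhere are flagged degenerate with p = 1.
#'
#' @param mat feature x sample matrix.
#' @param design study design.
#' @param test test tag (see above).
#' @param alpha significance level used for the `significant` flag.
#' @return long data.frame of `StatResult` rows: `feature`, `test`,
#'   `contrast` (`"omnibus"` or `"A vs B"`), `statistic`, `p`, `p_adj`,
#'   `tier`, `degenerate`.
#' @export
run_group_tests <- function(mat, design,
                            test = c("anova_bonferroni", "anova_fisher_lsd",
                                     "kruskal_ranks",
                                     "two_way_anova_bonferroni"),
                            alpha = 0.05) {
  test <- match.arg(test)
  stopifnot(alpha > 0, alpha < 1)
  if (test == "two_way_anova_bonferroni") {
    values_mat <- mat
    key <- design[match(colnames(mat), design$sample_id), ]
    group <- factor(key$group, levels = unique(design$group))
    batch <- factor(key$replicate)
  } else {
    values_mat <- subject_level_matrix(mat, design)
    key <- design[match(colnames(values_mat), design$subject_id), ]
    group <- factor(key$group, levels = unique(design$group))
    batch <- NULL
  }
  if (nlevels(group) < 2) stop("need at least two groups")
  if (min(table(group)) < 2 && test != "kruskal_ranks") {
    stop("parametric tests need >= 2 observations per group")
  }

  one_feature <- function(values) {
    degenerate <- stats::sd(values) == 0
    if (degenerate) {
      gs <- levels(group)
      combs <- utils::combn(gs, 2)
      contrasts <- data.frame(contrast = paste(combs[1, ], "vs", combs[2, ]),
                              statistic = 0, p = 1, p_adj = 1,
                              stringsAsFactors = FALSE)
      omni <- data.frame(contrast = "omnibus", statistic = 0, p = 1,
                         p_adj = 1, stringsAsFactors = FALSE)
      res <- rbind(omni, contrasts)
      res$degenerate <- TRUE
      return(res)
    }
    y <- if (test == "kruskal_ranks") rank(values) else values
    means <- tapply(y, group, mean)
    ns <- tapply(y, group, length)
    if (test == "two_way_anova_bonferroni") {
      if (nlevels(batch) < 2) {
        stop("two-way ANOVA needs >= 2 replicate batches")
      }
      fit <- stats::aov(y ~ group + batch)
      sm <- summary(fit)[[1]]
      f_stat <- sm["group", "F value"]
      p_omni <- sm["group", "Pr(>F)"]
      mse <- sm["Residuals", "Mean Sq"]
      df_err <- sm["Residuals", "Df"]
      contrasts <- .pooled_pairwise(means, ns, mse, df_err, "bonferroni")
    } else {
      fit <- stats::aov(y ~ group)
      sm <- summary(fit)[[1]]
      f_stat <- sm["group", "F value"]
      p_omni <- sm["group", "Pr(>F)"]
      mse <- sm["Residuals", "Mean Sq"]
      df_err <- sm["Residuals", "Df"]
      if (test == "kruskal_ranks") {
        kw <- stats::kruskal.test(values, group)
        f_stat <- unname(kw$statistic)
        p_omni <- kw$p.value
        contrasts <- .pooled_pairwise(means, ns, mse, df_err, "bonferroni")
      } else if (test == "anova_fisher_lsd") {
        contrasts <- .pooled_pairwise(means, ns, mse, df_err, "none")
        # protected LSD: contrasts only interpretable after significant
        # omnibus; blunt them to ns otherwise
        if (is.na(p_omni) || p_omni > alpha) contrasts$p_adj <- 1
      } else {
        contrasts <- .pooled_pairwise(means, ns, mse, df_err, "bonferroni")
      }
    }
    omni <- data.frame(contrast = "omnibus", statistic = unname(f_stat),
                       p = unname(p_omni), p_adj = unname(p_omni),
                       stringsAsFactors = FALSE)
    res <- rbind(omni, contrasts)
    res$degenerate <- FALSE
    res
  }

  out <- lapply(rownames(values_mat), function(f) {
    res <- one_feature(values_mat[f, ])
    res$feature <- f
    res
  })
  res <- do.call(rbind, out)
  res$test <- test
  res$tier <- .p_tier(res$p_adj)
  res$significant <- !is.na(res$p_adj) & res$p_adj <= alpha & !res$degenerate
  rownames(res) <- NULL
  res[, c("feature", "test", "contrast", "statistic", "p", "p_adj", "tier",
          "degenerate", "significant")]
}

#' Features significant in a test-result table
#'
#' A feature is significant iff any of its pairwise contrasts has adjusted
#' p below `alpha` (the within-feature contrast family controls the
#' family-wise error rate, so under the null the fraction of significant
#' features stays near `alpha`).
#'
#' @param results output of [run_group_tests()].
#' @param alpha significance level.
#' @return character vector of significant features.
#' @export
significant_features <- function(results, alpha = 0.05) {
  con <- results[results$contrast != "omnibus", , drop = FALSE]
  sig <- con[!is.na(con$p_adj) & con$p_adj <= alpha & !con$degenerate, ]
  unique(sig$feature)
}

#' Assign dementia-related categories to proteins
#'
#' Deterministic rule set applied to stage-wise contrast results, presence
#' calls and trend monotonicity; precedence (documented in the methods
#' vignette): AD_progression, then VaD, then early_AD, then AD, else none.
#' \describe{
#'   \item{AD_progression}{group-mean profile monotone across the AD stage
#'     axis and at least one significant stage-vs-control contrast.}
#'   \item{VaD}{significant contrast involving the VaD group, or presence
#'     exclusive to VaD.}
#'   \item{early_AD}{significant control-vs-first-stage contrast, or
#'     presence in the first AD stage but no later stage nor VaD.}
#'   \item{AD}{any other significant stage-vs-control contrast.}
#' }
#'
#' @param results output of [run_group_tests()] for the proteins.
#' @param group_means protein x group mean matrix (columns in stage order,
#'   control first; a column named per `vad_group` is treated off-axis).
#' @param presence optional protein presence matrix from
#'   [presence_by_condition()] (`level = "protein"`).
#' @param control_group,vad_group group labels (defaults "control", "VaD").
#' @param alpha significance level.
#' @return data.frame: `feature`, `category`.
#' @export
classify_dementia_category <- function(results, group_means,
                                       presence = NULL,
                                       control_group = "control",
                                       vad_group = "VaD", alpha = 0.05) {
  stage_cols <- setdiff(colnames(group_means), vad_group)
  ad_stages <- setdiff(stage_cols, control_group)
  first_stage <- ad_stages[1]
  con <- results[results$contrast != "omnibus" & !results$degenerate, ,
                 drop = FALSE]
  con_sig <- con[!is.na(con$p_adj) & con$p_adj <= alpha, , drop = FALSE]

  involves <- function(contrast, g) {
    sides <- strsplit(contrast, " vs ", fixed = TRUE)
    vapply(sides, function(s) g %in% s, logical(1))
  }
  classify_one <- function(f) {
    sig <- con_sig[con_sig$feature == f, , drop = FALSE]
    prof <- group_means[f, stage_cols]
    d <- diff(prof)
    monotone <- (all(d >= 0) || all(d <= 0)) && any(d != 0)
    sig_vs_control <- sig[involves(sig$contrast, control_group), ,
                          drop = FALSE]
    sig_stage_vs_control <- if (nrow(sig_vs_control) == 0) {
      sig_vs_control
    } else {
      hits <- vapply(ad_stages, function(g)
        involves(sig_vs_control$contrast, g),
        logical(nrow(sig_vs_control)))
      if (is.null(dim(hits))) hits <- matrix(hits, nrow = 1)
      sig_vs_control[rowSums(hits) > 0, , drop = FALSE]
    }
    # VaD modulation means VaD differs from control, not merely from some
    # AD stage that is itself modulated
    sig_vad <- any(involves(sig$contrast, vad_group) &
                     involves(sig$contrast, control_group))
    pres <- if (!is.null(presence) && f %in% rownames(presence))
      presence[f, ] else NULL
    only_in <- function(g) {
      if (is.null(pres)) return(FALSE)
      others <- setdiff(c(ad_stages, vad_group), g)
      others <- intersect(others, names(pres))
      isTRUE(pres[g]) && !any(pres[others])
    }
    if (monotone && nrow(sig_stage_vs_control) > 0) return("AD_progression")
    if (sig_vad || only_in(vad_group)) return("VaD")
    sig_early <- any(involves(sig_stage_vs_control$contrast, first_stage))
    if (sig_early || only_in(first_stage)) return("early_AD")
    if (nrow(sig_stage_vs_control) > 0) return("AD")
    "none"
  }
  feats <- rownames(group_means)
  data.frame(feature = feats,
             category = vapply(feats, classify_one, character(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
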