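# Pearson correlation screens: protein-level cross-compartment
# correlations and peptidome-wide heatmap tables with sign-reversal
# detection between groups.

#' Strength tier of a correlation coefficient
#'
#' `"strong"` for `|r| >= 0.70`, `"very_strong"` for `|r| >= 0.85`,
#' `"none"` otherwise.
#'
#' @param r numeric vector of Pearson coefficients.
#' @param strong,very_strong thresholds.
#' @return character vector of tiers.
#' @export
correlation_tier <- function(r, strong = 0.70, very_strong = 0.85) {
  ifelse(is.na(r), NA_character_,
         ifelse(abs(r) >= very_strong, "very_strong",
                ifelse(abs(r) >= strong, "strong", "none")))
}

# r, t-test p and Fisher-z CI for paired vectors; NA with a flag when a
# vector has zero variance or n < 3
.pearson_row <- function(x, y, conf = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3) {
    return(c(n = n, r = NA, ci_low = NA, ci_high = NA, p = NA, flag = 1))
  }
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(c(n = n, r = NA, ci_low = NA, ci_high = NA, p = NA, flag = 2))
  }
  r <- stats::cor(x, y)
  r_c <- max(min(r, 1 - 1e-15), -1 + 1e-15)
  tstat <- r_c * sqrt((n - 2) / (1 - r_c^2))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  z <- atanh(r_c)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  c(n = n, r = r, ci_low = tanh(z - q * se), ci_high = tanh(z + q * se),
    p = p, flag = 0)
}

#' Pairwise Pearson correlations between two feature matrices
#'
#' Computes r, the t-transform p value, and a Fisher-z 95% confidence
#' interval for feature pairs over the samples of one study group (or all
#' shared columns when `design`/`group` are omitted). `pairs = "all"`
#' crosses every row of `a` with every row of `b`; `pairs = "matched"`
#' correlates row i of `a` with row i of `b`.
#'
#' @param a,b feature x sample matrices sharing column names.
#' @param design optional study design used to subset samples by group.
#' @param group optional group label.
#' @param pairs `"all"`, `"matched"`, or a two-column data.frame of
#'   (feature_a, feature_b).
#' @param conf confidence level for the interval.
#' @return data.frame: `feature_a`, `feature_b`, `group`, `n`, `r`,
#'   `ci_low`, `ci_high`, `p`, `tier` (strength thresholds 0.70/0.85),
#'   `significant` (p <= 0.05), `flag` (`"ok"`, `"n_too_small"`,
#'   `"zero_variance"`).
#' @export
correlate_pairs <- function(a, b, design = NULL, group = NULL,
                            pairs = "all", conf = 0.95) {
  stopifnot(is.matrix(a), is.matrix(b))
  cols <- intersect(colnames(a), colnames(b))
  if (!is.null(design) && !is.null(group)) {
    keep <- design$sample_id[design$group == group]
    if (length(keep) == 0) stop("group absent from design: ", group)
    cols <- intersect(cols, keep)
  }
  if (length(cols) == 0) stop("no shared samples between the two matrices")
  a <- a[, cols, drop = FALSE]
  b <- b[, cols, drop = FALSE]
  if (identical(pairs, "all")) {
    pair_df <- expand.grid(feature_a = rownames(a), feature_b = rownames(b),
                           stringsAsFactors = FALSE)
  } else if (identical(pairs, "matched")) {
    stopifnot(nrow(a) == nrow(b))
    pair_df <- data.frame(feature_a = rownames(a), feature_b = rownames(b),
                          stringsAsFactors = FALSE)
  } else {
    pair_df <- data.frame(feature_a = pairs[[1]], feature_b = pairs[[2]],
                          stringsAsFactors = FALSE)
  }
  stats_mat <- t(vapply(seq_len(nrow(pair_df)), function(i) {
    .pearson_row(a[pair_df$feature_a[i], ], b[pair_df$feature_b[i], ],
                 conf = conf)
  }, c(n = 0, r = 0, ci_low = 0, ci_high = 0, p = 0, flag = 0)))
  res <- cbind(pair_df, as.data.frame(stats_mat))
  res$group <- if (is.null(group)) NA_character_ else group
  res$tier <- correlation_tier(res$r)
  res$significant <- !is.na(res$p) & res$p <= 0.05
  res$flag <- c("ok", "n_too_small", "zero_variance")[res$flag + 1]
  rownames(res) <- NULL
  res[, c("feature_a", "feature_b", "group", "n", "r", "ci_low", "ci_high",
          "p", "tier", "significant", "flag")]
}

#' Peptide-level correlation heatmap table with reversal detection
#'
#' For every requested group, correlates each microbial peptide with each
#' marker peptide, keeps pairs reaching `|r| > r_filter` in at least one
#' group, tiers p values (p <= 0.05 / 0.01 / 0.001), and reports pairs
#' whose correlation crosses from `>= +flip_threshold` in one group to
#' `<= -flip_threshold` in another with both correlations significant
#' (reversed correlations). Self-pairs (identical feature id on both
#' sides) are excluded from the reversal report by definition.
#'
#' @param microbial,marker peptide x sample matrices.
#' @param design study design.
#' @param groups character vector of >= 2 group labels.
#' @param r_filter table filter on `|r|` (default 0.5).
#' @param flip_threshold reversal threshold (default 0.5).
#' @param alpha significance level for the reversal report.
#' @return list with `table` (long-form correlations, `p_tier` column) and
#'   `reversals` (`feature_a`, `feature_b`, `group_pos`, `r_pos`,
#'   `group_neg`, `r_neg`).
#' @export
peptide_heatmap_table <- function(microbial, marker, design, groups,
                                  r_filter = 0.5, flip_threshold = 0.5,
                                  alpha = 0.05) {
  if (length(groups) < 2) stop("need >= 2 groups for a reversal screen")
  missing_groups <- setdiff(groups, unique(design$group))
  if (length(missing_groups) > 0) {
    stop("group(s) absent from design: ",
         paste(missing_groups, collapse = ", "))
  }
  per_group <- lapply(groups, function(g)
    correlate_pairs(microbial, marker, design, g))
  tab <- do.call(rbind, per_group)
  tab$p_tier <- .p_tier(tab$p)
  key <- paste(tab$feature_a, tab$feature_b, sep = "\t")
  keep_keys <- unique(key[!is.na(tab$r) & abs(tab$r) > r_filter])
  filtered <- tab[key %in% keep_keys, , drop = FALSE]

  reversals <- list()
  for (k in keep_keys) {
    rows <- tab[key == k, , drop = FALSE]
    if (rows$feature_a[1] == rows$feature_b[1]) next
    ok <- !is.na(rows$r) & rows$significant
    pos <- rows[ok & rows$r >= flip_threshold, , drop = FALSE]
    neg <- rows[ok & rows$r <= -flip_threshold, , drop = FALSE]
    if (nrow(pos) > 0 && nrow(neg) > 0) {
      reversals[[length(reversals) + 1]] <- data.frame(
        feature_a = rows$feature_a[1], feature_b = rows$feature_b[1],
        group_pos = pos$group[1], r_pos = pos$r[1],
        group_neg = neg$group[1], r_neg = neg$r[1],
        stringsAsFactors = FALSE)
    }
  }
  reversals <- if (length(reversals) > 0) do.call(rbind, reversals) else
    data.frame(feature_a = character(0), feature_b = character(0),
               group_pos = character(0), r_pos = numeric(0),
               group_neg = character(0), r_neg = numeric(0))
  rownames(filtered) <- NULL
  list(table = filtered, reversals = reversals)
}

#' Cross-compartment correlation of common proteins
#'
#' Partitions proteins into compartment-A-only, compartment-B-only and
#' common (detected in both), pairs samples by subject (technical
#' replicates averaged within subject), and computes one Pearson
#' correlation per common protein between its levels in the two
#' compartments. Negative significant correlations are flagged -- the
#' pattern of interest when vesicle and tissue levels trade off.
#'
#' @param mat_a,mat_b protein x sample matrices for the two compartments
#'   (e.g. brain extracellular vesicles and the remaining whole-brain
#'   tissue fraction).
#' @param design_a,design_b study designs mapping each compartment's
#'   samples to subjects.
#' @return list with `partition` (counts a_only / b_only / common and the
#'   protein id sets) and `correlations` (one row per common protein).
#' @export
cross_compartment_correlation <- function(mat_a, mat_b, design_a,
                                          design_b = design_a) {
  det_a <- rownames(mat_a)[rowSums(mat_a > 0) > 0]
  det_b <- rownames(mat_b)[rowSums(mat_b > 0) > 0]
  common <- intersect(det_a, det_b)
  partition <- list(a_only = setdiff(det_a, det_b),
                    b_only = setdiff(det_b, det_a),
                    common = common,
                    n_a_only = length(setdiff(det_a, det_b)),
                    n_b_only = length(setdiff(det_b, det_a)),
                    n_common = length(common))
  if (length(common) == 0) {
    warning("no common proteins between compartments")
    return(list(partition = partition,
                correlations = data.frame(feature_a = character(0))))
  }
  subj_a <- subject_level_matrix(mat_a[common, , drop = FALSE], design_a)
  subj_b <- subject_level_matrix(mat_b[common, , drop = FALSE], design_b)
  shared <- intersect(colnames(subj_a), colnames(subj_b))
  cors <- correlate_pairs(subj_a[, shared, drop = FALSE],
                          subj_b[, shared, drop = FALSE],
                          pairs = "matched")
  cors$negative_significant <- cors$significant & !is.na(cors$r) & cors$r < 0
  list(partition = partition, correlations = cors)
}
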