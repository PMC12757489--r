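# Spectral-count quantification.
#
# The long-form quantification table has one row per (peptide, sample) with
# a non-negative integer spectral count, or NA when the peptide was "not
# detected" in that sample. Protein abundance is the sum of the counts of
# the protein's unique peptides, so shared peptides never contribute to any
# protein (cross-attribution control).

#' Replace missing counts with zeros
#'
#' Missing values recorded as "not detected" become 0 prior to
#' protein-level quantification. Idempotent; the number of filled cells is
#' stored in the `"filled"` attribute.
#'
#' @param quant long quantification table (`peptide`, `sample_id`, `count`).
#' @return the table with no missing counts.
#' @export
zero_fill <- function(quant) {
  n_missing <- sum(is.na(quant$count))
  quant$count[is.na(quant$count)] <- 0
  if (any(quant$count < 0)) stop("negative counts are not allowed")
  attr(quant, "filled") <- n_missing
  quant
}

#' Roll peptide counts up to a protein x sample matrix
#'
#' Only peptides unique to a single protein contribute; a protein's value in
#' a sample is the sum of its unique-peptide counts there, so the matrix
#' total equals the unique-peptide count total exactly (mass balance).
#' Proteins without any unique peptide appear as all-zero rows with a
#' warning.
#'
#' @param quant zero-filled long quantification table.
#' @param attrib an `AttributionTable`.
#' @return numeric matrix, rows = protein accessions, columns = samples.
#' @export
rollup_to_protein <- function(quant, attrib) {
  stopifnot(inherits(attrib, "AttributionTable"))
  if (anyNA(quant$count)) stop("apply zero_fill() before rollup")
  uniq <- attrib$peptides[attrib$peptides$unique_to_protein, , drop = FALSE]
  samples <- sort(unique(quant$sample_id))
  proteins <- sort(unique(attrib$proteins$accession))
  mat <- matrix(0, nrow = length(proteins), ncol = length(samples),
                dimnames = list(proteins, samples))
  q <- quant[quant$peptide %in% uniq$peptide, , drop = FALSE]
  if (nrow(q) > 0) {
    q$protein <- uniq$proteins[match(q$peptide, uniq$peptide)]
    agg <- stats::aggregate(count ~ protein + sample_id, data = q, FUN = sum)
    agg <- agg[agg$protein %in% proteins, , drop = FALSE]
    mat[cbind(agg$protein, agg$sample_id)] <- agg$count
  }
  no_unique <- proteins[!(proteins %in% unique(q$protein))]
  if (length(no_unique) > 0) {
    warning(length(no_unique),
            " protein(s) without unique peptides have all-zero rows: ",
            paste(utils::head(no_unique, 5), collapse = ", "))
  }
  mat
}

#' Average technical replicates to subject level
#'
#' @param mat feature x sample matrix.
#' @param design study design with `sample_id` and `subject_id`.
#' @return feature x subject matrix (mean over each subject's replicates).
#' @export
subject_level_matrix <- function(mat, design) {
  samples <- colnames(mat)
  subj <- design$subject_id[match(samples, design$sample_id)]
  if (anyNA(subj)) {
    stop("samples absent from design: ",
         paste(utils::head(samples[is.na(subj)], 5), collapse = ", "))
  }
  groups <- split(seq_along(samples), subj)
  out <- vapply(groups, function(j)
    rowMeans(mat[, j, drop = FALSE]), numeric(nrow(mat)))
  if (nrow(mat) == 1) out <- matrix(out, nrow = 1,
                                    dimnames = list(rownames(mat),
                                                    names(groups)))
  out
}

#' Per-group means and SEMs of a protein matrix
#'
#' Technical replicates are first averaged within subject (so n per group is
#' the number of subjects), then group mean and SEM are computed over
#' subjects; `replicates = "pooled"` instead treats every sample as one
#' observation. SEM is reported as `NA` for single-observation groups.
#'
#' @param mat protein x sample matrix.
#' @param design study design.
#' @param replicates `"subject"` (default) or `"pooled"`.
#' @return long data.frame: `protein`, `group`, `mean`, `sem`, `n`.
#' @export
group_summarize <- function(mat, design, replicates = c("subject",
                                                        "pooled")) {
  replicates <- match.arg(replicates)
  if (replicates == "subject") {
    mat <- subject_level_matrix(mat, design)
    key <- design$group[match(colnames(mat),
                              design$subject_id)]
  } else {
    key <- design$group[match(colnames(mat), design$sample_id)]
  }
  if (anyNA(key)) stop("columns of mat not resolvable in design")
  groups <- unique(design$group)
  out <- lapply(groups, function(g) {
    sub <- mat[, key == g, drop = FALSE]
    n <- ncol(sub)
    if (n == 0) stop("group without samples: ", g)
    data.frame(protein = rownames(mat),
               group = g,
               mean = rowMeans(sub),
               sem = if (n > 1) apply(sub, 1, stats::sd) / sqrt(n)
                     else NA_real_,
               n = n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Protein x group mean matrix
#'
#' Convenience wrapper around [group_summarize()] returning the mean profile
#' matrix used for trend clustering.
#'
#' @inheritParams group_summarize
#' @param group_order optional column order.
#' @return protein x group matrix of means.
#' @export
group_mean_matrix <- function(mat, design, group_order = NULL,
                              replicates = "subject") {
  gs <- group_summarize(mat, design, replicates = replicates)
  groups <- if (is.null(group_order)) unique(design$group) else group_order
  out <- sapply(groups, function(g) {
    sub <- gs[gs$group == g, ]
    stats::setNames(sub$mean, sub$protein)[rownames(mat)]
  })
  if (nrow(mat) == 1) out <- matrix(out, nrow = 1,
                                    dimnames = list(rownames(mat), groups))
  out
}

#' Left-censored imputation followed by log2 transform
#'
#' Zeros (and missing values) are assumed to fall below the detection limit
#' and are replaced before log2: the deterministic `"half_min"` policy uses
#' half the minimum positive value of the protein's row; the stochastic
#' `"shifted_gaussian"` policy draws, per column, from a Gaussian in log2
#' space down-shifted by `shift` standard deviations with width
#' `width` standard deviations (seeded for reproducibility). Rows with no
#' positive value are flagged and imputed at half the global minimum
#' positive value.
#'
#' @param mat non-negative protein x sample matrix.
#' @param policy `"half_min"` (default) or `"shifted_gaussian"`.
#' @param seed RNG seed for the stochastic policy.
#' @param shift,width down-shift and width in SD units (log2 space).
#' @return log2-transformed matrix, finite everywhere; all-zero rows are
#'   listed in the `"flagged_rows"` attribute.
#' @export
censored_impute_log2 <- function(mat, policy = c("half_min",
                                                 "shifted_gaussian"),
                                 seed = 1L, shift = 1.8, width = 0.3) {
  policy <- match.arg(policy)
  if (any(mat < 0, na.rm = TRUE)) stop("matrix must be non-negative")
  mat[is.na(mat)] <- 0
  pos <- mat[mat > 0]
  if (length(pos) == 0) stop("matrix has no positive values to anchor imputation")
  global_floor <- min(pos) / 2
  all_zero <- rownames(mat)[rowSums(mat > 0) == 0]

  if (policy == "half_min") {
    out <- t(apply(mat, 1, function(row) {
      rp <- row[row > 0]
      floor_val <- if (length(rp) > 0) min(rp) / 2 else global_floor
      row[row == 0] <- floor_val
      row
    }))
    dimnames(out) <- dimnames(mat)
    out <- log2(out)
  } else {
    out <- log2(ifelse(mat == 0, NA, mat))
    set.seed(seed)
    for (j in seq_len(ncol(out))) {
      col <- out[, j]
      miss <- is.na(col)
      if (!any(miss)) next
      mu <- mean(col, na.rm = TRUE)
      sdv <- stats::sd(col, na.rm = TRUE)
      if (!is.finite(mu)) { mu <- log2(global_floor); sdv <- 0.5 }
      if (!is.finite(sdv) || sdv == 0) sdv <- 0.5
      out[miss, j] <- stats::rnorm(sum(miss), mean = mu - shift * sdv,
                                   sd = width * sdv)
    }
  }
  stopifnot(all(is.finite(out)))
  attr(out, "flagged_rows") <- all_zero
  out
}
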