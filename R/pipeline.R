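# End-to-end pipeline orchestration with a serializable config and a
# reproducibility manifest.

#' Build a pipeline configuration
#'
#' All tunable parameters of the pipeline in one serializable list; see
#' [validate_config()] for the accepted ranges.
#'
#' @param input_dir directory holding a bundle (`microbial.fasta`,
#'   `host.fasta`, `annotations.tsv`, `peptides.tsv`, `design.tsv`).
#' @param outdir output directory.
#' @param max_missed,min_len,max_len digestion parameters.
#' @param filter_mode `"substring"` or `"tryptic"` host filtering.
#' @param impute_policy `"half_min"` or `"shifted_gaussian"`.
#' @param alpha significance level.
#' @param n_clusters fuzzy c-means k (`NULL` = select by partition
#'   coefficient).
#' @param membership_threshold cluster retention threshold.
#' @param r_strong,r_very_strong,r_filter correlation thresholds.
#' @param seed RNG seed for all stochastic stages.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, outdir,
                            max_missed = 2, min_len = 7, max_len = 22,
                            filter_mode = "substring",
                            impute_policy = "half_min", alpha = 0.05,
                            n_clusters = NULL, membership_threshold = 0.5,
                            r_strong = 0.70, r_very_strong = 0.85,
                            r_filter = 0.5, seed = 1L) {
  structure(list(input_dir = input_dir, outdir = outdir,
                 max_missed = max_missed, min_len = min_len,
                 max_len = max_len, filter_mode = filter_mode,
                 impute_policy = impute_policy, alpha = alpha,
                 n_clusters = n_clusters,
                 membership_threshold = membership_threshold,
                 r_strong = r_strong, r_very_strong = r_very_strong,
                 r_filter = r_filter, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks every range and aggregates all problems rather than failing on
#' the first.
#'
#' @param config a `pipeline_config`.
#' @return character vector of error messages (length 0 when valid).
#' @export
validate_config <- function(config) {
  errors <- character(0)
  add <- function(msg) errors <<- c(errors, msg)
  num_in <- function(x, lo, hi, open_lo = FALSE, open_hi = FALSE) {
    is.numeric(x) && length(x) == 1 && is.finite(x) &&
      (if (open_lo) x > lo else x >= lo) &&
      (if (open_hi) x < hi else x <= hi)
  }
  if (!num_in(config$alpha, 0, 1, TRUE, TRUE)) {
    add("alpha must be in (0, 1)")
  }
  if (!num_in(config$min_len, 1, Inf)) add("min_len must be >= 1")
  if (is.numeric(config$min_len) && is.numeric(config$max_len) &&
      config$min_len > config$max_len) {
    add("min_len must not exceed max_len")
  }
  if (!num_in(config$max_missed, 0, Inf)) add("max_missed must be >= 0")
  if (!config$filter_mode %in% c("substring", "tryptic")) {
    add("filter_mode must be 'substring' or 'tryptic'")
  }
  if (!config$impute_policy %in% c("half_min", "shifted_gaussian")) {
    add("impute_policy must be 'half_min' or 'shifted_gaussian'")
  }
  if (!num_in(config$membership_threshold, 0, 1, TRUE, FALSE)) {
    add("membership_threshold must be in (0, 1]")
  }
  for (fld in c("r_strong", "r_very_strong", "r_filter")) {
    if (!num_in(config[[fld]], 0, 1, TRUE, FALSE)) {
      add(paste(fld, "must be in (0, 1]"))
    }
  }
  if (!is.null(config$n_clusters) &&
      !num_in(config$n_clusters, 2, Inf)) {
    add("n_clusters must be >= 2 or NULL")
  }
  errors
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

#' Run the full pipeline
#'
#' Executes digest/index, host filtering, attribution, quantification,
#' statistics and correlation stages on a bundle directory, writes all
#' tables, and emits `manifest.json` with input/output checksums, the
#' configuration and the seed. File names inside the manifest are relative
#' to the bundle/output directories, so re-running the same configuration
#' on the same inputs reproduces a byte-identical manifest.
#'
#' @param config a valid `pipeline_config`.
#' @return invisible list with the main stage outputs and `manifest`.
#' @export
run_pipeline <- function(config) {
  errors <- validate_config(config)
  if (length(errors) > 0) {
    stop("invalid config:\n  - ", paste(errors, collapse = "\n  - "))
  }
  ip <- function(f) file.path(config$input_dir, f)
  inputs <- c("microbial.fasta", "host.fasta", "annotations.tsv",
              "peptides.tsv", "design.tsv")
  missing_in <- inputs[!file.exists(ip(inputs))]
  if (length(missing_in) > 0) {
    stop("stage input: missing input file(s): ",
         paste(missing_in, collapse = ", "))
  }
  if (!dir.exists(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE)
  }
  op <- function(f) file.path(config$outdir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  stages_run <- character(0)
  outputs <- character(0)

  # 1. load
  stages_run <- c(stages_run, "load")
  microbial <- stage("load", read_fasta(ip("microbial.fasta"), "microbial"))
  host <- stage("load", read_fasta(ip("host.fasta"), "host"))
  annotations <- stage("load", suppressWarnings(
    read_taxon_annotations(ip("annotations.tsv"),
                           taxa = unique(microbial$records$taxon_id))))
  quant <- stage("load", utils::read.delim(ip("peptides.tsv"),
                                           stringsAsFactors = FALSE,
                                           na.strings = ""))
  design <- stage("load", utils::read.delim(ip("design.tsv"),
                                            stringsAsFactors = FALSE))

  # 2. digest + index
  stages_run <- c(stages_run, "index")
  index <- stage("index", build_peptide_index(
    microbial, max_missed = config$max_missed, min_len = config$min_len,
    max_len = config$max_len))

  # 3. host homology filter
  stages_run <- c(stages_run, "host_filter")
  filt <- stage("host_filter", filter_host_homologs(
    unique(quant$peptide), host, mode = config$filter_mode,
    max_missed = config$max_missed, min_len = config$min_len,
    max_len = config$max_len))
  outputs <- c(outputs, .write_tsv(filt$report$decisions,
                                   op("filter_report.tsv")))

  # 4. attribution
  stages_run <- c(stages_run, "attribute")
  attrib <- stage("attribute",
                  attribute_peptides(filt$retained, index, annotations))
  outputs <- c(outputs, .write_tsv(attrib$peptides, op("attribution_peptides.tsv")),
               .write_tsv(attrib$taxa, op("attribution_taxa.tsv")))
  presence <- stage("attribute", presence_by_condition(
    attrib, zero_fill(quant), design, level = "protein"))
  outputs <- c(outputs, .write_tsv(
    data.frame(feature = rownames(presence), presence, check.names = FALSE),
    op("presence_matrix.tsv")))

  # 5. quantification
  stages_run <- c(stages_run, "quantify")
  quant_z <- stage("quantify", zero_fill(quant))
  prot_mat <- stage("quantify", suppressWarnings(
    rollup_to_protein(quant_z, attrib)))
  summary_tab <- stage("quantify", group_summarize(prot_mat, design))
  log_mat <- stage("quantify", censored_impute_log2(
    prot_mat, policy = config$impute_policy, seed = config$seed))
  outputs <- c(outputs,
               .write_tsv(data.frame(protein = rownames(prot_mat), prot_mat,
                                     check.names = FALSE),
                          op("protein_matrix.tsv")),
               .write_tsv(summary_tab, op("group_summary.tsv")))

  # 6. statistics
  stages_run <- c(stages_run, "stats")
  nonzero <- rowSums(prot_mat) > 0
  stats_out <- NULL
  if (sum(nonzero) >= 3) {
    profiles <- stage("stats", group_mean_matrix(
      prot_mat[nonzero, , drop = FALSE], design,
      group_order = unique(design$group)))
    fcm_fit <- stage("stats", fuzzy_cluster(
      profiles, n_clusters = config$n_clusters, seed = config$seed,
      threshold = config$membership_threshold))
    tests <- lapply(c("anova_bonferroni", "anova_fisher_lsd",
                      "kruskal_ranks", "two_way_anova_bonferroni"),
                    function(tg) stage("stats", run_group_tests(
                      prot_mat[nonzero, , drop = FALSE], design, test = tg,
                      alpha = config$alpha)))
    tests <- do.call(rbind, tests)
    categories <- stage("stats", classify_dementia_category(
      tests[tests$test == "anova_bonferroni", ], profiles,
      presence = presence, control_group = unique(design$group)[1],
      alpha = config$alpha))
    symbols <- stats::setNames(attrib$proteins$gene_symbol,
                               attrib$proteins$accession)
    isoforms <- stage("stats", split_isoforms(
      fcm_fit, symbols, profiles[, 1]))
    stats_out <- list(fcm = fcm_fit, tests = tests,
                      categories = categories, isoforms = isoforms)
    outputs <- c(outputs,
                 .write_tsv(fcm_fit$assignments, op("clusters.tsv")),
                 .write_tsv(tests, op("tests.tsv")),
                 .write_tsv(categories, op("categories.tsv")),
                 .write_tsv(isoforms, op("isoforms.tsv")))
  }

  # 7. correlations
  stages_run <- c(stages_run, "correlate")
  pep_mat <- stage("correlate", {
    z <- quant_z
    m <- matrix(0, nrow = length(unique(z$peptide)),
                ncol = length(unique(z$sample_id)),
                dimnames = list(sort(unique(z$peptide)),
                                sort(unique(z$sample_id))))
    m[cbind(z$peptide, z$sample_id)] <- z$count
    m
  })
  retained_peps <- intersect(rownames(pep_mat), attrib$peptides$peptide)
  # cap the all-pairs screen at the 40 most variable peptides; the full
  # peptidome screen is available by calling peptide_heatmap_table directly
  if (length(retained_peps) > 40) {
    v <- apply(pep_mat[retained_peps, , drop = FALSE], 1, stats::var)
    retained_peps <- retained_peps[order(-v, retained_peps)][1:40]
  }
  corr_out <- NULL
  if (length(retained_peps) >= 2) {
    groups12 <- unique(design$group)[1:2]
    heat <- stage("correlate", peptide_heatmap_table(
      pep_mat[retained_peps, , drop = FALSE],
      pep_mat[retained_peps, , drop = FALSE],
      design, groups12, r_filter = config$r_filter))
    corr_out <- heat
    outputs <- c(outputs,
                 .write_tsv(heat$table, op("correlations.tsv")),
                 .write_tsv(heat$reversals, op("reversals.tsv")))
  }

  # manifest: checksums of inputs and outputs, relative names only
  manifest <- list(
    stages = stages_run,
    seed = config$seed,
    config = unclass(config)[setdiff(names(config),
                                     c("input_dir", "outdir"))],
    inputs = stats::setNames(
      as.vector(tools::md5sum(ip(inputs))), inputs),
    outputs = stats::setNames(
      as.vector(tools::md5sum(outputs)), basename(outputs)))
  jsonlite::write_json(manifest, op("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(index = index, filter = filt, attribution = attrib,
                 protein_matrix = prot_mat, group_summary = summary_tab,
                 log_matrix = log_mat, stats = stats_out,
                 correlations = corr_out, presence = presence,
                 manifest = manifest,
                 manifest_path = op("manifest.json")))
}
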