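# Synthetic-data generator with planted ground truth.
#
# Proteins are assembled as concatenations of tryptic "blocks": random
# peptides of 7-22 residues ending in K or R, with no internal K/R and no
# leading proline, so that a zero-missed-cleavage digest recovers the
# blocks exactly. Planting is then block placement: copy a microbial block
# verbatim into a host protein (host homolog), copy it with at least one
# I<->L swap (I/L homolog), or place it in two proteins of different taxa
# (shared peptide). After assembly the provenance of every block is
# re-verified against the realized databases by canonical substring scan,
# so the truth map is exact even if a random block collides with host text.

PROVENANCE_LEVELS <- c("microbial_only", "host_homologous",
                       "host_il_homologous", "shared_multiprotein")
TREND_LEVELS <- c("flat", "up_with_stage", "down_with_stage", "early_peak",
                  "vad_only", "absent_in_vad")

DEFAULT_GROUPS <- c("control", "AD3", "AD4", "AD5", "AD6", "VaD")

#' Study design table
#'
#' Default design mirrors the discovery cohort: six groups (age-matched
#' controls, four AD Braak stages, vascular dementia), three subjects per
#' condition, each analyzed in technical triplicate.
#'
#' @param groups group labels; the first is treated as control and a group
#'   named `"VaD"` as the off-axis vascular-dementia contrast.
#' @param n_subjects subjects per group.
#' @param n_replicates technical replicates per subject.
#' @param fraction sample fraction label (`"bEV"`, `"WB"`, `"pEV"`).
#' @return data.frame: `sample_id`, `subject_id`, `group`, `fraction`,
#'   `replicate`.
#' @export
make_study_design <- function(groups = DEFAULT_GROUPS, n_subjects = 3,
                              n_replicates = 3, fraction = "bEV") {
  out <- expand.grid(replicate = seq_len(n_replicates),
                     subject = seq_len(n_subjects),
                     group = groups, stringsAsFactors = FALSE)
  out <- out[order(match(out$group, groups), out$subject, out$replicate), ]
  data.frame(
    sample_id = sprintf("%s_s%d_r%d_%s", out$group, out$subject,
                        out$replicate, fraction),
    subject_id = sprintf("%s_s%d_%s", out$group, out$subject, fraction),
    group = out$group,
    fraction = fraction,
    replicate = out$replicate,
    stringsAsFactors = FALSE, row.names = NULL)
}

# residues for block interiors: canonical minus K/R (cleavage) and minus P
# at the first position (would suppress the upstream cleavage site)
.interior_aa <- setdiff(.canonical_aa, c("K", "R"))
.start_aa <- setdiff(.interior_aa, "P")

.random_block <- function(len) {
  paste0(paste(c(sample(.start_aa, 1),
                 sample(.interior_aa, len - 2, replace = TRUE)),
               collapse = ""),
         sample(c("K", "R"), 1))
}

# n distinct blocks, distinct also under I->L canonicalization
.block_pool <- function(n, len_range = c(7L, 18L)) {
  blocks <- character(0)
  seen <- character(0)
  while (length(blocks) < n) {
    need <- n - length(blocks)
    fresh <- vapply(sample(seq(len_range[1], len_range[2]), need,
                           replace = TRUE),
                    .random_block, character(1))
    canon <- canonicalize_il(fresh)
    keep <- !duplicated(canon) & !(canon %in% seen)
    blocks <- c(blocks, fresh[keep])
    seen <- c(seen, canon[keep])
  }
  blocks
}

# swap at least one I/L residue; NA if the block has none
.il_swap <- function(block) {
  chars <- strsplit(block, "")[[1]]
  pos <- which(chars %in% c("I", "L"))
  if (length(pos) == 0) return(NA_character_)
  flip <- pos[stats::runif(length(pos)) < 0.5]
  if (length(flip) == 0) flip <- sample(pos, 1)
  chars[flip] <- ifelse(chars[flip] == "I", "L", "I")
  paste(chars, collapse = "")
}

#' Generate microbial and host protein databases with planted homology
#'
#' Builds `n_taxa * proteins_per_taxon` microbial proteins and `host_size`
#' host proteins from tryptic blocks. A fraction of microbial blocks is
#' planted into host proteins verbatim (`host_homolog_frac`), another with
#' one or more I/L swaps (`il_homolog_frac`), and a fraction is shared
#' between two proteins of different taxa (`shared_frac`). Gene symbols
#' recycle across taxa so the same symbol maps to several proteins, as for
#' widely conserved bacterial genes.
#'
#' @param n_taxa,proteins_per_taxon,host_size database dimensions.
#' @param peptides_per_protein tryptic blocks per protein.
#' @param host_homolog_frac,il_homolog_frac,shared_frac planting fractions
#'   of the microbial block pool.
#' @param trend_levels trends sampled for the non-flat half of the
#'   proteins (default: all non-flat trends; designs without a VaD group
#'   must exclude the VaD-referencing trends).
#' @param seed RNG seed; fixed seed gives byte-identical databases.
#' @return list with `microbial` and `host` (`ProteinDatabase`),
#'   `provenance` (data.frame: `peptide`, `provenance`), and
#'   `protein_trends` (named character vector, trend per microbial
#'   accession, assigned uniformly over the non-flat trends for half the
#'   proteins).
#' @export
make_databases <- function(n_taxa = 8, proteins_per_taxon = 6,
                           host_size = 40, peptides_per_protein = 12,
                           host_homolog_frac = 0.04,
                           il_homolog_frac = 0.04, shared_frac = 0.04,
                           trend_levels = setdiff(TREND_LEVELS, "flat"),
                           seed = 1L) {
  stopifnot(n_taxa >= 1, proteins_per_taxon >= 1, host_size >= 1,
            peptides_per_protein >= 2)
  set.seed(seed)
  n_prot <- n_taxa * proteins_per_taxon
  n_blocks <- n_prot * peptides_per_protein
  host_blocks_per_protein <- max(4L, peptides_per_protein %/% 2L)
  pool <- .block_pool(n_blocks + host_size * host_blocks_per_protein)
  microbial_blocks <- pool[seq_len(n_blocks)]
  host_own_blocks <- pool[-seq_len(n_blocks)]

  block_matrix <- matrix(microbial_blocks, nrow = n_prot, byrow = TRUE)
  taxa <- sprintf("Tax%02d", seq_len(n_taxa))
  accessions <- sprintf("MP%04d", seq_len(n_prot))
  prot_taxon <- rep(taxa, each = proteins_per_taxon)
  gene_symbols <- sprintf("gene%d", rep(seq_len(proteins_per_taxon),
                                        times = n_taxa))

  # shared peptides: overwrite a block of a protein in another taxon with a
  # block from this one
  n_shared <- round(shared_frac * n_blocks)
  if (n_shared > 0 && n_taxa >= 2) {
    donors <- sample(n_prot, n_shared, replace = TRUE)
    for (d in donors) {
      receivers <- which(prot_taxon != prot_taxon[d])
      rcv <- sample(receivers, 1)
      block_matrix[rcv, sample(peptides_per_protein, 1)] <-
        block_matrix[d, sample(peptides_per_protein, 1)]
    }
  }

  realized_blocks <- unique(as.vector(block_matrix))
  n_hh <- round(host_homolog_frac * length(realized_blocks))
  n_il <- round(il_homolog_frac * length(realized_blocks))
  if (n_hh + n_il > length(realized_blocks)) {
    stop("planting fractions exceed the available block pool")
  }
  planted <- sample(realized_blocks, n_hh + n_il)
  verbatim_plants <- planted[seq_len(n_hh)]
  il_sources <- planted[-seq_len(n_hh)]
  il_plants <- vapply(il_sources, .il_swap, character(1))
  il_plants <- il_plants[!is.na(il_plants)]

  host_inserts <- c(verbatim_plants, il_plants)
  total_host_blocks <- host_size * host_blocks_per_protein
  if (length(host_inserts) > total_host_blocks) {
    stop("host too small for the requested planted fragments")
  }
  host_block_matrix <- matrix(host_own_blocks[seq_len(total_host_blocks)],
                              nrow = host_size, byrow = TRUE)
  if (length(host_inserts) > 0) {
    slots <- sample(total_host_blocks, length(host_inserts))
    host_block_matrix[slots] <- host_inserts
  }

  microbial <- protein_database(data.frame(
    accession = accessions,
    sequence = apply(block_matrix, 1, paste, collapse = ""),
    taxon_id = prot_taxon,
    gene_symbol = gene_symbols,
    description = sprintf("synthetic protein %s of %s", gene_symbols,
                          prot_taxon),
    stringsAsFactors = FALSE), kind = "microbial")
  host <- protein_database(data.frame(
    accession = sprintf("HP%04d", seq_len(host_size)),
    sequence = apply(host_block_matrix, 1, paste, collapse = ""),
    taxon_id = HOST_TAXON,
    gene_symbol = "",
    description = "synthetic host protein",
    stringsAsFactors = FALSE), kind = "host")

  # verify provenance against the realized databases: exact truth even if a
  # random block happens to collide with host text
  host_text <- paste(host$records$sequence, collapse = "1")
  host_canon <- canonicalize_il(host_text)
  parent_count <- vapply(realized_blocks, function(b)
    sum(rowSums(block_matrix == b) > 0), 0L)
  prov <- vapply(realized_blocks, function(b) {
    if (grepl(b, host_text, fixed = TRUE)) return("host_homologous")
    if (grepl(canonicalize_il(b), host_canon, fixed = TRUE)) {
      return("host_il_homologous")
    }
    if (parent_count[[b]] > 1) return("shared_multiprotein")
    "microbial_only"
  }, character(1))

  trends <- rep("flat", n_prot)
  non_flat <- sample(n_prot, max(1L, n_prot %/% 2L))
  trends[non_flat] <- sample(trend_levels, length(non_flat),
                             replace = TRUE)
  names(trends) <- accessions

  list(microbial = microbial, host = host,
       provenance = data.frame(peptide = realized_blocks,
                               provenance = unname(prov),
                               stringsAsFactors = FALSE, row.names = NULL),
       protein_trends = trends)
}

#' Generate a taxon annotation table
#'
#' Habitat, pathogenicity and Gram status sampled per taxon with
#' oral-microbiome-heavy defaults.
#'
#' @param taxa character vector of taxon ids.
#' @param seed RNG seed.
#' @return annotation data.frame (see [read_taxon_annotations()]).
#' @export
make_annotations <- function(taxa, seed = 1L) {
  set.seed(seed)
  data.frame(
    taxon_id = taxa,
    habitat = sample(c("oral", "gut", "other"), length(taxa),
                     replace = TRUE, prob = c(0.7, 0.15, 0.15)),
    pathogenicity = sample(c("disease_associated", "opportunistic",
                             "health_associated"), length(taxa),
                           replace = TRUE, prob = c(0.35, 0.35, 0.3)),
    gram = sample(c("negative", "positive"), length(taxa), replace = TRUE,
                  prob = c(0.6, 0.4)),
    stringsAsFactors = FALSE)
}

# per-group mean for a planted trend; stage axis is ordinal
# (control = 0 ... final stage), VaD is an off-axis categorical contrast
.trend_mean <- function(trend, group, groups, base_mean, effect_size,
                        vad_group = "VaD") {
  stages <- setdiff(groups, vad_group)
  s <- match(group, stages) - 1L
  is_vad <- !is.na(match(group, vad_group))
  switch(trend,
    flat = base_mean,
    up_with_stage = if (is_vad) base_mean else base_mean * effect_size^s,
    down_with_stage = if (is_vad) base_mean else base_mean * effect_size^-s,
    early_peak = {
      if (is_vad || s == 0) base_mean
      else if (s == 1) base_mean * effect_size^2
      else if (s == 2) base_mean * effect_size
      else base_mean
    },
    vad_only = if (is_vad) base_mean * effect_size else 0,
    absent_in_vad = if (is_vad) 0 else base_mean,
    stop("unknown trend: ", trend))
}

#' Generate a peptide quantification table from planted truth
#'
#' Spectral counts are drawn from a negative binomial around protein-level
#' group means that follow each protein's planted trend (`up_with_stage`
#' multiplies the mean by `effect_size` per stage step from control to the
#' final stage). Dropout is missing-at-low-abundance: the probability of a
#' "not detected" cell decreases with the peptide's expected count.
#' Planted correlation pairs are realized through a shared latent
#' log-normal factor per group (with a sign flip where requested) and are
#' exempt from dropout so the target correlation is realized as stated.
#'
#' @param dbs output of [make_databases()].
#' @param design study design.
#' @param effect_size per-stage fold change of planted trends (> 0).
#' @param dropout_rate overall dropout scale in `[0, 1)`.
#' @param base_mean baseline protein-level spectral count.
#' @param dispersion negative-binomial dispersion (0 = Poisson option).
#' @param correlation_pairs optional data.frame
#'   (`peptide_a`, `peptide_b`, `group`, `r`) of pairs to plant.
#' @param seed RNG seed.
#' @return list with `quant` (long table: `peptide`, `sample_id`, `count`,
#'   NA = not detected) and `truth` (a `SyntheticTruth`: provenance map,
#'   protein trends, realized correlation pairs, seed).
#' @export
make_quant_tables <- function(dbs, design, effect_size = 2,
                              dropout_rate = 0.1, base_mean = 30,
                              dispersion = 0.3, correlation_pairs = NULL,
                              seed = 1L) {
  stopifnot(effect_size > 0, dropout_rate >= 0, dropout_rate < 1)
  set.seed(seed)
  groups <- unique(design$group)
  vad_group <- if ("VaD" %in% groups) "VaD" else character(0)
  bad_trend <- setdiff(unique(dbs$protein_trends), TREND_LEVELS)
  if (length(bad_trend) > 0) stop("unknown trend(s): ",
                                  paste(bad_trend, collapse = ", "))
  if (length(vad_group) == 0 &&
      any(dbs$protein_trends %in% c("vad_only", "absent_in_vad"))) {
    stop("design has no VaD group but trends reference it")
  }

  rec <- dbs$microbial$records
  # peptide-level means: protein group mean spread over blocks with a fixed
  # per-peptide ionization-like weight
  idx0 <- build_peptide_index(dbs$microbial, max_missed = 0)
  pep_tab <- unique(idx0[, c("peptide", "accession")])
  pep_tab <- pep_tab[order(pep_tab$peptide, pep_tab$accession), ]
  # a shared peptide draws its counts from its first parent's trend
  pep_tab <- pep_tab[!duplicated(pep_tab$peptide), ]
  n_pep <- nrow(pep_tab)
  pep_weight <- stats::rlnorm(n_pep, 0, 0.4)
  names(pep_weight) <- pep_tab$peptide

  samples <- design$sample_id
  group_of <- design$group
  mu_group <- matrix(NA_real_, nrow = n_pep, ncol = length(groups),
                     dimnames = list(pep_tab$peptide, groups))
  for (g in groups) {
    mu_group[, g] <- vapply(seq_len(n_pep), function(i) {
      trend <- dbs$protein_trends[[pep_tab$accession[i]]]
      .trend_mean(trend, g, groups, base_mean, effect_size) *
        pep_weight[i]
    }, 0)
  }

  size <- if (dispersion > 0) 1 / dispersion else Inf
  draw <- function(mu) {
    if (is.infinite(size)) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = size)
  }
  counts <- matrix(0L, nrow = n_pep, ncol = length(samples),
                   dimnames = list(pep_tab$peptide, samples))
  for (j in seq_along(samples)) {
    counts[, j] <- draw(mu_group[, group_of[j]])
  }

  corr_peptides <- character(0)
  realized_pairs <- NULL
  if (!is.null(correlation_pairs) && nrow(correlation_pairs) > 0) {
    sigma <- 0.3
    for (i in seq_len(nrow(correlation_pairs))) {
      pa <- correlation_pairs$peptide_a[i]
      pb <- correlation_pairs$peptide_b[i]
      g <- correlation_pairs$group[i]
      rho <- correlation_pairs$r[i]
      if (!all(c(pa, pb) %in% pep_tab$peptide)) {
        stop("correlation pair references unknown peptide(s)")
      }
      if (!g %in% groups) stop("correlation pair references unknown group: ", g)
      cols <- which(group_of == g)
      z <- stats::rnorm(length(cols))
      e <- stats::rnorm(length(cols))
      w <- rho * z + sqrt(1 - rho^2) * e
      counts[pa, cols] <- round(mu_group[pa, g] * exp(sigma * z))
      counts[pb, cols] <- round(mu_group[pb, g] * exp(sigma * w))
      corr_peptides <- c(corr_peptides, pa, pb)
    }
    realized_pairs <- correlation_pairs
  }

  if (dropout_rate > 0) {
    mu_ref <- stats::median(mu_group[mu_group > 0])
    for (j in seq_along(samples)) {
      mu <- mu_group[, group_of[j]]
      p_miss <- pmin(0.95, 2 * dropout_rate * mu_ref / (mu_ref + mu))
      p_miss[pep_tab$peptide %in% corr_peptides] <- 0
      miss <- stats::runif(n_pep) < p_miss
      counts[miss, j] <- NA
    }
  }

  quant <- data.frame(
    peptide = rep(pep_tab$peptide, times = length(samples)),
    sample_id = rep(samples, each = n_pep),
    count = as.integer(round(as.vector(counts))),
    stringsAsFactors = FALSE)

  truth <- structure(list(
    provenance = dbs$provenance,
    protein_trends = dbs$protein_trends,
    correlation_pairs = realized_pairs,
    seed = seed,
    groups = groups,
    base_mean = base_mean,
    effect_size = effect_size,
    dropout_rate = dropout_rate,
    dispersion = dispersion), class = "SyntheticTruth")
  list(quant = quant, truth = truth)
}

#' Generate a complete synthetic bundle
#'
#' Orchestrates [make_databases()], [make_study_design()],
#' [make_annotations()] and [make_quant_tables()], optionally planting
#' correlation pairs between microbial-only peptides (including sign-flip
#' pairs across the first two groups to emulate reversed correlations).
#'
#' @inheritParams make_databases
#' @inheritParams make_quant_tables
#' @param groups,n_subjects,n_replicates design parameters.
#' @param n_correlation_pairs pairs planted at `correlation_r` in the first
#'   group.
#' @param n_flip_pairs pairs planted at `+flip_r` in the first group and
#'   `-flip_r` in the second.
#' @param correlation_r,flip_r target Pearson coefficients.
#' @param seed master seed; sub-stages derive their own seeds from it.
#' @return list of class `SyntheticBundle`: `microbial`, `host`,
#'   `annotations`, `design`, `quant`, `truth`.
#' @export
synthesize_bundle <- function(n_taxa = 8, proteins_per_taxon = 6,
                              host_size = 40, peptides_per_protein = 12,
                              groups = DEFAULT_GROUPS, n_subjects = 3,
                              n_replicates = 3, effect_size = 2,
                              dropout_rate = 0.1, base_mean = 30,
                              dispersion = 0.3, n_correlation_pairs = 2,
                              n_flip_pairs = 1, correlation_r = 0.9,
                              flip_r = 0.8, seed = 1L) {
  seed <- as.integer(seed) %% 1000003L
  trend_levels <- setdiff(TREND_LEVELS, "flat")
  if (!"VaD" %in% groups) {
    trend_levels <- setdiff(trend_levels, c("vad_only", "absent_in_vad"))
  }
  dbs <- make_databases(n_taxa = n_taxa,
                        proteins_per_taxon = proteins_per_taxon,
                        host_size = host_size,
                        peptides_per_protein = peptides_per_protein,
                        trend_levels = trend_levels,
                        seed = seed)
  design <- make_study_design(groups, n_subjects, n_replicates)
  annotations <- make_annotations(unique(dbs$microbial$records$taxon_id),
                                  seed = seed + 1L)
  pairs <- NULL
  n_pairs <- n_correlation_pairs + n_flip_pairs
  if (n_pairs > 0) {
    set.seed(seed + 2L)
    mo <- dbs$provenance$peptide[dbs$provenance$provenance ==
                                   "microbial_only"]
    if (length(mo) < 2 * n_pairs) stop("too few microbial-only peptides to plant pairs")
    picks <- matrix(sample(mo, 2 * n_pairs), ncol = 2)
    pairs <- data.frame(peptide_a = character(0), peptide_b = character(0),
                        group = character(0), r = numeric(0))
    if (n_correlation_pairs > 0) {
      pairs <- rbind(pairs, data.frame(
        peptide_a = picks[seq_len(n_correlation_pairs), 1],
        peptide_b = picks[seq_len(n_correlation_pairs), 2],
        group = groups[1], r = correlation_r, stringsAsFactors = FALSE))
    }
    if (n_flip_pairs > 0) {
      fp <- picks[n_correlation_pairs + seq_len(n_flip_pairs), ,
                  drop = FALSE]
      pairs <- rbind(pairs,
                     data.frame(peptide_a = fp[, 1], peptide_b = fp[, 2],
                                group = groups[1], r = flip_r,
                                stringsAsFactors = FALSE),
                     data.frame(peptide_a = fp[, 1], peptide_b = fp[, 2],
                                group = groups[2], r = -flip_r,
                                stringsAsFactors = FALSE))
    }
  }
  qt <- make_quant_tables(dbs, design, effect_size = effect_size,
                          dropout_rate = dropout_rate,
                          base_mean = base_mean, dispersion = dispersion,
                          correlation_pairs = pairs, seed = seed + 3L)
  structure(list(microbial = dbs$microbial, host = dbs$host,
                 annotations = annotations, design = design,
                 quant = qt$quant, truth = qt$truth),
            class = "SyntheticBundle")
}

#' Write a synthetic bundle to disk
#'
#' Writes `microbial.fasta`, `host.fasta`, `annotations.tsv`,
#' `peptides.tsv` (missing counts as empty cells), `design.tsv` and
#' `truth.json`.
#'
#' @param bundle a `SyntheticBundle`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_bundle <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "SyntheticBundle"))
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", outdir)
  }
  p <- function(f) file.path(outdir, f)
  write_fasta(bundle$microbial, p("microbial.fasta"))
  write_fasta(bundle$host, p("host.fasta"))
  write_taxon_annotations(bundle$annotations, p("annotations.tsv"))
  utils::write.table(bundle$quant, p("peptides.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(bundle$design, p("design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- bundle$truth
  jsonlite::write_json(
    list(provenance = truth$provenance,
         protein_trends = as.list(truth$protein_trends),
         correlation_pairs = truth$correlation_pairs,
         seed = truth$seed, groups = truth$groups,
         base_mean = truth$base_mean, effect_size = truth$effect_size,
         dropout_rate = truth$dropout_rate,
         dispersion = truth$dispersion),
    p("truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Read a synthetic bundle back from disk
#'
#' @param dir directory written by [write_bundle()].
#' @return a `SyntheticBundle`.
#' @export
read_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  microbial <- read_fasta(p("microbial.fasta"), kind = "microbial")
  host <- read_fasta(p("host.fasta"), kind = "host")
  annotations <- read_taxon_annotations(p("annotations.tsv"))
  quant <- utils::read.delim(p("peptides.tsv"), stringsAsFactors = FALSE,
                             na.strings = "")
  design <- utils::read.delim(p("design.tsv"), stringsAsFactors = FALSE)
  tj <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  truth <- structure(list(
    provenance = as.data.frame(tj$provenance),
    protein_trends = unlist(tj$protein_trends),
    correlation_pairs = if (!is.null(tj$correlation_pairs))
      as.data.frame(tj$correlation_pairs) else NULL,
    seed = tj$seed, groups = tj$groups, base_mean = tj$base_mean,
    effect_size = tj$effect_size, dropout_rate = tj$dropout_rate,
    dispersion = tj$dispersion), class = "SyntheticTruth")
  structure(list(microbial = microbial, host = host,
                 annotations = annotations, design = design, quant = quant,
                 truth = truth), class = "SyntheticBundle")
}
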