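# Taxonomic attribution of retained peptides.
#
# A peptide is unique to a protein iff it has exactly one parent protein in
# the database, and unique to a taxon iff all its parent proteins share one
# taxon. Protein-level uniqueness feeds quantification; taxon-level
# uniqueness feeds organism presence calls.

#' Attribute peptides to proteins and taxa
#'
#' Resolves each peptide in the peptide index, computes protein- and
#' taxon-level uniqueness flags, and joins taxon annotations. Peptides
#' absent from the index are reported as orphans, never silently dropped.
#'
#' @param peptides character vector of retained peptide sequences.
#' @param index a `PeptideIndex` built over the search database.
#' @param annotations optional taxon annotation data.frame
#'   (see [read_taxon_annotations()]).
#' @return an `AttributionTable`: list with `peptides` (per-peptide flags
#'   and parent sets), `proteins` (per-protein supporting peptides),
#'   `taxa` (per-taxon summary with annotations), `orphans`.
#' @export
attribute_peptides <- function(peptides, index, annotations = NULL) {
  peptides <- unique(toupper(peptides))
  parents <- index_parents(index)
  pos <- match(peptides, parents$peptide)
  orphans <- peptides[is.na(pos)]
  resolved <- peptides[!is.na(pos)]
  p <- parents[pos[!is.na(pos)], , drop = FALSE]
  pep_tab <- data.frame(
    peptide = resolved,
    n_proteins = p$n_proteins,
    n_taxa = p$n_taxa,
    proteins = p$proteins,
    taxa = p$taxa,
    unique_to_protein = p$n_proteins == 1L,
    unique_to_taxon = p$n_taxa == 1L,
    stringsAsFactors = FALSE)
  rownames(pep_tab) <- NULL

  sub_idx <- index[index$peptide %in% resolved, , drop = FALSE]
  prot_tab <- if (nrow(sub_idx) > 0) {
    sp <- split(sub_idx, sub_idx$accession)
    out <- lapply(names(sp), function(acc) {
      rows <- sp[[acc]]
      peps <- unique(rows$peptide)
      uniq <- pep_tab$peptide[pep_tab$unique_to_protein]
      data.frame(accession = acc,
                 taxon_id = rows$taxon_id[1],
                 gene_symbol = rows$gene_symbol[1],
                 n_peptides = length(peps),
                 n_unique_peptides = sum(peps %in% uniq),
                 peptides = paste(sort(peps), collapse = ";"),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  } else {
    data.frame(accession = character(0), taxon_id = character(0),
               gene_symbol = character(0), n_peptides = integer(0),
               n_unique_peptides = integer(0), peptides = character(0))
  }
  rownames(prot_tab) <- NULL

  taxa <- sort(unique(prot_tab$taxon_id))
  uniq_tax_pep <- pep_tab[pep_tab$unique_to_taxon, , drop = FALSE]
  taxa_tab <- data.frame(
    taxon_id = taxa,
    n_proteins = vapply(taxa, function(t)
      sum(prot_tab$taxon_id == t), 0L),
    n_unique_taxon_peptides = vapply(taxa, function(t)
      sum(uniq_tax_pep$taxa == t), 0L),
    stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    m <- match(taxa_tab$taxon_id, annotations$taxon_id)
    taxa_tab$habitat <- ifelse(is.na(m), "unannotated",
                               annotations$habitat[m])
    taxa_tab$pathogenicity <- ifelse(is.na(m), "unannotated",
                                     annotations$pathogenicity[m])
    taxa_tab$gram <- ifelse(is.na(m), "unannotated", annotations$gram[m])
  }
  rownames(taxa_tab) <- NULL

  structure(list(peptides = pep_tab, proteins = prot_tab, taxa = taxa_tab,
                 orphans = orphans),
            class = "AttributionTable")
}

#' @export
print.AttributionTable <- function(x, ...) {
  cat(sprintf(paste0("AttributionTable: %d peptides (%d unique to protein, ",
                     "%d unique to taxon), %d proteins, %d taxa, %d orphans\n"),
              nrow(x$peptides), sum(x$peptides$unique_to_protein),
              sum(x$peptides$unique_to_taxon), nrow(x$proteins),
              nrow(x$taxa), length(x$orphans)))
  invisible(x)
}

# samples (columns of quant) detected per subject: a subject detects a
# feature if any of its replicates has a positive count
.detected_by_subject <- function(counts, design) {
  # counts: named numeric per sample; returns subjects with detection
  pos <- names(counts)[!is.na(counts) & counts > 0]
  unique(design$subject_id[design$sample_id %in% pos])
}

#' Commonly detected proteins and taxa across all subjects
#'
#' A protein (taxon) is "common" iff it is detected -- at least one
#' supporting unique peptide with a positive spectral count, pooling a
#' subject's technical replicates -- in every subject of the design.
#' Returns counts and fractions plus Gram / habitat / pathogenicity
#' breakdowns of the common taxa.
#'
#' @param attrib an `AttributionTable`.
#' @param quant long quantification table (`peptide`, `sample_id`, `count`).
#' @param design study design data.frame.
#' @return list with `proteins`, `taxa` (per-feature detection tables with a
#'   `common` flag) and `summary` (counts, fractions, breakdown tables).
#' @export
common_sets <- function(attrib, quant, design) {
  stopifnot(inherits(attrib, "AttributionTable"))
  extra <- setdiff(unique(quant$sample_id), design$sample_id)
  if (length(extra) > 0) {
    stop("quant contains samples absent from design: ",
         paste(utils::head(extra, 5), collapse = ", "))
  }
  subjects <- unique(design$subject_id)
  det <- quant[!is.na(quant$count) & quant$count > 0, , drop = FALSE]
  det$subject_id <- design$subject_id[match(det$sample_id, design$sample_id)]

  feature_common <- function(peps) {
    subj <- unique(det$subject_id[det$peptide %in% peps])
    c(n = length(subj), common = length(subj) == length(subjects))
  }

  uniq_prot_pep <- attrib$peptides[attrib$peptides$unique_to_protein, ,
                                   drop = FALSE]
  prot <- attrib$proteins
  prot_stats <- t(vapply(prot$accession, function(acc) {
    peps <- uniq_prot_pep$peptide[uniq_prot_pep$proteins == acc]
    feature_common(peps)
  }, c(n = 0, common = 0)))
  prot$n_subjects_detected <- as.integer(prot_stats[, "n"])
  prot$common <- prot_stats[, "common"] == 1

  uniq_tax_pep <- attrib$peptides[attrib$peptides$unique_to_taxon, ,
                                  drop = FALSE]
  taxa <- attrib$taxa
  tax_stats <- t(vapply(taxa$taxon_id, function(tx) {
    peps <- uniq_tax_pep$peptide[uniq_tax_pep$taxa == tx]
    feature_common(peps)
  }, c(n = 0, common = 0)))
  taxa$n_subjects_detected <- as.integer(tax_stats[, "n"])
  taxa$common <- tax_stats[, "common"] == 1

  breakdown <- function(col) {
    if (!col %in% names(taxa)) return(NULL)
    table(taxa[[col]][taxa$common])
  }
  list(proteins = prot, taxa = taxa,
       summary = list(
         n_proteins = nrow(prot),
         n_common_proteins = sum(prot$common),
         frac_common_proteins = if (nrow(prot) > 0)
           sum(prot$common) / nrow(prot) else NA_real_,
         n_taxa = nrow(taxa),
         n_common_taxa = sum(taxa$common),
         frac_common_taxa = if (nrow(taxa) > 0)
           sum(taxa$common) / nrow(taxa) else NA_real_,
         gram = breakdown("gram"),
         habitat = breakdown("habitat"),
         pathogenicity = breakdown("pathogenicity")))
}

#' Presence matrix of taxa (or proteins) by condition
#'
#' A taxon is present in a condition iff at least one of its
#' taxon-unique peptides has a positive count in at least one sample of the
#' condition. With `level = "protein"`, protein-unique peptides are used
#' instead.
#'
#' @param attrib an `AttributionTable`.
#' @param quant long quantification table.
#' @param design study design.
#' @param level `"taxon"` (default) or `"protein"`.
#' @return logical matrix, rows features, columns conditions (groups).
#' @export
presence_by_condition <- function(attrib, quant, design,
                                  level = c("taxon", "protein")) {
  level <- match.arg(level)
  det <- quant[!is.na(quant$count) & quant$count > 0, , drop = FALSE]
  det$group <- design$group[match(det$sample_id, design$sample_id)]
  groups <- unique(design$group)
  if (level == "taxon") {
    peps <- attrib$peptides[attrib$peptides$unique_to_taxon, , drop = FALSE]
    features <- sort(unique(peps$taxa))
    key <- peps$taxa
  } else {
    peps <- attrib$peptides[attrib$peptides$unique_to_protein, ,
                            drop = FALSE]
    features <- sort(unique(peps$proteins))
    key <- peps$proteins
  }
  mat <- matrix(FALSE, nrow = length(features), ncol = length(groups),
                dimnames = list(features, groups))
  for (f in features) {
    fp <- peps$peptide[key == f]
    g <- unique(det$group[det$peptide %in% fp])
    mat[f, groups %in% g] <- TRUE
  }
  mat
}

#' Re-attribution consistency under database restriction
#'
#' Re-attributes peptides against a restricted database (typically
#' `restrict_database(full_db, identified taxa/proteins)`) and reports
#' every peptide whose parent set or uniqueness status changed. Restriction
#' can only shrink parent sets, so shared peptides may gain uniqueness but a
#' unique peptide can never become shared; violations are reported.
#'
#' @param peptides character vector of peptide sequences.
#' @param full_db,restricted_db `ProteinDatabase` objects.
#' @param max_missed,min_len,max_len digestion parameters.
#' @return list with `table` (per-peptide parent counts under both
#'   databases and a `status` column), `n_gained_uniqueness`, `violations`
#'   (rows where a parent set grew -- impossible under true restriction),
#'   `lost_all_parents` (peptides resolvable only in the full database).
#' @export
attribution_consistency_check <- function(peptides, full_db, restricted_db,
                                          max_missed = 2, min_len = 7,
                                          max_len = 22) {
  full_idx <- build_peptide_index(full_db, max_missed, min_len, max_len)
  rest_idx <- build_peptide_index(restricted_db, max_missed, min_len,
                                  max_len)
  pf <- index_parents(full_idx)
  pr <- index_parents(rest_idx)
  peptides <- unique(toupper(peptides))
  mf <- match(peptides, pf$peptide)
  mr <- match(peptides, pr$peptide)
  tab <- data.frame(
    peptide = peptides,
    n_parents_full = ifelse(is.na(mf), 0L, pf$n_proteins[mf]),
    n_parents_restricted = ifelse(is.na(mr), 0L, pr$n_proteins[mr]),
    stringsAsFactors = FALSE)
  tab$status <- with(tab, ifelse(
    n_parents_restricted > n_parents_full, "grew",
    ifelse(n_parents_full > 1 & n_parents_restricted == 1,
           "gained_uniqueness",
           ifelse(n_parents_full > 0 & n_parents_restricted == 0,
                  "lost_all_parents", "unchanged"))))
  list(table = tab,
       n_gained_uniqueness = sum(tab$status == "gained_uniqueness"),
       violations = tab[tab$status == "grew", , drop = FALSE],
       lost_all_parents = tab$peptide[tab$status == "lost_all_parents"])
}
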