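# In-silico tryptic digestion and peptide indexing.
#
# Trypsin cleaves C-terminal to K or R except when the next residue is
# proline. Peptides are emitted for 0..max_missed missed cleavages and then
# restricted to the analysis length window (default 7-22 residues, the
# window observed for identified microbiome-derived peptides).

#' Tryptic cleavage boundaries of a sequence
#'
#' @param sequence amino-acid string.
#' @return integer vector of fragment end positions (1-based, inclusive);
#'   the final element is `nchar(sequence)`.
#' @keywords internal
tryptic_boundaries <- function(sequence) {
  n <- nchar(sequence)
  m <- gregexpr("[KR](?!P)", sequence, perl = TRUE)[[1]]
  cuts <- if (m[1] == -1) integer(0) else as.integer(m)
  unique(c(cuts, n))
}

#' Digest one protein sequence with trypsin rules
#'
#' Cleaves after K or R unless followed by P, emitting all fragments with
#' 0 to `max_missed` missed cleavages. Fragments containing the ambiguity
#' placeholder `"X"` are dropped when `drop_ambiguous = TRUE` (default),
#' because such peptides cannot be compared under I/L-variant logic.
#'
#' @param sequence amino-acid string (sanitized).
#' @param max_missed maximum number of missed cleavages (default 2).
#' @param accession,taxon_id optional provenance carried into the output.
#' @param drop_ambiguous drop fragments containing `"X"`.
#' @return data.frame with columns `peptide`, `start` (0-based offset in the
#'   parent), `missed`, `length`, and `accession`/`taxon_id` when supplied.
#' @examples
#' digest_protein("MKRVLSEK", max_missed = 0)  # MK, R, VLSEK
#' @export
digest_protein <- function(sequence, max_missed = 2, accession = NA_character_,
                           taxon_id = NA_character_, drop_ambiguous = TRUE) {
  stopifnot(length(sequence) == 1, max_missed >= 0)
  ends <- tryptic_boundaries(sequence)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  k <- length(ends)
  out <- vector("list", max_missed + 1)
  for (mm in 0:max_missed) {
    if (k - mm < 1) break
    i <- seq_len(k - mm)
    frag_start <- starts[i]
    frag_end <- ends[i + mm]
    out[[mm + 1]] <- data.frame(
      peptide = substring(sequence, frag_start, frag_end),
      start = frag_start - 1L,
      missed = mm,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(peptide = character(0), start = integer(0),
                      missed = integer(0))
  }
  res$length <- nchar(res$peptide)
  if (drop_ambiguous && nrow(res) > 0) {
    res <- res[!grepl("X", res$peptide, fixed = TRUE), , drop = FALSE]
  }
  res$accession <- accession
  res$taxon_id <- taxon_id
  rownames(res) <- NULL
  res
}

#' Filter peptides to a length window
#'
#' @param peptides data.frame with a `length` column (as produced by
#'   [digest_protein()]) or a character vector of sequences.
#' @param min_len,max_len inclusive bounds (defaults 7 and 22).
#' @return same type as the input, restricted to the window.
#' @export
length_filter <- function(peptides, min_len = 7, max_len = 22) {
  stopifnot(min_len >= 1, min_len <= max_len)
  if (is.character(peptides)) {
    return(peptides[nchar(peptides) >= min_len & nchar(peptides) <= max_len])
  }
  peptides[peptides$length >= min_len & peptides$length <= max_len, ,
           drop = FALSE]
}

#' Build a peptide index over a protein database
#'
#' Digests every protein and merges equal peptide sequences from different
#' proteins into one entry with the full parent set. Isoleucine and leucine
#' are NOT merged here; I/L ambiguity is handled exclusively by the host
#' homology filter, keeping attribution literal to database sequences.
#'
#' @param db a `ProteinDatabase`.
#' @param max_missed maximum missed cleavages (default 2).
#' @param min_len,max_len peptide length window (defaults 7 and 22).
#' @return a `PeptideIndex`: a data.frame with one row per
#'   (peptide, parent, offset) occurrence and columns `peptide`,
#'   `accession`, `taxon_id`, `gene_symbol`, `start`, `missed`.
#' @export
build_peptide_index <- function(db, max_missed = 2, min_len = 7,
                                max_len = 22) {
  stopifnot(inherits(db, "ProteinDatabase"))
  r <- db$records
  if (nrow(r) == 0) stop("database is empty")
  per_protein <- lapply(seq_len(nrow(r)), function(i) {
    d <- digest_protein(r$sequence[i], max_missed = max_missed,
                        accession = r$accession[i], taxon_id = r$taxon_id[i])
    d <- length_filter(d, min_len, max_len)
    if (nrow(d) > 0) d$gene_symbol <- r$gene_symbol[i]
    d
  })
  idx <- do.call(rbind, per_protein[vapply(per_protein, nrow, 0L) > 0])
  if (is.null(idx)) {
    idx <- data.frame(peptide = character(0), start = integer(0),
                      missed = integer(0), length = integer(0),
                      accession = character(0), taxon_id = character(0),
                      gene_symbol = character(0))
  }
  idx <- idx[order(idx$peptide, idx$accession, idx$start), ]
  rownames(idx) <- NULL
  attr(idx, "params") <- list(max_missed = max_missed, min_len = min_len,
                              max_len = max_len)
  class(idx) <- c("PeptideIndex", "data.frame")
  idx
}

#' Look up the parents of a peptide in an index
#'
#' @param index a `PeptideIndex`.
#' @param peptide peptide sequence.
#' @return data.frame of index rows for that peptide (0 rows if absent).
#' @export
index_lookup <- function(index, peptide) {
  index[index$peptide == peptide, , drop = FALSE]
}

#' Per-peptide parent summary of an index
#'
#' @param index a `PeptideIndex`.
#' @return data.frame with one row per distinct peptide sequence:
#'   `peptide`, `n_proteins`, `n_taxa`, `proteins`, `taxa` (collapsed with
#'   `";"`).
#' @export
index_parents <- function(index) {
  if (nrow(index) == 0) {
    return(data.frame(peptide = character(0), n_proteins = integer(0),
                      n_taxa = integer(0), proteins = character(0),
                      taxa = character(0)))
  }
  sp <- split(seq_len(nrow(index)), index$peptide)
  res <- lapply(names(sp), function(p) {
    rows <- index[sp[[p]], ]
    acc <- sort(unique(rows$accession))
    tax <- sort(unique(rows$taxon_id))
    data.frame(peptide = p, n_proteins = length(acc), n_taxa = length(tax),
               proteins = paste(acc, collapse = ";"),
               taxa = paste(tax, collapse = ";"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
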