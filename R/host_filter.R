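# Host-homology exclusion of candidate microbial peptides.
#
# Mass spectrometry cannot distinguish isoleucine from leucine, so a
# candidate peptide is host-homologous if ANY of its 2^k I/L variants occurs
# in the host proteome. Instead of enumerating variants, both the peptide
# and the host text are canonicalized (I -> L) and a single substring search
# is performed; this is exactly equivalent to variant enumeration, which is
# retained in il_variants() as the test oracle.

#' Enumerate all isoleucine/leucine variants of a peptide
#'
#' Returns exactly `2^k` sequences where `k` is the number of I/L residues;
#' the input itself is included.
#'
#' @param peptide peptide sequence.
#' @return character vector of variants.
#' @examples
#' il_variants("LILAK")  # 8 variants
#' @export
il_variants <- function(peptide) {
  stopifnot(length(peptide) == 1)
  chars <- strsplit(peptide, "")[[1]]
  pos <- which(chars %in% c("I", "L"))
  if (length(pos) == 0) return(peptide)
  combos <- expand.grid(rep(list(c("I", "L")), length(pos)),
                        stringsAsFactors = FALSE)
  vapply(seq_len(nrow(combos)), function(i) {
    chars[pos] <- unlist(combos[i, ], use.names = FALSE)
    paste(chars, collapse = "")
  }, character(1))
}

#' Canonicalize I/L ambiguity
#'
#' Maps every isoleucine to leucine so that two sequences are equal iff they
#' are indistinguishable under I/L substitution.
#'
#' @param x character vector of sequences.
#' @return canonicalized sequences.
#' @export
canonicalize_il <- function(x) chartr("I", "L", x)

#' Remove peptides with host-homologous sequences
#'
#' A peptide is excluded iff any of its I/L variants occurs in the host
#' proteome: as a contiguous substring of any host protein in
#' `mode = "substring"` (default, the conservative reading of "present in
#' the host proteome"), or as an exact tryptic host peptide in
#' `mode = "tryptic"` (sensitivity-analysis mode). Peptides containing the
#' ambiguity placeholder `"X"` are excluded with reason
#' `"ambiguous residue"`. Order of retained peptides is preserved.
#'
#' @param peptides character vector of candidate peptide sequences.
#' @param host a host `ProteinDatabase`.
#' @param mode `"substring"` or `"tryptic"`.
#' @param max_missed,min_len,max_len digestion parameters for tryptic mode.
#' @return list with `retained` (character vector) and `report`
#'   (a `FilterReport`: counts plus a per-peptide decision table naming the
#'   matching host accession for every exclusion).
#' @export
filter_host_homologs <- function(peptides, host, mode = c("substring",
                                                          "tryptic"),
                                 max_missed = 2, min_len = 7, max_len = 22) {
  mode <- match.arg(mode)
  stopifnot(inherits(host, "ProteinDatabase"))
  if (nrow(host$records) == 0) stop("host database is empty; filter would be vacuous")
  peptides <- toupper(peptides)
  ambiguous <- grepl("X", peptides, fixed = TRUE)
  canon <- canonicalize_il(peptides)
  host_canon <- canonicalize_il(host$records$sequence)

  if (mode == "substring") {
    # single concatenated text for a fast first pass; sanitized sequences
    # are all letters, so a digit is a safe separator
    blob <- paste(host_canon, collapse = "1")
    hit <- vapply(canon, function(p) grepl(p, blob, fixed = TRUE),
                  logical(1), USE.NAMES = FALSE)
    match_acc <- rep(NA_character_, length(peptides))
    for (i in which(hit & !ambiguous)) {
      j <- which(grepl(canon[i], host_canon, fixed = TRUE))
      match_acc[i] <- paste(host$records$accession[j], collapse = ";")
    }
  } else {
    host_idx <- build_peptide_index(host, max_missed = max_missed,
                                    min_len = min_len, max_len = max_len)
    host_pep_canon <- canonicalize_il(host_idx$peptide)
    pos <- match(canon, host_pep_canon)
    hit <- !is.na(pos)
    match_acc <- rep(NA_character_, length(peptides))
    for (i in which(hit & !ambiguous)) {
      j <- which(host_pep_canon == canon[i])
      match_acc[i] <- paste(sort(unique(host_idx$accession[j])),
                            collapse = ";")
    }
  }

  excluded <- hit | ambiguous
  n_il <- nchar(gsub("[^IL]", "", peptides))
  decisions <- data.frame(
    peptide = peptides,
    n_variants = 2^n_il,
    excluded = excluded,
    reason = ifelse(ambiguous, "ambiguous residue",
                    ifelse(hit, "host homolog", "")),
    host_accession = ifelse(ambiguous, NA_character_, match_acc),
    stringsAsFactors = FALSE)
  report <- structure(
    list(input = length(peptides),
         retained = sum(!excluded),
         excluded = sum(excluded),
         mode = mode,
         decisions = decisions),
    class = "FilterReport")
  list(retained = peptides[!excluded], report = report)
}

#' @export
print.FilterReport <- function(x, ...) {
  cat(sprintf("FilterReport (%s mode): %d peptides in, %d retained, %d excluded\n",
              x$mode, x$input, x$retained, x$excluded))
  invisible(x)
}

#' Export a filter report as TSV
#' @param report a `FilterReport`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  stopifnot(inherits(report, "FilterReport"))
  utils::write.table(report$decisions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
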