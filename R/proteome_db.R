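# Protein database model and I/O.
#
# A ProteinDatabase is a flat table of protein records (accession, sequence,
# taxon, gene symbol, description) plus a kind tag ("microbial" or "host").
# Host records carry the sentinel taxon_id "HOST" so that one record type
# serves both databases.

HOST_TAXON <- "HOST"

.canonical_aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Sanitize an amino-acid sequence
#'
#' Uppercases, strips whitespace, and replaces non-canonical residues
#' (B, Z, J, U, O and anything else outside the 20 canonical letters)
#' with `"X"`. Peptides containing `"X"` are later dropped from digestion
#' output because their identity cannot be compared unambiguously under
#' isoleucine/leucine-variant logic.
#'
#' @param x character vector of sequences.
#' @return character vector of sanitized sequences.
#' @export
sanitize_sequence <- function(x) {
  x <- toupper(gsub("[[:space:]]", "", x))
  gsub(sprintf("[^%s]", paste(.canonical_aa, collapse = "")), "X", x)
}

#' Construct a protein database
#'
#' @param records data.frame with columns `accession`, `sequence`,
#'   `taxon_id`, `gene_symbol`, `description`.
#' @param kind `"microbial"` or `"host"`.
#' @param sanitize sanitize sequences on construction (default `TRUE`).
#' @return an object of class `ProteinDatabase`.
#' @export
protein_database <- function(records, kind = c("microbial", "host"),
                             sanitize = TRUE) {
  kind <- match.arg(kind)
  req <- c("accession", "sequence", "taxon_id", "gene_symbol", "description")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0) {
    stop("records is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records[, req], stringsAsFactors = FALSE)
  dup <- unique(records$accession[duplicated(records$accession)])
  if (length(dup) > 0) {
    stop("duplicated accession(s): ", paste(dup, collapse = ", "))
  }
  if (sanitize) records$sequence <- sanitize_sequence(records$sequence)
  empty <- which(nchar(records$sequence) == 0)
  if (length(empty) > 0) {
    stop("empty sequence for record(s): ",
         paste(records$accession[empty], collapse = ", "))
  }
  if (kind == "host") records$taxon_id <- HOST_TAXON
  no_taxon <- which(is.na(records$taxon_id) | records$taxon_id == "")
  if (kind == "microbial" && length(no_taxon) > 0) {
    stop("microbial record(s) without taxon_id: ",
         paste(records$accession[no_taxon], collapse = ", "))
  }
  rownames(records) <- NULL
  structure(list(records = records, kind = kind), class = "ProteinDatabase")
}

#' @export
print.ProteinDatabase <- function(x, ...) {
  cat(sprintf("ProteinDatabase (%s): %d records, %d taxa\n",
              x$kind, nrow(x$records), length(unique(x$records$taxon_id))))
  invisible(x)
}

#' @export
length.ProteinDatabase <- function(x) nrow(x$records)

#' Read a FASTA protein database
#'
#' Headers are parsed with a configurable delimiter into up to three fields:
#' accession, taxon token, gene symbol (default dialect
#' `"acc|taxon|symbol"`). Host databases may carry bare accessions; their
#' taxon is forced to the `"HOST"` sentinel.
#'
#' @param path FASTA file.
#' @param kind `"microbial"` or `"host"`.
#' @param sep header field delimiter (fixed string, default `"|"`).
#' @return a `ProteinDatabase`.
#' @export
read_fasta <- function(path, kind = c("microbial", "host"), sep = "|") {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) stop("no FASTA records in ", path)
  headers <- names(aa)
  toks <- strsplit(headers, sep, fixed = TRUE)
  parse_one <- function(i) {
    tk <- trimws(toks[[i]])
    tk <- tk[tk != ""]
    if (length(tk) < 1) stop("malformed header at record ", i, ": '",
                             headers[i], "'")
    if (kind == "microbial" && length(tk) < 2) {
      stop("malformed header at record ", i,
           ": expected 'accession", sep, "taxon[", sep, "symbol]', got '",
           headers[i], "'")
    }
    c(accession = tk[1],
      taxon_id = if (length(tk) >= 2) tk[2] else HOST_TAXON,
      gene_symbol = if (length(tk) >= 3) tk[3] else "",
      description = if (length(tk) >= 4) paste(tk[-(1:3)], collapse = " ")
                    else "")
  }
  parsed <- t(vapply(seq_along(toks), parse_one, character(4)))
  seqs <- as.character(aa)
  empty <- which(nchar(gsub("[[:space:]]", "", seqs)) == 0)
  if (length(empty) > 0) {
    stop("empty sequence at record(s): ", paste(empty, collapse = ", "))
  }
  protein_database(
    data.frame(accession = parsed[, "accession"],
               sequence = seqs,
               taxon_id = parsed[, "taxon_id"],
               gene_symbol = parsed[, "gene_symbol"],
               description = parsed[, "description"],
               stringsAsFactors = FALSE),
    kind = kind)
}

#' Write a protein database to FASTA
#'
#' Headers are serialized as `accession|taxon|symbol`, the default dialect
#' understood by [read_fasta()].
#'
#' @param db a `ProteinDatabase`.
#' @param path output file.
#' @param sep header field delimiter.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(db, path, sep = "|") {
  stopifnot(inherits(db, "ProteinDatabase"))
  r <- db$records
  aa <- Biostrings::AAStringSet(r$sequence)
  names(aa) <- paste(r$accession, r$taxon_id, r$gene_symbol, sep = sep)
  Biostrings::writeXStringSet(aa, path, width = 60)
  invisible(path)
}

HABITAT_LEVELS <- c("oral", "gut", "other", "unannotated")
PATHOGENICITY_LEVELS <- c("disease_associated", "opportunistic",
                          "health_associated", "unannotated")
GRAM_LEVELS <- c("negative", "positive", "not_applicable", "unannotated")

#' Read a taxon annotation table
#'
#' Tab-separated table with header columns `taxon_id`, `habitat`
#' (oral/gut/other), `pathogenicity`
#' (disease_associated/opportunistic/health_associated) and `gram`
#' (negative/positive/not_applicable). Taxa present in the database but
#' absent from the table receive explicit `"unannotated"` placeholders with
#' a warning rather than being dropped.
#'
#' @param path TSV file.
#' @param taxa optional character vector of taxa that must be covered
#'   (e.g. `unique(db$records$taxon_id)`).
#' @return data.frame with one row per taxon.
#' @export
read_taxon_annotations <- function(path, taxa = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("taxon_id", "habitat", "pathogenicity", "gram")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0) {
    stop("annotation table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  check_enum <- function(col, levels) {
    bad <- which(!(tab[[col]] %in% levels))
    if (length(bad) > 0) {
      stop(sprintf("unknown %s token '%s' at row %d", col,
                   tab[[col]][bad[1]], bad[1]))
    }
  }
  check_enum("habitat", HABITAT_LEVELS)
  check_enum("pathogenicity", PATHOGENICITY_LEVELS)
  check_enum("gram", GRAM_LEVELS)
  tab <- tab[, req]
  if (!is.null(taxa)) {
    taxa <- setdiff(unique(taxa), HOST_TAXON)
    absent <- setdiff(taxa, tab$taxon_id)
    if (length(absent) > 0) {
      warning("taxa without annotation, recorded as 'unannotated': ",
              paste(absent, collapse = ", "))
      tab <- rbind(tab, data.frame(taxon_id = absent, habitat = "unannotated",
                                   pathogenicity = "unannotated",
                                   gram = "unannotated",
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(tab) <- NULL
  tab
}

#' Write a taxon annotation table
#' @param annotations data.frame as returned by [read_taxon_annotations()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_taxon_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Restrict a database to a set of taxa or accessions
#'
#' Keeps exactly the records whose taxon or accession is in `keep`. Used by
#' the attribution consistency check, which re-attributes peptides against a
#' database reduced to the taxa and proteins identified in a first pass.
#'
#' @param db a `ProteinDatabase`.
#' @param keep non-empty character vector of taxon ids and/or accessions.
#' @return a `ProteinDatabase` of the same kind.
#' @export
restrict_database <- function(db, keep) {
  stopifnot(inherits(db, "ProteinDatabase"))
  if (length(keep) == 0) stop("keep must be non-empty")
  r <- db$records
  sel <- r$taxon_id %in% keep | r$accession %in% keep
  if (!any(sel)) {
    stop("keep set is disjoint from the database (no taxon or accession ",
         "matches)")
  }
  protein_database(r[sel, , drop = FALSE], kind = db$kind, sanitize = FALSE)
}
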