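# Independent brute-force oracles used across tests. These deliberately
# take the slow, literal route (variant enumeration, exhaustive substring
# scans, set algebra on raw rows) so they stay independent of the package's
# optimized implementations.

# host-homology oracle: enumerate all 2^k I/L variants and scan every host
# sequence for each variant
oracle_host_excluded <- function(peptides, host_db) {
  host_seqs <- host_db$records$sequence
  vapply(peptides, function(p) {
    if (grepl("X", p, fixed = TRUE)) return(TRUE)
    vs <- il_variants(p)
    any(vapply(vs, function(v)
      any(grepl(v, host_seqs, fixed = TRUE)), logical(1)))
  }, logical(1))
}

# peptide-index oracle: exhaustive substring scan restricted to tryptic
# boundaries, honoring the missed-cleavage cap
oracle_parents <- function(peptide, db, max_missed = 2) {
  recs <- db$records
  found <- character(0)
  for (i in seq_len(nrow(recs))) {
    seqv <- recs$sequence[i]
    n <- nchar(seqv)
    chars <- strsplit(seqv, "")[[1]]
    is_cut <- function(pos) {            # cleavage after position pos?
      pos >= 1 && pos <= n &&
        chars[pos] %in% c("K", "R") &&
        (pos == n || chars[pos + 1] != "P")
    }
    hits <- gregexpr(peptide, seqv, fixed = TRUE)[[1]]
    if (hits[1] == -1) next
    len <- nchar(peptide)
    for (st in as.integer(hits)) {
      en <- st + len - 1
      left_ok <- st == 1 || is_cut(st - 1)
      right_ok <- en == n || is_cut(en)
      internal <- sum(vapply(st:(en - 1), is_cut, logical(1)))
      if (left_ok && right_ok && internal <= max_missed) {
        found <- c(found, recs$accession[i])
        break
      }
    }
  }
  sort(unique(found))
}

# tiny hand-built database used by attribution tests: peptide sharing
# within and across taxa is explicit in the sequences
tiny_attribution_db <- function() {
  # SSTTVVYK appears in P1 (TaxA), P3 (TaxA) and P2 (TaxB);
  # HHHGGFFK appears in P1 and P3 only (both TaxA);
  # QQQWWEEK appears in P1 only
  protein_database(data.frame(
    accession = c("P1", "P2", "P3"),
    sequence = c("QQQWWEEKSSTTVVYKHHHGGFFK",
                 "SSTTVVYKQQQQQQQK",
                 "HHHGGFFKSSTTVVYK"),
    taxon_id = c("TaxA", "TaxB", "TaxA"),
    gene_symbol = c("g1", "g2", "g1"),
    description = "",
    stringsAsFactors = FALSE), kind = "microbial")
}

# small deterministic bundle shared by several tests
small_bundle <- function(seed = 7, ...) {
  synthesize_bundle(n_taxa = 4, proteins_per_taxon = 4, host_size = 20,
                    peptides_per_protein = 8, seed = seed, ...)
}

# peptide x sample count matrix from a long quant table
quant_matrix <- function(quant) {
  q <- zero_fill(quant)
  m <- matrix(0, nrow = length(unique(q$peptide)),
              ncol = length(unique(q$sample_id)),
              dimnames = list(sort(unique(q$peptide)),
                              sort(unique(q$sample_id))))
  m[cbind(q$peptide, q$sample_id)] <- q$count
  m
}

# run filter -> attribute -> zero-fill -> rollup on a bundle
bundle_protein_matrix <- function(bundle, max_missed = 2) {
  idx <- build_peptide_index(bundle$microbial, max_missed = max_missed)
  filt <- filter_host_homologs(unique(bundle$quant$peptide), bundle$host)
  at <- suppressWarnings(
    attribute_peptides(filt$retained, idx, bundle$annotations))
  list(attrib = at,
       mat = suppressWarnings(rollup_to_protein(zero_fill(bundle$quant),
                                                at)),
       index = idx, filter = filt)
}
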