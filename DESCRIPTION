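Package: metapept
Title: Taxonomic Attribution and Quantification of Microbiome-Derived
    Peptides in Host Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-search metaproteomic analysis of microbiome-derived
    peptides detected in host samples such as brain extracellular
    vesicles. Provides in-silico tryptic digestion and peptide indexing
    of multi-taxon protein databases, isoleucine/leucine-aware exclusion
    of host-homologous peptides, unique-peptide taxonomic attribution,
    spectral-count quantification with zero-fill and left-censored
    imputation policies, fuzzy c-means abundance-trend clustering with
    ANOVA-family stage-wise testing, and peptidome-wide Pearson
    correlation screens with sign-reversal detection. A synthetic-data
    generator plants ground-truth provenance, abundance trends and
    correlation structure so that every stage of the pipeline can be
    validated end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
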