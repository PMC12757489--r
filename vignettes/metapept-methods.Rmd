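---
title: "Detecting microbiome-derived peptides in host proteomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting microbiome-derived peptides in host proteomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Shotgun metaproteomics of host samples — brain extracellular vesicles
(bEVs), the residual whole-brain tissue fraction (WB), plasma EVs — can
reveal proteins of microbial origin circulating in human compartments.
The analytical risk is severe: a peptide-spectrum match against a
multi-taxon microbial database is only evidence of microbial origin if the
peptide sequence could not equally have come from the host. Because mass
spectrometry cannot distinguish isoleucine from leucine (identical mass),
a microbial-looking peptide that matches a host sequence *under any I/L
substitution* is uninformative and must be discarded. `metapept`
implements the post-search stages of such a study: host-homology
exclusion, unique-peptide taxonomic attribution, spectral-count
quantification, disease-stage trend analysis, and correlation screens —
together with a synthetic-data generator that plants ground truth so every
stage can be validated end to end.

The package consumes post-FDR peptide identification tables (as exported
by a search engine) plus the microbial and host FASTA databases; it does
not perform peptide-spectrum matching, FDR control, or reporter-ion
quantitation.

## Host-homology exclusion under I/L ambiguity

A candidate peptide with $k$ residues in $\{I, L\}$ has $2^k$
indistinguishable variants. The exclusion rule is: discard the peptide iff
**any** variant occurs in the host proteome. Enumerating $2^k$ variants is
exponential, so the implementation canonicalizes both the peptide and the
host text by mapping $I \to L$ and performs a single fixed-string
substring search. Two sequences are equal under some I/L substitution iff
their canonical forms are equal, so canonical matching is exactly
equivalent to variant enumeration; the enumeration route is kept as the
test oracle, and the suite asserts zero disagreements between the two on
thousands of generated peptides.

Two matching modes are provided:

* `substring` (default): the variant must occur as a contiguous substring
  anywhere in a host protein. This is the conservative reading of
  "present in the host proteome" — it excludes strictly more peptides and
  protects the microbial-origin claim.
* `tryptic`: the variant must equal a tryptic host peptide. Offered for
  sensitivity analysis; it excludes a subset of what `substring` excludes
  (asserted as a property test).

Peptides containing the ambiguity placeholder `X` (from non-canonical
residues B, Z, J, U, O) are excluded with an explicit reason, since their
identity cannot be compared.

## Digestion and attribution

In-silico trypsin digestion cleaves after K or R except before P, emits
0–`max_missed` missed cleavages (default 2, a common search-engine
setting; configurable because the original search settings of such
studies are rarely reported), and restricts peptides to the 7–22 residue
window in which microbiome-derived peptides are observed. N-terminal
methionine loss is not modeled (off by default; no evidence it matters at
the attribution level). I and L are *not* merged at index time — the
index stays literal to the database so attribution is exact; I/L
ambiguity is handled only by the host filter.

A peptide is *unique to a protein* iff it occurs in exactly one database
protein, and *unique to a taxon* iff all its parent proteins belong to
one taxon. Protein-level uniqueness feeds quantification (shared peptides
never contribute counts, preventing cross-attribution); taxon-level
uniqueness feeds organism presence calls: a taxon is called present in a
condition iff at least one of its taxon-unique peptides has a positive
count there. Both levels are exposed because a peptide mapping to several
proteins of one organism is still unambiguous evidence for that organism,
although not for a single protein.

The attribution-consistency operation re-attributes peptides against a
database restricted to the identified taxa/proteins. Restriction can only
shrink parent sets, so shared peptides may *gain* uniqueness but a unique
peptide can never lose it; the report lists both transitions and flags
any impossible growth.

## Quantification

Protein abundance is the summed spectral count of the protein's unique
peptides (mass balance is asserted as exact integer equality). Two
missing-value policies mirror the primary and validation analysis paths:

* **zero-fill** (primary): "not detected" becomes 0 before rollup.
* **left-censored imputation + log2** (validation): zeros are assumed
  below the detection limit. The default deterministic policy imputes
  half the row's minimum positive value (reproducible without a seed);
  the stochastic alternative draws from a per-column Gaussian in log2
  space down-shifted by 1.8 SD with width 0.3 SD, a standard proteomics
  down-shift, under a fixed seed.

Technical replicates are averaged within subject before group statistics,
so $n$ per group equals the number of subjects — this avoids
pseudo-replication; a pooled mode is available. No between-sample
normalization is applied by default (spectral counting across comparable
runs); this is deliberate and configurable.

## Stage-wise trend analysis

Group-mean profiles (per-protein z-scored) are clustered with fuzzy
c-means (fuzzifier $m = 2$, alternating updates until the maximum
centroid shift is below $10^{-6}$ or 300 iterations; the objective is
asserted non-increasing in every run). Proteins whose maximum membership
falls below 0.5 are flagged unretained, the standard partition
cutoff for this analysis. The cluster count is chosen by maximizing the
fuzzy partition coefficient over $k \in 2..8$ unless fixed by the user.
The implementation is in-package so per-iteration invariants can be
asserted; an independent implementation (`e1071::cmeans`) serves as a
cross-check oracle in the test suite, never as the implementation.

Proteins sharing a gene symbol but landing in different trend clusters
are split into isoforms (`DnaK_1`, `DnaK_2`, ...) — the same conserved
bacterial gene contributed by different organisms can be modulated in
opposite directions. Subscripts are assigned in descending order of the
clusters' first-condition mean, which makes labels deterministic under
cluster relabeling.

Four test variants are run side by side rather than guessing which
applied to which protein in the source analyses: one-way ANOVA with
Bonferroni-corrected pairwise contrasts (primary), protected Fisher's
LSD, one-way ANOVA on ranks, and a two-way ANOVA with factors group and
replicate batch (the only plausible second factor in this design;
documented as an assumption). Bonferroni adjusts within each feature's
contrast family, so the per-feature family-wise error rate is
controlled; under a null generator the fraction of significant features
stays at or below the nominal level (asserted at 6% tolerance). A
feature counts as significant when any pairwise adjusted p is at or
below $\alpha = 0.05$. Degenerate features (identical values everywhere)
report $p = 1$ with a flag.

Dementia-category assignment applies deterministic rules with precedence
**AD_progression → VaD → early_AD → AD → none**:
progression requires a monotone stage profile plus at least one
significant stage-vs-control contrast; VaD requires VaD to differ from
control (or presence exclusive to VaD); early_AD requires a significant
first-stage contrast or presence exclusive to the first stage. Monotone
progression is tested first because a stage-trending protein is usually
also significant at individual stages, and the trend is the more specific
description; VaD modulation is defined against control rather than
against any AD stage so that stage-modulated proteins are not
misattributed to VaD.

## Correlation screens

Pearson correlations are computed on zero-filled counts by default (the
primary quantitation path; an option uses the imputed log2 matrix), with
p from the t transform and a 95% Fisher-z confidence interval. Strength
tiers use $|r| \ge 0.70$ (strong) and $|r| \ge 0.85$ (very strong),
applied exactly at the boundaries. The peptide-level heatmap table keeps
pairs with $|r| > 0.5$ in at least one group — the absolute value is
used deliberately where the figure-legend convention is ambiguous — and
the reversal report lists pairs with $r \ge +0.5$ in one group and
$\le -0.5$ in another, both significant at raw $p \le 0.05$ (raw tiers
match the figure-legend convention; a BH-adjusted column can be emitted
but is not used for filtering). Cross-compartment correlations pair
samples by subject, since both fractions derive from the same tissue
sample, and flag significant negative correlations — the pattern of
interest when vesicle and tissue levels trade off.

## The synthetic-data generator

Proteins are assembled as concatenations of tryptic *blocks*: random
peptides of 7–22 residues ending in K or R, with no internal cleavage
site and no leading proline, so a zero-missed-cleavage digest recovers
the blocks exactly and planting reduces to block placement. The
generator plants, with configurable fractions: verbatim host homologs,
I/L-swapped host homologs, and peptides shared across taxa. After
assembly, the provenance of every block is re-verified against the
realized databases by canonical substring scan, so the truth map stays
exact even in the rare case where a random block collides with host
text.

Spectral counts are drawn from a negative binomial (dispersion 0.3 by
default — spectral counts are overdispersed; Poisson available) around
protein-level group means following each protein's planted trend. The
stage axis is ordinal (control = 0 through the final stage); `VaD` is an
off-axis categorical group. `up_with_stage` multiplies the mean by
`effect_size` per stage step, `early_peak` peaks at the first disease
stage, `vad_only`/`absent_in_vad` gate presence on the VaD group.
Dropout is missing-at-low-abundance: the probability of a "not
detected" cell decreases with the expected count, reflecting where
label-free missingness actually arises. Planted correlation pairs are
realized through a shared latent log-normal factor per group (sign
flipped where a reversal is planted) and are exempt from dropout so the
target coefficient is realized as stated.

The default study design is 6 conditions × 3 subjects × 3 technical
replicates, matching the discovery cohort structure the package targets.
What the generator does **not** emulate: spectra, retention times,
search-engine scoring, FDR filtering, batch effects, or realistic
peptide-intensity distributions; passing tests therefore demonstrate
correctness of the post-search logic, not robustness to
identification-level artifacts in real data.

## Validation problem sizes

The test suite validates the host filter against brute-force variant
enumeration on ten bundles of ~1,000 candidate peptides against 60 host
proteins; statistical calibration on 1,000 null features; planted-effect
power (effect size 3, 3 subjects × 3 replicates, 10% dropout) over 50
generator seeds; clustering recovery over 20 seeds; and correlation
recovery at $n = 30$ samples per group. These sizes give stable
pass/fail behavior for the properties asserted while keeping the suite
quick to run.

## Known limitations

* Exact-occurrence homology only: a host peptide differing by one
  non-I/L substitution is not excluded, matching the method being
  implemented but not protecting against near-homology.
* Flat taxon identifiers: no taxonomy-tree reasoning or lowest common
  ancestor; strain-level entries sharing identical sequences are
  reported as collisions rather than resolved.
* No probabilistic protein inference; uniqueness is set-theoretic.
* The two-way ANOVA's second factor (replicate batch) is an assumption;
  the design table carries no other candidate factor.
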