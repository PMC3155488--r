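---
title: "Methods: per-subset MHC class I expression profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-subset MHC class I expression profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhcsubsets)
```

## The measurement problem

MHC class I alleles are too similar for antibody- or qPCR-based
allele-level quantification, especially in macaques, where a single
haplotype can carry many expressed class I genes. The strategy implemented
by this package genotypes expression instead: a short polymorphic amplicon
(190 bp of exon 2 for macaques; 581 bp for humans) is amplified from the
cDNA of each purified leukocyte subset, each subset twice with two
distinct 10-bp MID tags, pooled and deep sequenced. Because every class I
transcript is amplified by the same universal primers, the read share of
each allele estimates its share of class I transcripts — a *relative*
measure: the analysis cannot tell one gene transcribed more from the
others transcribed less, and primer bias can distort the dominance
hierarchy. The two MID replicates exist to detect (not remove) such bias;
they are kept visible as per-MID points next to the combined estimate.

## Pipeline model and assumptions

The read model is `MID (10 bp) + forward primer + insert + reverse
complement of the reverse primer`, forward strand, substitution errors
only. That matches the simulator exactly and real amplicon data
approximately; indels (e.g. homopolymer errors typical of
pyrosequencing) are out of scope, which is why assignment is an ungapped
mismatch count rather than an alignment. The stages:

* **Demultiplexing** (`demultiplex()`): a read joins a MID bin iff its
  10-bp prefix is within `max_tag_mismatch` of that tag *and strictly
  closer* to it than to any other tag; ties are unassigned. The default is
  0 (exact match) — the conservative reading of binning by tag, and the
  right one when tags are well separated. `make_mid_tags()` enforces
  pairwise tag distance ≥ 3 so even 1-mismatch binning would be
  unambiguous.
* **Trimming** (`trim_reads()`): primers are verified at their anchored
  positions within `max_primer_mismatch` (default 2) and the insert length
  must match `expected_insert_length` within `length_tolerance` (default
  0, since the amplicon is fixed-length under a substitution-only model).
  Reads containing `N` are rejected; rejection reasons (`contains_N`,
  `no_fwd_primer`, `no_rev_primer`, `bad_length`) are return states, not
  errors, and are tallied in the run log.
* **Contigs** (`collapse_identical()`): 100%-identity clusters, i.e.
  byte-identical inserts. Sorted by descending read count, then
  lexicographically — a deterministic tie-break.
* **Assignment** (`assign_clusters()`): mismatch count against every
  reference amplicon; best score within `max_mismatch` (default 2 for the
  190 bp amplicon) wins. A unique best is an allele call; equally best
  alleles within one lineage collapse to the two-digit group (the natural
  resolution of a short amplicon); equally best across lineages is
  ambiguous; nothing within the ceiling is unassigned. Assignment happens
  once per contig and is weighted by its read count — the same order of
  operations as contig-then-database-search, and cheaper.
* **Counting** (`count_table()`): read-weighted counts per (subset, MID,
  allele-or-group); ambiguous and unassigned reads are tallied separately
  and never enter the allele counts or the normalization denominator.

With the default error rate 0.005/bp a 190 bp read carries ≥ 3 errors
about 7% of the time and is then typically unassignable; because errors
are independent of the allele drawn, this loss is unbiased and the
fraction estimates remain binomial around the truth, which is what the
recovery tests assert (3 binomial SD at n = 2000 reads).

There is no chimera detector and no singleton filter (`min` cluster size
is effectively 1): artifact sequences are whatever fails assignment, and
filtering can be done downstream on the contig table if desired.

## Normalization and statistics

`normalize_profile()` sums counts over the two MIDs *before* dividing
(never averaging per-MID fractions — with unequal MID depths the two are
not the same). `renormalize_excluding()` removes a dominant allele and
rescales, preserving pairwise ratios exactly because it recomputes from
counts. `chi_square_across_subsets()` interprets "frequency of an allele
across cell types" as the 2 × k table of allele-vs-all-other reads per
subset, tested with the uncorrected chi-square (df = k − 1); the
construction is a documented interpretation since contingency tables can
be formed in more than one way. Expected counts below 5 produce a warning,
not a switch to an exact test, and p-values are reported raw (the
differential-transcription driver adds a Bonferroni-adjusted column via
`stats::p.adjust` alongside, never instead), mirroring how such
per-allele p-values are conventionally reported. `mixture_check()`
renormalizes the supplied composition to sum to 1 and unions allele sets
with zeros, so partially specified compositions behave predictably.
`limit_of_detection()` flags alleles under 2 combined reads; the threshold
is a design choice exposed as a parameter.

## Motif procedures

`find_discriminative_positions()` implements the strict "only present in"
criterion: unanimity in the differential group and absence of that state
from every comparison sequence. Sequences must be pre-aligned and
equal-length (the examined exon 3 window is length-conserved among the
alleles of interest); a length check deliberately replaces a gapped
aligner. The comparison-group consensus is majority rule with alphabetical
tie-break. `classify_substitutions()` labels all nucleotide changes inside
a codon jointly — synonymous if the amino acid is unchanged, nonsynonymous
otherwise — so a codon with two changes producing one replacement counts
two nonsynonymous differences, the only convention consistent with
reporting two nonsynonymous differences for an ATG→GAG codon. Codon
numbering is caller-supplied metadata (`first_codon`); the package does
not infer mature-protein numbering.

`classify_residue()` uses lower-inclusive, upper-exclusive fold classes
(dominant ≥ 3.5, strong [2.5, 3.5), weak [2.0, 2.5)) so the classes
partition the half-line, with the ≥ 3.5 boundary explicitly inclusive.
`fold_increase()` reports a fold as missing (never infinite) when the
prior cycle is below 0.1 pmol — division by a near-zero yield is
meaningless. Within a class, residues are ranked by descending fold (the
binding hierarchy); anchors are cycles with a dominant residue.

## Surface expression

`relative_expression()` is (MFI peptide / MFI no peptide) × 100. The
pan-MHC (W6/32) adjustment is deliberately a *separate*, optional step
(`w632_scale()`, multiplying by reference-to-subset pan-MHC ratio, the
reference defaulting to the animal's across-subset mean) because the exact
normalization form used with such data is not standardized; raw and
scaled variants are always distinguishable in the output. Tests are
two-sided throughout; the unpaired t defaults to the classic
pooled-variance form with Welch behind a flag. Degenerate inputs are
reported rather than raised: identical pairs give t = 0, p = 1; constant
non-zero differences give an infinite t flagged `degenerate`; an
all-constant repeated-measures matrix gives F = 0, p = 1 (the 0/0 cases
are resolved by the direction the limit takes).

## What the simulators emulate — and what they do not

`GroundTruth` holds per-subset allele fraction vectors, a PBMC
composition, optional per-MID amplification bias (a per-allele positive
multiplier, renormalized into the sampling weights), a per-base
substitution error rate, and a seed. All generators are bit-reproducible
given seed and parameters; per-subset and per-MID streams are derived
deterministically from the base seed so adding one simulation never
shifts another.

Default study conditions, chosen once: 190 bp amplicon; toy references
with pairwise distance ≥ 5 (so 2-mismatch assignment cannot confuse
alleles); 12 MID tags; 2 MIDs × 1000 reads per subset (the order of the
few-thousand reads per subset a pooled pyrosequencing run yields); error
rate 0.005/bp — a free parameter of the simulator, not a measured
instrument property; composition CD4 0.35, CD8 0.20, CD14 0.20, CD16
0.10, CD20 0.15 (typical primate PBMC proportions, with the CD14 value
also the condition under which a 0.45 CD14-dominant allele dilutes to
0.09 in PBMC); Edman/MFI noise coefficient of variation 0.05 (lognormal).

Not emulated: flowgram/homopolymer chemistry, PCR chimeras, indels,
quality scores (FASTQ is read, qualities ignored), cell-separation
impurity, and real allele sequence homology structure (toy references are
random subject to divergence constraints). Passing tests therefore
demonstrate correctness of the computational procedure under its stated
error model — not robustness to 454-specific artifacts, which the
out-of-scope list above excludes deliberately.

One internal consistency choice: the simulator appends the reverse
complement of the reverse primer to each read even though the shortest
statement of the read model omits it, because the trimmer verifies and
removes it and enumerates its absence as a rejection reason. Errors are
applied to the insert only.

The Edman simulator gives non-designated residues a background fold of
0.9 (carry-over decay, safely below every class boundary) and re-derives
the classes from the finished noisy table, erroring if noise flipped any
planted class — so a successfully constructed table always round-trips.
Note a weak residue planted at fold 2.2 sits only 0.095 log-units above
the 2.0 boundary; at the default 5% noise some seeds are rejected, which
is the intended behavior of that check, and noiseless tables are used
wherever exact round-tripping is asserted.

## Verification strategy and problem sizes

The test suite runs two routes against each other wherever an independent
oracle exists: the statistics (chi-square, paired/unpaired t,
repeated-measures ANOVA, implemented over `stats::chisq.test`,
`stats::t.test` and `stats::aov`) are checked against direct
textbook-formula recomputation to 1e-10 on 1000 random instances each;
translation is checked against a second genetic-code implementation on
all 64 codons; discriminative positions and allele assignment are checked
against exhaustive scans on random instances. End-to-end identity is
asserted at zero error (the count table must equal the generator's
emission log exactly, 12 MIDs × 1000 reads), and stochastic recovery at
the default error rate within 3 binomial SD across 20 seeded replicates
(2 × 1000 reads per population). These sizes keep the full suite around a
minute while leaving the binomial bounds tight enough to detect percent-
level bias.

## Known limitations

* Relative, not absolute, quantification; primer bias is detectable via
  MID replicates but not corrected.
* Ungapped assignment cannot place reads from alleles with indel variation
  in the amplicon, nor discover novel alleles (unassigned contigs are
  simply listed).
* The 2 × k chi-square treats reads as independent draws; PCR duplicates
  in real data violate this and inflate significance.
* Lineage-level calls depend on the reference: alleles missing from the
  reference silently donate reads to their nearest lineage-mate within
  the mismatch ceiling.
* The W6/32 scaling form is one reasonable choice among several; results
  using it should state the reference signal used.
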