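# mhcsubsets

Per-subset MHC class I expression profiling from MID-tagged amplicon
sequencing, for immunogeneticists studying how individual class I alleles
are expressed across leukocyte subsets (CD4+ and CD8+ T cells, CD14+
monocytes, CD16+ cells, CD20+ B cells) in macaques and humans.

Macaques transcribe up to ~20 distinct MHC class I alleles per haplotype,
and the sequences are so homologous that allele-level expression cannot be
resolved by antibodies or qPCR. The approach implemented here resolves it
by sequencing: a short, polymorphic amplicon (190 bp of exon 2 in
macaques, 581 bp in humans) is amplified from each purified leukocyte
subset with two independent PCR reactions carrying distinct 10-bp MID
(multiplex identifier) tags, pooled, and deep sequenced. Reads are binned
by MID, collapsed into 100%-identity contigs, and matched against a
reference of class I sequences; alleles that a short amplicon cannot
separate are reported at the two-digit lineage level (e.g. `Mafa-B*134`).

## The model

**Relative transcript abundance.** For each subset, the profile is

    fraction(allele) = combined reads for that allele from both MID tags
                       / total combined reads from both MID tags

The two MID replicates control for primer bias; the method is relative —
it cannot distinguish one allele being transcribed more from the others
being transcribed less. Downstream operations: renormalization after
excluding a dominant allele (preserving all pairwise ratios), a
limit-of-detection flag for alleles with fewer than 2 supporting reads,
a gene-dosage comparison (heterozygous carriers are expected at about half
the homozygous fraction), and a PBMC mixture check — the whole-PBMC
fraction of an allele should equal the composition-weighted sum of its
subset fractions.

**Differential transcription.** An allele's frequency is compared across
k subsets by an uncorrected chi-square test on the 2 × k table of
allele-vs-all-other read counts, X² = Σ(O−E)²/E with df = k − 1.

**Discriminative sequence motifs.** Over pre-aligned allele sequences, a
position is discriminative when all differentially expressed alleles share
a state carried by no other allele. Nucleotide differences are classified
per codon as synonymous or nonsynonymous under the standard genetic code
(a multi-hit codon's changes are labeled jointly by the amino acid
outcome), and a reference database can be scanned for motif carriers.

**Peptide-binding motifs from Edman degradation.** From a cycle ×
amino-acid picomole table, fold increase over the prior cycle classifies
each residue: dominant (≥ 3.5×), strong (2.5–3.5×), weak (2.0–2.5×);
anchor positions are cycles with a dominant residue, and residues within a
class are ordered by descending fold.

**Surface expression by fluorescent peptides.** Relative expression =
(MFI peptide / MFI no peptide) × 100, optionally scaled by the pan-MHC
(W6/32) MFI; subsets are compared by paired/unpaired t tests and one-way
repeated-measures ANOVA.

A synthetic-data module (`make_toy_reference()`, `simulate_subset_reads()`,
`simulate_pbmc()`, `simulate_edman_table()`, `simulate_mfi_table()`)
generates every input with known ground truth, including dual-MID
replicates with optional per-MID bias, substitution sequencing error, and
PBMC as a composition-weighted subset mixture.

## Worked example

Simulate a monocyte-dominant allele (45% of CD14+ transcripts, absent
from CD4+ cells), run the read-to-counts pipeline, and test for
differential transcription:

```r
library(mhcsubsets)

ref <- make_toy_reference(5, 190, min_pairwise_differences = 5, seed = 42)
truth <- ground_truth(
  reference = ref,
  subset_profiles = list(
    CD14 = setNames(c(0.45, 0.25, 0.15, 0.10, 0.05), ref$name),
    CD4  = setNames(c(0.00, 0.40, 0.30, 0.20, 0.10), ref$name)),
  composition = c(CD14 = 0.2, CD4 = 0.8),
  error_rate = 0.005, seed = 42)

mids <- make_mid_tags(4, seed = 42)
cd14 <- simulate_subset_reads(truth, "CD14", 1000, mids[1:2, ])
cd4  <- simulate_subset_reads(truth, "CD4",  1000, mids[3:4, ])

run <- run_amplicon_pipeline(
  rbind(cd14$reads, cd4$reads), ref, mids,
  data.frame(tag_id = mids$tag_id, subset = rep(c("CD14", "CD4"), each = 2)))

normalize_profile(run$count_table, "CD14")
#> <transcript_profile> subset CD14, 1863 reads
#> Mafa-B*001:01 Mafa-B*002:01 Mafa-B*003:01 Mafa-B*004:01 Mafa-B*005:01
#>         0.449         0.256         0.142         0.105         0.048

chi_square_across_subsets(run$count_table, ref$name[1])
#> <diff_result> Mafa-B*001:01: X^2 = 1085, df = 1, p = < 2.22e-16
#>   CD14    CD4
#> 0.4493 0.0000
```

The planted 0.45 is recovered at 0.449 from 1863 assigned reads (reads
with three or more sequencing errors fall outside the 2-mismatch
assignment ceiling and are dropped, which leaves the fractions unbiased),
and the monocyte restriction is overwhelmingly significant.

The motif machinery on two alpha-2-domain consensus windows:

```r
mt <- motif_table(group_diff  = rep("GCTGCGGATGAG", 2),
                  group_other = rep("GCCGCGGACATG", 3), first_codon = 159)
mt
#> <motif_result> 4 discriminative position(s) {3,9,10,11}; 2 synonymous / 2 nonsynonymous nt difference(s)
#> G C C G C G G A C A T G
#> • • T • • • • • T G A •
subset(mt$per_codon, classification == "nonsynonymous")
#>   codon ref_codon derived_codon ref_aa derived_aa n_nt_diff classification
#> 4   162       ATG           GAG      M          E         2  nonsynonymous
```

Four positions discriminate the differentially expressed alleles; two of
the differences are synonymous and two replace methionine with glutamic
acid at codon 162.

## The analysis workflow

The `analysis/` scripts rebuild the whole study on synthetic data and
write their tables under `results/` (large intermediates go to
`scratch/`, which is disposable):

```sh
Rscript analysis/01_simulate_reads.R           # reads + study tables
Rscript analysis/02_transcript_profiles.R      # pipeline + profiles
Rscript analysis/03_differential_transcription.R
Rscript analysis/04_sequence_motif.R
Rscript analysis/05_edman_motif.R
Rscript analysis/06_surface_expression.R
```

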