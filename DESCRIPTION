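Package: mhcsubsets
Title: MHC Class I Transcript and Surface-Expression Profiling in Leukocyte Subsets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring relative MHC class I allele expression in
    surface-marker-defined leukocyte subsets from MID-tagged amplicon
    sequencing. Implements demultiplexing of 10-bp multiplex identifier
    (MID) tags, primer trimming, collapsing of reads into 100%-identity
    contigs, mismatch-bounded assignment against a reference of highly
    homologous class I alleles, normalization to per-subset transcript
    profiles with dual-MID replicates, chi-square tests of differential
    transcription, dominant-allele exclusion renormalization, gene-dosage
    and PBMC-mixture consistency checks, discovery of discriminative
    sequence motifs with synonymous/nonsynonymous codon classification,
    Edman-degradation peptide-binding-motif construction, and
    fluorescent-peptide relative surface-expression statistics. A
    synthetic-data module generates references, reads with known ground
    truth, Edman cycle tables and flow-cytometry MFI tables so the whole
    workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    seqinr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
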