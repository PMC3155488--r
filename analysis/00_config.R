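# Shared study definition for the analysis workflow.
#
# All data are synthetic stand-ins generated by the package's simulators
# (no sequencing or flow-cytometry data are distributed): one MHC-defined
# "homozygous" animal with a CD14-dominant class I transcript, a
# "heterozygous" carrier at half gene dose, Edman degradation of the
# dominant allele's eluted peptides, and a 20-animal fluorescent-peptide
# staining panel.

library(mhcsubsets)

STUDY_SEED <- 20110715L

SUBSETS <- c("CD4", "CD8", "CD14", "CD16", "CD20")
COMPOSITION <- c(CD4 = 0.35, CD8 = 0.20, CD14 = 0.20, CD16 = 0.10,
                 CD20 = 0.15)
N_READS_PER_MID <- 1000
AMPLICON_LENGTH <- 190

# The CD14-dominant transcript is allele 1 of the toy reference; its true
# fraction per subset mirrors a monocyte-restricted expression pattern
# (high in CD14+, intermediate in CD16+, near the detection limit in
# lymphocytes).
DOMINANT_FRACTION <- c(CD4 = 0.005, CD8 = 0.002, CD14 = 0.45, CD16 = 0.15,
                       CD20 = 0.01)

make_study_reference <- function() {
  make_toy_reference(8, AMPLICON_LENGTH, min_pairwise_differences = 5,
                     seed = STUDY_SEED)
}

make_study_truth <- function(dominant_scale = 1) {
  ref <- make_study_reference()
  base <- c(0.20, 0.18, 0.15, 0.13, 0.12, 0.12, 0.10)  # other 7 alleles
  profiles <- lapply(SUBSETS, function(s) {
    dom <- DOMINANT_FRACTION[[s]] * dominant_scale
    setNames(c(dom, (1 - dom) * base), ref$name)
  })
  names(profiles) <- SUBSETS
  ground_truth(ref, profiles, composition = COMPOSITION,
               error_rate = 0.005, seed = STUDY_SEED)
}

DOMINANT_ALLELE <- make_study_reference()$name[1]

results_path <- function(...) {
  dir.create("results", showWarnings = FALSE)
  file.path("results", ...)
}

scratch_path <- function(...) {
  dir.create(file.path("scratch", "sim"), recursive = TRUE,
             showWarnings = FALSE)
  file.path("scratch", "sim", ...)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  message("  wrote ", path)
}
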