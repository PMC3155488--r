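#!/usr/bin/env Rscript
# Simulate the study's raw sequencing inputs: dual-MID amplicon reads for
# five leukocyte subsets plus whole PBMC of a homozygous carrier of a
# CD14-dominant class I allele, and a CD14 run for a heterozygous carrier
# at half gene dose. Reads (FASTA) and emission logs go to scratch/sim/;
# the small study tables go to results/.

source("analysis/00_config.R")

truth <- make_study_truth()
ref <- truth$reference
mids <- make_mid_tags(12, seed = STUDY_SEED)

message("Simulating ", length(SUBSETS), " subsets + PBMC, 2 MIDs x ",
        N_READS_PER_MID, " reads each, error rate ", truth$error_rate)

sims <- lapply(seq_along(SUBSETS), function(i) {
  simulate_subset_reads(truth, SUBSETS[i], N_READS_PER_MID,
                        mids[(2 * i - 1):(2 * i), ])
})
pbmc <- simulate_pbmc(truth, N_READS_PER_MID, mids[11:12, ])
sims <- c(sims, list(pbmc))

reads <- do.call(rbind, lapply(sims, `[[`, "reads"))
emission <- do.call(rbind, lapply(sims, `[[`, "emission"))

write_reads_fasta(reads, scratch_path("hom_reads.fasta"))
write_tsv(emission, scratch_path("hom_emission.tsv"))

# Heterozygous carrier: the dominant allele at half its homozygous
# fraction in CD14+ cells (gene dosage).
het <- make_study_truth(dominant_scale = 0.5)
het_mids <- make_mid_tags(2, seed = STUDY_SEED + 1)
het_sim <- simulate_subset_reads(het, "CD14", N_READS_PER_MID, het_mids)
write_reads_fasta(het_sim, scratch_path("het_cd14_reads.fasta"))
write_tsv(het_sim$emission, scratch_path("het_cd14_emission.tsv"))

write_allele_fasta(ref, scratch_path("reference.fasta"))
write_tsv(mids, results_path("mid_tags.tsv"))
write_tsv(het_mids, results_path("mid_tags_het.tsv"))
write_tsv(data.frame(tag_id = mids$tag_id,
                     subset = rep(c(SUBSETS, "PBMC"), each = 2)),
          results_path("subset_map.tsv"))
write_tsv(data.frame(subset = names(COMPOSITION),
                     fraction = unname(COMPOSITION)),
          results_path("composition.tsv"))
true_prof <- do.call(rbind, lapply(names(truth$subset_profiles), function(s) {
  data.frame(subset = s, allele = names(truth$subset_profiles[[s]]),
             true_fraction = unname(truth$subset_profiles[[s]]))
}))
write_tsv(true_prof, results_path("true_profiles.tsv"))

message("Done: ", nrow(reads) + nrow(het_sim$reads), " reads simulated; ",
        "the CD14-dominant allele is ", DOMINANT_ALLELE,
        " at true fraction 0.45 in CD14+ cells.")
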