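#' Ground truth for a simulated subset-expression study
#'
#' Bundles everything the read simulators need: the allele reference, the
#' true per-subset relative transcript fractions, the PBMC composition, any
#' per-MID amplification bias, and the per-base substitution error rate.
#'
#' @param reference an [mhc_reference].
#' @param subset_profiles named list; each element is a named numeric vector
#'   of allele fractions for one subset, summing to 1 (within 1e-9).
#' @param composition optional named numeric vector: fraction of whole PBMC
#'   contributed by each subset (non-negative, sum <= 1).
#' @param mid_bias optional named list mapping a MID `tag_id` to a named
#'   numeric vector of positive per-allele amplification multipliers
#'   (alleles not listed have multiplier 1). Models primer bias between the
#'   two replicate amplifications.
#' @param error_rate per-base substitution probability in \[0, 0.05\].
#' @param seed integer seed; all simulators derived from this truth are
#'   deterministic given it.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(reference, subset_profiles, composition = NULL,
                         mid_bias = list(), error_rate = 0.005, seed = 1L) {
  stopifnot(inherits(reference, "mhc_reference"))
  if (!length(subset_profiles) || is.null(names(subset_profiles))) {
    stop("subset_profiles must be a named list of fraction vectors")
  }
  for (s in names(subset_profiles)) {
    p <- subset_profiles[[s]]
    if (is.null(names(p)) || any(p < 0)) {
      stop("profile for ", sQuote(s), " must be a named non-negative vector")
    }
    if (abs(sum(p) - 1) > 1e-9) {
      stop("profile for ", sQuote(s), " must sum to 1 (got ", sum(p), ")")
    }
    missing <- setdiff(names(p), reference$name)
    if (length(missing)) {
      stop("profile for ", sQuote(s), " names allele(s) absent from the ",
           "reference: ", paste(sQuote(missing), collapse = ", "))
    }
  }
  if (!is.null(composition)) {
    if (is.null(names(composition)) || any(composition < 0)) {
      stop("composition must be a named non-negative vector")
    }
    if (sum(composition) > 1 + 1e-9) stop("composition must sum to <= 1")
  }
  for (b in mid_bias) {
    if (is.null(names(b)) || any(b <= 0)) {
      stop("mid_bias entries must be named positive multipliers")
    }
  }
  if (error_rate < 0 || error_rate > 0.05) {
    stop("error_rate must be in [0, 0.05]")
  }
  structure(
    list(reference = reference, subset_profiles = subset_profiles,
         composition = composition, mid_bias = mid_bias,
         error_rate = error_rate, seed = as.integer(seed)),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", length(x$subset_profiles), " subset(s), ",
      nrow(x$reference), " reference allele(s), error_rate = ",
      x$error_rate, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate a toy reference of divergent, homologous allele sequences
#'
#' Random amplicon-length sequences constrained so every pair differs at a
#' minimum number of positions (so that bounded-mismatch assignment cannot
#' confuse alleles). A sequence motif can be embedded in a chosen subset of
#' alleles: carriers match the motif exactly, non-carriers are guaranteed to
#' differ from it at one or more motif positions.
#'
#' @param n_alleles number of alleles.
#' @param amplicon_length sequence length in bp (default 190, the length of
#'   the short class I exon-2 amplicon).
#' @param min_pairwise_differences minimum Hamming distance between any two
#'   allele sequences.
#' @param motif_spec optional list with elements `positions` (1-based),
#'   `states` (bases at those positions) and `carriers` (indices of the
#'   alleles that carry the motif).
#' @param seed integer seed; generation is deterministic given it.
#' @param locus locus string used to build allele names (each allele gets
#'   its own lineage, `locus*001`, `locus*002`, ...).
#' @param max_attempts rejection-sampling attempts per allele before the
#'   constraints are declared infeasible.
#' @return an [mhc_reference].
#' @export
make_toy_reference <- function(n_alleles, amplicon_length = 190,
                               min_pairwise_differences = 5,
                               motif_spec = NULL, seed = 1L,
                               locus = "Mafa-B", max_attempts = 1000L) {
  stopifnot(n_alleles >= 1, amplicon_length >= 1,
            min_pairwise_differences >= 0,
            min_pairwise_differences <= amplicon_length)
  if (!is.null(motif_spec)) {
    stopifnot(length(motif_spec$positions) == length(motif_spec$states))
    if (any(motif_spec$positions < 1 |
            motif_spec$positions > amplicon_length)) {
      stop("motif positions must lie within the amplicon")
    }
    if (any(motif_spec$carriers < 1 | motif_spec$carriers > n_alleles)) {
      stop("motif carrier indices out of range")
    }
  }
  seqs <- with_seed(derive_seed(seed, "toy_reference"), {
    out <- character(n_alleles)
    for (i in seq_len(n_alleles)) {
      placed <- FALSE
      for (attempt in seq_len(max_attempts)) {
        s <- strsplit(random_dna(amplicon_length), "", fixed = TRUE)[[1]]
        if (!is.null(motif_spec)) {
          if (i %in% motif_spec$carriers) {
            s[motif_spec$positions] <- motif_spec$states
          } else if (all(s[motif_spec$positions] == motif_spec$states)) {
            j <- sample(seq_along(motif_spec$positions), 1)
            p <- motif_spec$positions[j]
            s[p] <- sample(setdiff(DNA_BASES, motif_spec$states[j]), 1)
          }
        }
        cand <- paste(s, collapse = "")
        if (i == 1 ||
            all(vapply(out[seq_len(i - 1)], str_hamming, integer(1),
                       b = cand) >= min_pairwise_differences)) {
          out[i] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not satisfy min_pairwise_differences = ",
             min_pairwise_differences, " for ", n_alleles, " alleles of ",
             "length ", amplicon_length, " after ", max_attempts,
             " attempts")
      }
    }
    out
  })
  mhc_reference(sprintf("%s*%03d:01", locus, seq_len(n_alleles)), seqs)
}

#' Generate a set of distinct 10-bp MID tags
#'
#' @param n number of tags (default 12, one pooled sequencing group).
#' @param seed integer seed.
#' @param min_distance minimum pairwise Hamming distance between tags.
#' @return data.frame with columns `tag_id` (`"MID01"`, ...) and
#'   `tag_sequence`.
#' @export
make_mid_tags <- function(n = 12, seed = 1L, min_distance = 3) {
  stopifnot(n >= 1, min_distance <= 10)
  tags <- with_seed(derive_seed(seed, "mid_tags"), {
    out <- character(n)
    for (i in seq_len(n)) {
      for (attempt in seq_len(10000L)) {
        cand <- random_dna(10)
        if (i == 1 ||
            all(vapply(out[seq_len(i - 1)], str_hamming, integer(1),
                       b = cand) >= min_distance)) {
          out[i] <- cand
          break
        }
      }
      if (!nzchar(out[i])) stop("could not generate distinct MID tags")
    }
    out
  })
  data.frame(tag_id = sprintf("MID%02d", seq_len(n)), tag_sequence = tags,
             stringsAsFactors = FALSE)
}

#' Default toy PCR primer pair
#'
#' Fixed arbitrary primer sequences used by the simulators and the worked
#' examples; any primer pair can be substituted.
#'
#' @return list with elements `fwd` and `rev`.
#' @export
default_primers <- function() {
  list(fwd = "GCTCCCACTCCATGAGGTAT", rev = "GGTCCCAATACTCCGGACC")
}

# Apply i.i.d. per-base substitution errors to a character vector of reads.
mutate_sequences <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  L <- nchar(seqs)
  nmut <- stats::rbinom(length(seqs), L, rate)
  for (i in which(nmut > 0)) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(L[i], nmut[i])
    for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

# Shared machinery: emit dual-MID reads from one fraction vector.
simulate_reads_from_profile <- function(truth, profile, label,
                                        n_reads_per_mid, mids,
                                        primer_fwd, primer_rev, seed) {
  stopifnot(n_reads_per_mid >= 1)
  mids <- validate_mid_table(mids)
  amp <- amplicon_sequences(truth$reference)[names(profile)]
  rc_rev <- revcomp(primer_rev)
  reads <- vector("list", nrow(mids))
  emission <- vector("list", nrow(mids))
  for (m in seq_len(nrow(mids))) {
    tag_id <- mids$tag_id[m]
    bias <- truth$mid_bias[[tag_id]]
    w <- profile
    if (!is.null(bias)) {
      mult <- rep(1, length(w))
      names(mult) <- names(w)
      shared <- intersect(names(bias), names(w))
      mult[shared] <- bias[shared]
      w <- w * mult
    }
    w <- w / sum(w)
    res <- with_seed(derive_seed(seed, label, tag_id), {
      alleles <- sample(names(w), n_reads_per_mid, replace = TRUE, prob = w)
      inserts <- mutate_sequences(unname(amp[alleles]), truth$error_rate)
      list(alleles = alleles, inserts = inserts)
    })
    ids <- sprintf("%s_%s_%05d", label, tag_id, seq_len(n_reads_per_mid))
    reads[[m]] <- data.frame(
      read_id = ids,
      sequence = paste0(mids$tag_sequence[m], primer_fwd, res$inserts,
                        rc_rev),
      stringsAsFactors = FALSE
    )
    emission[[m]] <- data.frame(
      read_id = ids, subset = label, mid = tag_id,
      true_allele = res$alleles, stringsAsFactors = FALSE
    )
  }
  structure(list(reads = do.call(rbind, reads),
                 emission = do.call(rbind, emission)),
            class = "sim_reads", seed = as.integer(seed))
}

#' Simulate dual-MID amplicon reads for one leukocyte subset
#'
#' Each read is `MID tag + forward primer + allele amplicon + reverse
#' complement of the reverse primer`; substitution errors (at the truth's
#' `error_rate`) are applied to the amplicon insert. The allele of each read
#' is drawn from the subset's fraction vector, reweighted by any per-MID
#' bias and renormalized. The emission log records the true allele of every
#' read, giving exact ground truth for pipeline validation.
#'
#' @param truth a [ground_truth].
#' @param subset subset id present in `truth$subset_profiles`.
#' @param n_reads_per_mid reads emitted per MID replicate.
#' @param mids data.frame of two rows (`tag_id`, `tag_sequence`): the two
#'   replicate MID tags for this subset.
#' @param primer_fwd,primer_rev primer sequences.
#' @param seed integer seed (defaults to the truth's seed).
#' @return list of class `sim_reads` with `reads` (data.frame `read_id`,
#'   `sequence`) and `emission` (data.frame `read_id`, `subset`, `mid`,
#'   `true_allele`).
#' @export
simulate_subset_reads <- function(truth, subset, n_reads_per_mid = 1000,
                                  mids, primer_fwd = default_primers()$fwd,
                                  primer_rev = default_primers()$rev,
                                  seed = truth$seed) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!subset %in% names(truth$subset_profiles)) {
    stop("unknown subset: ", sQuote(subset))
  }
  simulate_reads_from_profile(truth, truth$subset_profiles[[subset]], subset,
                              n_reads_per_mid, mids, primer_fwd, primer_rev,
                              seed)
}

#' Composition-weighted PBMC mixture profile
#'
#' The expected whole-PBMC fraction vector: the composition-weighted sum of
#' the per-subset profiles, renormalized to sum to 1.
#'
#' @param subset_profiles named list of per-subset fraction vectors.
#' @param composition named numeric vector of subset fractions of PBMC.
#' @return named numeric vector over the union of alleles.
#' @export
mixture_profile <- function(subset_profiles, composition) {
  if (!length(composition) || sum(composition) <= 0) {
    stop("composition must have positive total")
  }
  subsets <- names(composition)
  missing <- setdiff(subsets, names(subset_profiles))
  if (length(missing)) {
    stop("composition names subset(s) without a profile: ",
         paste(sQuote(missing), collapse = ", "))
  }
  alleles <- unique(unlist(lapply(subset_profiles[subsets], names)))
  mix <- stats::setNames(numeric(length(alleles)), alleles)
  for (s in subsets) {
    p <- subset_profiles[[s]]
    mix[names(p)] <- mix[names(p)] + composition[[s]] * p
  }
  mix / sum(mix)
}

#' Simulate dual-MID amplicon reads for whole PBMC
#'
#' PBMC reads are drawn from the composition-weighted mixture of the subset
#' profiles ([mixture_profile()]), so an allele present at fraction f only
#' in a subset contributing fraction c of PBMC appears at about f*c in the
#' PBMC profile.
#'
#' @inheritParams simulate_subset_reads
#' @return as [simulate_subset_reads()], with subset label `"PBMC"`.
#' @export
simulate_pbmc <- function(truth, n_reads_per_mid = 1000, mids,
                          primer_fwd = default_primers()$fwd,
                          primer_rev = default_primers()$rev,
                          seed = truth$seed) {
  stopifnot(inherits(truth, "ground_truth"))
  if (is.null(truth$composition)) stop("truth has no composition")
  mix <- mixture_profile(truth$subset_profiles, truth$composition)
  simulate_reads_from_profile(truth, mix, "PBMC", n_reads_per_mid, mids,
                              primer_fwd, primer_rev, seed)
}

#' Aggregate an emission log to per-(subset, MID, allele) counts
#'
#' @param emission the `emission` data.frame of a `sim_reads` object (or
#'   several rbind-ed together).
#' @return data.frame with columns `subset`, `mid`, `allele`, `count`.
#' @export
emission_counts <- function(emission) {
  agg <- stats::aggregate(list(count = rep(1L, nrow(emission))),
                          by = list(subset = emission$subset,
                                    mid = emission$mid,
                                    allele = emission$true_allele),
                          FUN = sum)
  agg <- agg[order(agg$subset, agg$mid, agg$allele), ]
  rownames(agg) <- NULL
  agg[, c("subset", "mid", "allele", "count")]
}

#' Write simulated reads to FASTA
#'
#' @param sim a `sim_reads` object (or any data.frame with `read_id` and
#'   `sequence` columns).
#' @param path output FASTA path.
#' @export
write_reads_fasta <- function(sim, path) {
  reads <- if (inherits(sim, "sim_reads")) sim$reads else sim
  if (is.null(reads$sequence) || is.null(reads$read_id)) {
    stop("need a sim_reads object or a data.frame with read_id and sequence")
  }
  ss <- Biostrings::DNAStringSet(stats::setNames(reads$sequence,
                                                 reads$read_id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read amplicon reads from FASTA/FASTQ
#'
#' @param path input path; format is taken from the extension (`.fastq` /
#'   `.fq` read as FASTQ, anything else as FASTA).
#' @return data.frame with columns `read_id`, `sequence`.
#' @export
read_reads <- function(path) {
  fastq <- grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE)
  ss <- if (fastq) Biostrings::readDNAStringSet(path, format = "fastq")
        else Biostrings::readDNAStringSet(path)
  data.frame(read_id = sub("\\s.*$", "", names(ss)),
             sequence = as.character(ss), stringsAsFactors = FALSE,
             row.names = NULL)
}

AA_20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Simulate an Edman-degradation picomole table
#'
#' Builds a cycle-by-amino-acid picomole table in which designated residues
#' rise over the previous cycle by a specified fold (>= 3.5 dominant,
#' 2.5-3.5 strong, 2.0-2.5 weak) while background residues decay slightly
#' (fold 0.9), then applies multiplicative lognormal noise. Construction
#' fails if the noise flips any planted residue out of its fold class, so a
#' returned table always round-trips through [build_motif()].
#'
#' @param motif data.frame with columns `cycle` (2..n_cycles), `residue`
#'   (one-letter amino acid) and `fold` (the planted fold increase over the
#'   previous cycle).
#' @param n_cycles number of sequencing cycles (>= 2; 14 in a typical run).
#' @param baseline_picomoles cycle-1 yield for every residue.
#' @param noise_cv coefficient of variation of the lognormal noise.
#' @param seed integer seed.
#' @return numeric matrix of class `edman_table` (rows = cycles, columns =
#'   the 20 amino acids).
#' @export
simulate_edman_table <- function(motif, n_cycles = 14,
                                 baseline_picomoles = 10, noise_cv = 0.05,
                                 seed = 1L) {
  if (n_cycles < 2) stop("n_cycles must be >= 2")
  if (baseline_picomoles <= 0) stop("baseline_picomoles must be positive")
  if (noise_cv < 0 || noise_cv > 0.2) stop("noise_cv must be in [0, 0.2]")
  stopifnot(all(c("cycle", "residue", "fold") %in% names(motif)))
  if (any(motif$cycle < 2 | motif$cycle > n_cycles)) {
    stop("motif cycles must be in 2..n_cycles")
  }
  if (any(!motif$residue %in% AA_20)) stop("unknown residue in motif spec")
  if (any(motif$fold < 0)) stop("folds must be non-negative")
  if (anyDuplicated(motif[, c("cycle", "residue")])) {
    stop("duplicate (cycle, residue) in motif spec")
  }
  background_fold <- 0.9
  m <- matrix(0, nrow = n_cycles, ncol = length(AA_20),
              dimnames = list(cycle = seq_len(n_cycles), residue = AA_20))
  m[1, ] <- baseline_picomoles
  for (k in 2:n_cycles) {
    folds <- rep(background_fold, length(AA_20))
    names(folds) <- AA_20
    sel <- motif$cycle == k
    folds[motif$residue[sel]] <- motif$fold[sel]
    m[k, ] <- m[k - 1, ] * folds
  }
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- with_seed(derive_seed(seed, "edman"),
                       matrix(exp(stats::rnorm(length(m), 0, sdlog)),
                              nrow = n_cycles))
    m <- m * noise
  }
  out <- structure(m, class = "edman_table", seed = as.integer(seed))
  planted_class <- classify_residue(motif$fold)
  observed <- fold_increase(out)
  obs_class <- classify_residue(observed[cbind(match(motif$cycle,
                                                     rownames(observed)),
                                               match(motif$residue, AA_20))])
  if (!identical(planted_class, obs_class)) {
    stop("noise_cv = ", noise_cv, " violates the planted fold-class ",
         "separations for this seed; lower it")
  }
  out
}

#' Read an Edman cycle table from tab-delimited text
#'
#' Expected layout: a `cycle` column followed by one column per amino acid
#' (one-letter codes), picomoles in the cells.
#'
#' @param path path to the tab-delimited file.
#' @return an `edman_table` matrix.
#' @export
read_edman_table <- function(path) {
  x <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"cycle" %in% names(x)) stop("Edman table needs a 'cycle' column")
  aa <- setdiff(names(x), "cycle")
  m <- as.matrix(x[, aa, drop = FALSE])
  rownames(m) <- x$cycle
  as_edman_table(m)
}

#' Validate/construct an Edman cycle table
#'
#' @param m numeric matrix, rows = cycles (>= 2), columns = amino acids,
#'   all values >= 0.
#' @return the matrix with class `edman_table`.
#' @export
as_edman_table <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("an Edman table needs at least 2 cycles")
  if (any(m < 0)) stop("picomole values must be >= 0")
  if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
  structure(m, class = "edman_table")
}

#' Simulate a flow-cytometry MFI table for fluorescent-peptide staining
#'
#' For every (animal, subset) three stains are emitted: `no_peptide`
#' (background, MFI = baseline), the test peptide (MFI = baseline x true
#' relative level) and `pan_MHC` (the W6/32 total class I signal).
#' Multiplicative lognormal noise with the given CV is applied to every
#' MFI; at `noise_cv = 0` the table is exact, so a planted level of 2.0
#' yields a downstream relative expression of exactly 200%.
#'
#' @param expression data.frame with columns `animal`, `subset`, `level`
#'   (true relative level, > 0) and optionally `haplotype`.
#' @param mfi_no_peptide positive background MFI.
#' @param noise_cv coefficient of variation of the lognormal noise.
#' @param seed integer seed.
#' @param peptide stain label for the test peptide (e.g. `"fGR9"`).
#' @param w632_mfi pan-MHC MFI scale: a single number or a named vector by
#'   subset.
#' @return data.frame of class `mfi_table` with columns `animal`,
#'   `haplotype`, `subset`, `stain`, `mfi`.
#' @export
simulate_mfi_table <- function(expression, mfi_no_peptide = 100,
                               noise_cv = 0.05, seed = 1L,
                               peptide = "fGR9", w632_mfi = 2000) {
  stopifnot(all(c("animal", "subset", "level") %in% names(expression)))
  if (mfi_no_peptide <= 0) stop("mfi_no_peptide must be positive")
  if (any(expression$level <= 0)) stop("true levels must be positive")
  if (any(w632_mfi <= 0)) stop("w632_mfi must be positive")
  hap <- if ("haplotype" %in% names(expression)) expression$haplotype
         else rep(NA_character_, nrow(expression))
  w632 <- if (length(w632_mfi) == 1) rep(w632_mfi, nrow(expression))
          else unname(w632_mfi[expression$subset])
  base <- data.frame(animal = rep(expression$animal, each = 3),
                     haplotype = rep(hap, each = 3),
                     subset = rep(expression$subset, each = 3),
                     stain = rep(c("no_peptide", peptide, "pan_MHC"),
                                 nrow(expression)),
                     mfi = as.vector(rbind(mfi_no_peptide,
                                           mfi_no_peptide * expression$level,
                                           w632)),
                     stringsAsFactors = FALSE)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    base$mfi <- base$mfi * with_seed(derive_seed(seed, "mfi"),
                                     exp(stats::rnorm(nrow(base), 0, sdlog)))
  }
  structure(base, class = c("mfi_table", "data.frame"), seed = as.integer(seed))
}
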