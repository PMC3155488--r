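#' Find positions that discriminate one sequence group from another
#'
#' Over a set of pre-aligned, equal-length sequences, returns every
#' position where (a) all sequences of the differential group share one
#' state and (b) no sequence of the comparison group carries that state —
#' the "only present in the differentially expressed alleles" criterion.
#' Also returns the comparison-group consensus (per-position majority,
#' ties broken alphabetically) for dot-matrix style reporting.
#'
#' @param group_diff character vector of sequences sharing the phenotype
#'   (e.g. CD14-dominant alleles).
#' @param group_other character vector of comparison sequences (e.g. all
#'   other class I B alleles). Both groups must be non-empty and all
#'   sequences equal length.
#' @return list with `positions` (1-based, increasing), `states` (the
#'   discriminative group's base at each position) and `other_consensus`
#'   (string).
#' @export
find_discriminative_positions <- function(group_diff, group_other) {
  if (!length(group_diff) || !length(group_other)) {
    stop("both groups must be non-empty")
  }
  L <- unique(nchar(c(group_diff, group_other)))
  if (length(L) != 1) stop("all sequences must have equal length")
  D <- seq_char_matrix(group_diff)
  O <- seq_char_matrix(group_other)
  positions <- integer(0)
  states <- character(0)
  consensus <- character(L)
  for (j in seq_len(L)) {
    tab <- table(O[, j])
    consensus[j] <- sort(names(tab)[tab == max(tab)])[1]
    dj <- unique(D[, j])
    if (length(dj) == 1 && !any(O[, j] == dj)) {
      positions <- c(positions, j)
      states <- c(states, dj)
    }
  }
  list(positions = positions, states = states,
       other_consensus = paste(consensus, collapse = ""))
}

#' Translate a coding DNA sequence
#'
#' Standard genetic code; stop codons are rendered as `"*"`. Length must be
#' a multiple of 3 and only A/C/G/T is accepted.
#'
#' @param nt_sequence character vector of DNA sequences.
#' @param three_letter if TRUE return hyphen-joined three-letter codes
#'   (e.g. `"Ala-Ala-Asp-Met"`) instead of one-letter strings.
#' @return character vector of amino acid sequences.
#' @export
translate_dna <- function(nt_sequence, three_letter = FALSE) {
  nt_sequence <- toupper(nt_sequence)
  if (any(nchar(nt_sequence) %% 3 != 0)) {
    stop("sequence length must be a multiple of 3")
  }
  if (any(!is_acgt(nt_sequence))) {
    stop("only A/C/G/T characters can be translated")
  }
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(nt_sequence), no.init.codon = TRUE))
  if (!three_letter) return(aa)
  vapply(strsplit(aa, "", fixed = TRUE), function(x) {
    paste(AA_THREE[x], collapse = "-")
  }, character(1))
}

AA_THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
              "*" = "***")

#' Classify nucleotide substitutions within codons
#'
#' Compares two equal-length, codon-aligned windows codon by codon. All
#' nucleotide differences inside a codon are labeled synonymous when the
#' encoded amino acid is unchanged and nonsynonymous when it changed
#' (multi-hit codons are labeled jointly: two nucleotide changes producing
#' one amino acid replacement count as two nonsynonymous differences).
#'
#' @param reference_window,derived_window equal-length DNA strings whose
#'   length is a multiple of 3.
#' @param first_codon codon number assigned to the first codon of the
#'   window (mature-protein numbering supplied by the user; e.g. 159 for a
#'   window whose fourth codon is codon 162).
#' @return list with `per_codon` (data.frame `codon`, `ref_codon`,
#'   `derived_codon`, `ref_aa`, `derived_aa`, `n_nt_diff`,
#'   `classification` in identical/synonymous/nonsynonymous), `n_syn_nt`
#'   and `n_nonsyn_nt` (nucleotide-level difference counts).
#' @export
classify_substitutions <- function(reference_window, derived_window,
                                   first_codon = 1) {
  reference_window <- toupper(reference_window)
  derived_window <- toupper(derived_window)
  if (nchar(reference_window) != nchar(derived_window)) {
    stop("windows must have equal length")
  }
  if (nchar(reference_window) %% 3 != 0) {
    stop("window length is not reducible to whole codons")
  }
  n_codons <- nchar(reference_window) / 3
  starts <- 3 * (seq_len(n_codons) - 1) + 1
  ref_codons <- substring(reference_window, starts, starts + 2)
  der_codons <- substring(derived_window, starts, starts + 2)
  ref_aa <- translate_dna(ref_codons)
  der_aa <- translate_dna(der_codons)
  n_nt_diff <- mapply(str_hamming, ref_codons, der_codons, USE.NAMES = FALSE)
  classification <- ifelse(n_nt_diff == 0, "identical",
                           ifelse(ref_aa == der_aa, "synonymous",
                                  "nonsynonymous"))
  per_codon <- data.frame(
    codon = first_codon + seq_len(n_codons) - 1,
    ref_codon = ref_codons, derived_codon = der_codons,
    ref_aa = ref_aa, derived_aa = der_aa,
    n_nt_diff = as.integer(n_nt_diff),
    classification = classification, stringsAsFactors = FALSE)
  list(per_codon = per_codon,
       n_syn_nt = sum(n_nt_diff[classification == "synonymous"]),
       n_nonsyn_nt = sum(n_nt_diff[classification == "nonsynonymous"]))
}

#' Full discriminative-motif analysis of two allele groups
#'
#' Runs [find_discriminative_positions()] and, on the discriminative-group
#' consensus versus the comparison-group consensus,
#' [classify_substitutions()], returning the combined motif result with a
#' dot-matrix text rendering (matching states printed as a bullet).
#'
#' @inheritParams find_discriminative_positions
#' @param first_codon codon number of the window's first codon.
#' @return list of class `motif_result` combining both analyses, with a
#'   `dot_matrix` character vector for display.
#' @export
motif_table <- function(group_diff, group_other, first_codon = 1) {
  disc <- find_discriminative_positions(group_diff, group_other)
  diff_consensus <- {
    D <- seq_char_matrix(group_diff)
    apply(D, 2, function(col) {
      tab <- table(col)
      sort(names(tab)[tab == max(tab)])[1]
    })
  }
  diff_consensus <- paste(diff_consensus, collapse = "")
  subs <- classify_substitutions(disc$other_consensus, diff_consensus,
                                 first_codon)
  structure(c(disc,
              list(diff_consensus = diff_consensus,
                   per_codon = subs$per_codon,
                   n_syn_nt = subs$n_syn_nt,
                   n_nonsyn_nt = subs$n_nonsyn_nt,
                   dot_matrix = render_dot_matrix(disc$other_consensus,
                                                  diff_consensus))),
            class = "motif_result")
}

#' Dot-matrix rendering of a derived sequence against a reference
#'
#' @param reference,derived equal-length strings (nucleotide windows, or
#'   translations with multiples of 3 handled by the caller).
#' @param match_char character printed where derived matches reference.
#' @return character vector of two display lines.
#' @export
render_dot_matrix <- function(reference, derived, match_char = "•") {
  r <- strsplit(reference, "", fixed = TRUE)[[1]]
  d <- strsplit(derived, "", fixed = TRUE)[[1]]
  if (length(r) != length(d)) stop("sequences must have equal length")
  shown <- ifelse(d == r, match_char, d)
  c(paste(r, collapse = " "), paste(shown, collapse = " "))
}

#' @export
print.motif_result <- function(x, ...) {
  cat("<motif_result> ", length(x$positions), " discriminative position(s)",
      if (length(x$positions)) paste0(" {",
                                      paste(x$positions, collapse = ","),
                                      "}"),
      "; ", x$n_syn_nt, " synonymous / ", x$n_nonsyn_nt,
      " nonsynonymous nt difference(s)\n", sep = "")
  cat(x$dot_matrix, sep = "\n")
  invisible(x)
}

#' Scan a reference for carriers of a sequence motif
#'
#' A sequence carries the motif iff it matches every (position, state)
#' pair; positions are given within the examined window and offset by
#' `window_anchor` into the full sequence. An empty motif matches every
#' sequence.
#'
#' @param reference an [mhc_reference] or named character vector of
#'   sequences.
#' @param positions integer positions within the window.
#' @param states bases required at those positions.
#' @param window_anchor 1-based position in each full sequence where the
#'   window starts.
#' @return list with `carriers` (names), `n_carriers`, `n_total` and
#'   `fraction`.
#' @export
scan_motif <- function(reference, positions, states, window_anchor = 1) {
  seqs <- if (inherits(reference, "mhc_reference")) {
    stats::setNames(reference$sequence, reference$name)
  } else {
    reference
  }
  stopifnot(length(positions) == length(states))
  if (!length(seqs)) stop("empty reference")
  if (length(positions)) {
    abs_pos <- window_anchor + positions - 1
    too_short <- nchar(seqs) < max(abs_pos)
    if (any(too_short)) {
      stop("motif window extends beyond sequence ",
           sQuote(names(seqs)[too_short][1] %||% "<unnamed>"))
    }
    carrier <- rep(TRUE, length(seqs))
    for (i in seq_along(abs_pos)) {
      carrier <- carrier &
        substr(seqs, abs_pos[i], abs_pos[i]) == states[i]
    }
  } else {
    carrier <- rep(TRUE, length(seqs))
  }
  nm <- names(seqs) %||% as.character(seq_along(seqs))
  list(carriers = nm[carrier], n_carriers = sum(carrier),
       n_total = length(seqs), fraction = sum(carrier) / length(seqs))
}

#' Fold increase of each residue over the previous Edman cycle
#'
#' fold(cycle, residue) = picomoles(cycle) / picomoles(cycle - 1). The fold
#' is reported as missing (NA), not infinite, when the prior-round value is
#' below `floor` picomoles.
#'
#' @param table an `edman_table` matrix (rows = cycles, cols = residues).
#' @param floor prior-round picomole floor below which the fold is
#'   undefined (default 0.1 pmol).
#' @return numeric matrix with rows = cycles 2..n.
#' @export
fold_increase <- function(table, floor = 0.1) {
  m <- unclass(table)
  if (nrow(m) < 2) stop("need at least 2 cycles")
  prev <- m[-nrow(m), , drop = FALSE]
  cur <- m[-1, , drop = FALSE]
  folds <- cur / prev
  folds[prev < floor] <- NA_real_
  rownames(folds) <- rownames(m)[-1]
  folds
}

#' Classify an Edman fold increase
#'
#' Thresholds: dominant iff fold >= 3.5; strong iff 2.5 <= fold < 3.5;
#' weak iff 2.0 <= fold < 2.5; none otherwise. Lower bounds are inclusive
#' and upper bounds exclusive, so the classes partition \[0, Inf); a
#' missing fold classifies as none.
#'
#' @param fold numeric vector of fold increases (>= 0 or NA).
#' @return character vector in dominant/strong/weak/none.
#' @export
classify_residue <- function(fold) {
  if (any(!is.na(fold) & fold < 0)) stop("folds must be non-negative")
  out <- rep("none", length(fold))
  out[!is.na(fold) & fold >= 2.0] <- "weak"
  out[!is.na(fold) & fold >= 2.5] <- "strong"
  out[!is.na(fold) & fold >= 3.5] <- "dominant"
  out
}

#' Build a peptide-binding motif from an Edman cycle table
#'
#' Applies [fold_increase()] and [classify_residue()] at every cycle
#' (peptide position). Within each class at a cycle, residues are ordered
#' by descending fold — the binding hierarchy. Anchor positions are the
#' cycles with at least one dominant residue.
#'
#' @param table an `edman_table` matrix.
#' @param floor prior-round picomole floor passed to [fold_increase()].
#' @return object of class `binding_motif`: list with `per_cycle` (named
#'   list of data.frames `residue`, `fold`, `class`, dominant/strong/weak
#'   only) and `anchor_positions` (integer cycles).
#' @export
build_motif <- function(table, floor = 0.1) {
  folds <- fold_increase(table, floor)
  class_order <- c("dominant", "strong", "weak")
  per_cycle <- lapply(rownames(folds), function(k) {
    f <- folds[k, ]
    cl <- classify_residue(f)
    keep <- cl %in% class_order
    df <- data.frame(residue = colnames(folds)[keep],
                     fold = unname(f[keep]),
                     class = cl[keep], stringsAsFactors = FALSE)
    df <- df[order(match(df$class, class_order), -df$fold), ]
    rownames(df) <- NULL
    df
  })
  names(per_cycle) <- rownames(folds)
  anchors <- as.integer(rownames(folds))[
    vapply(per_cycle, function(df) any(df$class == "dominant"), logical(1))]
  structure(list(per_cycle = per_cycle, anchor_positions = anchors),
            class = "binding_motif")
}

#' @export
print.binding_motif <- function(x, ...) {
  cat("<binding_motif> anchors at cycle(s): ",
      if (length(x$anchor_positions))
        paste(x$anchor_positions, collapse = ", ") else "none", "\n",
      sep = "")
  for (k in names(x$per_cycle)) {
    df <- x$per_cycle[[k]]
    if (!nrow(df)) next
    cat("  cycle ", k, ": ",
        paste0(df$residue, " (", df$class, ", ",
               sprintf("%.1f", df$fold), "x)", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
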