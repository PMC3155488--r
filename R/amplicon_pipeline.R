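#' Bin reads by their 10-bp MID tag
#'
#' A read joins the bin of tag t iff the Hamming distance between its 10-bp
#' prefix and t is at most `max_tag_mismatch` and strictly smaller than its
#' distance to every other tag; ties and non-matches go to the unassigned
#' pool. Binned reads are returned with the MID prefix stripped, ready for
#' primer trimming. Bins are disjoint and counts are conserved.
#'
#' @param reads data.frame with columns `read_id`, `sequence`.
#' @param tag_set data.frame with columns `tag_id`, `tag_sequence` (10-bp,
#'   pairwise distinct; anything else is a configuration error).
#' @param max_tag_mismatch maximum prefix mismatches tolerated (default 0:
#'   exact MID match).
#' @return list with `bins` (named list of read data.frames, MID stripped)
#'   and `unassigned` (read data.frame, original sequences).
#' @export
demultiplex <- function(reads, tag_set, max_tag_mismatch = 0) {
  tag_set <- validate_mid_table(tag_set)
  n <- nrow(reads)
  assigned_tag <- rep(NA_character_, n)
  long_enough <- nchar(reads$sequence) >= 10
  if (any(long_enough)) {
    prefixes <- substr(reads$sequence[long_enough], 1, 10)
    mm <- mismatch_matrix(prefixes, tag_set$tag_sequence)
    best <- apply(mm, 1, min)
    n_best <- rowSums(mm == best)
    which_best <- max.col(-mm, ties.method = "first")
    ok <- best <= max_tag_mismatch & n_best == 1
    assigned_tag[long_enough][ok] <- tag_set$tag_id[which_best[ok]]
  }
  bins <- lapply(stats::setNames(tag_set$tag_id, tag_set$tag_id),
                 function(t) {
    sel <- !is.na(assigned_tag) & assigned_tag == t
    data.frame(read_id = reads$read_id[sel],
               sequence = substring(reads$sequence[sel], 11),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  unassigned <- reads[is.na(assigned_tag), c("read_id", "sequence")]
  rownames(unassigned) <- NULL
  list(bins = bins, unassigned = unassigned)
}

#' Trim primers and extract amplicon inserts
#'
#' Operates on MID-stripped reads: verifies the forward primer at the 5'
#' end and the reverse complement of the reverse primer at the 3' end (each
#' within `max_primer_mismatch` mismatches at its anchored position),
#' extracts the insert between them, and rejects reads whose insert length
#' deviates from `expected_insert_length` by more than `length_tolerance`.
#' Rejection is a return state, never an error; reasons are `contains_N`,
#' `no_fwd_primer`, `no_rev_primer`, `bad_length`.
#'
#' @param reads data.frame with columns `read_id`, `sequence` (MID already
#'   stripped).
#' @param primer_fwd,primer_rev primer sequences (as handed to the PCR, the
#'   reverse primer is given 5'->3' on the opposite strand).
#' @param expected_insert_length expected insert length in bp (190 for the
#'   short macaque class I amplicon, 581 for the human one).
#' @param length_tolerance allowed absolute deviation from the expected
#'   insert length.
#' @param max_primer_mismatch mismatches tolerated within each primer.
#' @return data.frame with columns `read_id`, `insert`, `accepted`,
#'   `reason` (NA when accepted).
#' @export
trim_reads <- function(reads, primer_fwd, primer_rev,
                       expected_insert_length, length_tolerance = 0,
                       max_primer_mismatch = 2) {
  n <- nrow(reads)
  nf <- nchar(primer_fwd)
  rc_rev <- revcomp(primer_rev)
  nr <- nchar(rc_rev)
  insert <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  seqs <- reads$sequence
  L <- nchar(seqs)

  has_n <- grepl("N", seqs, fixed = TRUE)
  reason[has_n] <- "contains_N"

  todo <- which(!has_n)
  fwd_ok <- logical(n)
  long <- todo[L[todo] >= nf]
  if (length(long)) {
    head_mm <- vapply(substr(seqs[long], 1, nf), str_hamming, integer(1),
                      b = primer_fwd, USE.NAMES = FALSE)
    fwd_ok[long] <- head_mm <= max_primer_mismatch
  }
  reason[!has_n & !fwd_ok] <- "no_fwd_primer"

  todo <- which(is.na(reason))
  rev_ok <- logical(n)
  long <- todo[L[todo] >= nf + nr]
  if (length(long)) {
    tail_mm <- vapply(substr(seqs[long], L[long] - nr + 1, L[long]),
                      str_hamming, integer(1), b = rc_rev,
                      USE.NAMES = FALSE)
    rev_ok[long] <- tail_mm <= max_primer_mismatch
  }
  reason[is.na(reason) & !rev_ok] <- "no_rev_primer"

  todo <- which(is.na(reason))
  if (length(todo)) {
    ins <- substr(seqs[todo], nf + 1, L[todo] - nr)
    good_len <- abs(nchar(ins) - expected_insert_length) <= length_tolerance
    insert[todo[good_len]] <- ins[good_len]
    reason[todo[!good_len]] <- "bad_length"
  }

  data.frame(read_id = reads$read_id, insert = insert,
             accepted = is.na(reason), reason = reason,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Collapse inserts into 100%-identity contigs
#'
#' Two inserts share a contig iff their sequences are byte-identical.
#' Output is sorted by descending read count, then lexicographically by
#' sequence.
#'
#' @param inserts character vector of insert sequences (optionally named by
#'   read id), or the output of [trim_reads()] (accepted rows are used).
#' @return data.frame with columns `insert_sequence`, `read_count`,
#'   `member_ids` (list column of read ids).
#' @export
collapse_identical <- function(inserts) {
  if (is.data.frame(inserts)) {
    keep <- inserts$accepted
    ids <- inserts$read_id[keep]
    inserts <- stats::setNames(inserts$insert[keep], ids)
  }
  if (!length(inserts)) {
    return(data.frame(insert_sequence = character(0),
                      read_count = integer(0),
                      member_ids = I(list())))
  }
  ids <- names(inserts) %||% as.character(seq_along(inserts))
  if (is.null(names(inserts))) names(inserts) <- ids
  groups <- split(ids, unname(inserts))
  out <- data.frame(insert_sequence = names(groups),
                    read_count = lengths(groups),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$member_ids <- I(unname(groups))
  ord <- order(-out$read_count, out$insert_sequence)
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}

# Best ungapped mismatch count between an insert and one reference amplicon
# of possibly different length: slide the shorter along the longer.
best_overlap_mismatch <- function(a, b) {
  if (nchar(a) == nchar(b)) return(str_hamming(a, b))
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  la <- nchar(a); lb <- nchar(b)
  best <- la
  for (off in 0:(lb - la)) {
    d <- str_hamming(a, substr(b, off + 1, off + la))
    if (d < best) best <- d
  }
  best
}

#' Assign contigs to reference alleles by bounded mismatch count
#'
#' Each contig is compared (ungapped mismatch count) to every reference
#' amplicon. Among references within `max_mismatch`, the best-scoring
#' allele(s) win: a unique best gives a single-allele call; several equally
#' best alleles all in one lineage give a two-digit lineage-group call;
#' equally best alleles across lineages give an ambiguous call; no
#' reference within the ceiling leaves the contig unassigned.
#'
#' @param clusters output of [collapse_identical()], or a character vector
#'   of insert sequences (each counted as one read).
#' @param reference an [mhc_reference] (must be non-empty).
#' @param max_mismatch mismatch ceiling (default 2 for the 190 bp amplicon).
#' @return data.frame with columns `insert_sequence`, `read_count`,
#'   `assigned_type` (`"allele"`, `"lineage"`, `"ambiguous"`,
#'   `"unassigned"`), `assigned` (allele name, lineage name, or
#'   semicolon-joined ambiguous set; NA when unassigned), `mismatches`
#'   (best score found), `tie_size` (number of equally best references).
#' @export
assign_clusters <- function(clusters, reference, max_mismatch = 2) {
  if (!inherits(reference, "mhc_reference") || nrow(reference) == 0) {
    stop("reference must be a non-empty mhc_reference")
  }
  if (is.character(clusters)) {
    clusters <- data.frame(insert_sequence = clusters,
                           read_count = 1L, stringsAsFactors = FALSE)
  }
  amp <- amplicon_sequences(reference)
  amp_chars <- strsplit(unname(amp), "", fixed = TRUE)
  amp_len <- nchar(amp)
  k <- nrow(clusters)
  m <- length(amp)
  assigned <- rep(NA_character_, k)
  assigned_type <- rep("unassigned", k)
  mismatches <- integer(k)
  tie_size <- integer(k)
  for (i in seq_len(k)) {
    ins <- clusters$insert_sequence[i]
    li <- nchar(ins)
    d <- integer(m)
    same <- amp_len == li
    if (any(same)) {
      ichars <- strsplit(ins, "", fixed = TRUE)[[1]]
      idx <- which(same)
      A <- matrix(unlist(amp_chars[idx], use.names = FALSE),
                  nrow = length(idx), ncol = li, byrow = TRUE)
      d[idx] <- as.integer(rowSums(A != matrix(ichars, nrow = length(idx),
                                               ncol = li, byrow = TRUE)))
    }
    for (j in which(!same)) d[j] <- best_overlap_mismatch(ins, amp[j])
    best <- min(d)
    mismatches[i] <- best
    cand <- which(d == best)
    tie_size[i] <- length(cand)
    if (best <= max_mismatch) {
      if (length(cand) == 1) {
        assigned[i] <- reference$name[cand]
        assigned_type[i] <- "allele"
      } else {
        lin <- unique(reference$lineage[cand])
        if (length(lin) == 1) {
          assigned[i] <- lin
          assigned_type[i] <- "lineage"
        } else {
          assigned[i] <- paste(sort(reference$name[cand]), collapse = ";")
          assigned_type[i] <- "ambiguous"
        }
      }
    }
  }
  data.frame(insert_sequence = clusters$insert_sequence,
             read_count = clusters$read_count,
             assigned_type = assigned_type, assigned = assigned,
             mismatches = mismatches, tie_size = tie_size,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build a per-(subset, MID, allele) count table
#'
#' Counts are read-weighted: each contig contributes its full read count to
#' its assigned allele or lineage group. Ambiguous and unassigned reads are
#' tallied separately and excluded from the allele counts.
#'
#' @param assignments data.frame with columns `subset`, `mid`,
#'   `assigned_type`, `assigned`, `read_count` (the per-bin outputs of
#'   [assign_clusters()] with subset/MID labels attached).
#' @return object of class `count_table`: a list with `counts` (data.frame
#'   `subset`, `mid`, `allele`, `count`) and `other` (data.frame `subset`,
#'   `mid`, `category`, `count` for ambiguous/unassigned reads).
#' @export
count_table <- function(assignments) {
  need <- c("subset", "mid", "assigned_type", "assigned", "read_count")
  stopifnot(all(need %in% names(assignments)))
  ok <- assignments$assigned_type %in% c("allele", "lineage")
  counts <- if (any(ok)) {
    agg <- stats::aggregate(
      list(count = assignments$read_count[ok]),
      by = list(subset = assignments$subset[ok],
                mid = assignments$mid[ok],
                allele = assignments$assigned[ok]),
      FUN = sum)
    agg[order(agg$subset, agg$mid, agg$allele), ]
  } else {
    data.frame(subset = character(0), mid = character(0),
               allele = character(0), count = integer(0))
  }
  rownames(counts) <- NULL
  other <- if (any(!ok)) {
    cat2 <- ifelse(assignments$assigned_type[!ok] == "ambiguous",
                   "ambiguous", "unassigned")
    agg <- stats::aggregate(
      list(count = assignments$read_count[!ok]),
      by = list(subset = assignments$subset[!ok],
                mid = assignments$mid[!ok], category = cat2),
      FUN = sum)
    agg[order(agg$subset, agg$mid, agg$category), ]
  } else {
    data.frame(subset = character(0), mid = character(0),
               category = character(0), count = integer(0))
  }
  rownames(other) <- NULL
  structure(list(counts = counts[, c("subset", "mid", "allele", "count")],
                 other = other),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("<count_table> ", sum(x$counts$count), " assigned read(s) over ",
      length(unique(x$counts$subset)), " subset(s); ",
      sum(x$other$count), " ambiguous/unassigned\n", sep = "")
  invisible(x)
}

#' Run the full read-to-counts amplicon pipeline
#'
#' Demultiplexes by MID, trims primers, collapses to 100%-identity contigs
#' per bin, assigns contigs to the reference, and tabulates read-weighted
#' counts per (subset, MID, allele-or-group).
#'
#' @param reads data.frame with columns `read_id`, `sequence`.
#' @param reference an [mhc_reference].
#' @param mid_table data.frame `tag_id`, `tag_sequence`.
#' @param subset_map data.frame `tag_id`, `subset` mapping each MID to the
#'   leukocyte subset it amplified (two MIDs per subset in the dual-MID
#'   design).
#' @param primer_fwd,primer_rev primer sequences.
#' @param expected_insert_length,length_tolerance,max_primer_mismatch see
#'   [trim_reads()].
#' @param max_tag_mismatch see [demultiplex()].
#' @param max_mismatch see [assign_clusters()].
#' @return list of class `amplicon_run` with elements `count_table`,
#'   `assignments` (per-contig calls with subset/MID), `rejects`
#'   (data.frame `read_id`, `stage`, `reason`) and `log` (per-stage read
#'   tallies).
#' @export
run_amplicon_pipeline <- function(reads, reference, mid_table, subset_map,
                                  primer_fwd = default_primers()$fwd,
                                  primer_rev = default_primers()$rev,
                                  expected_insert_length = 190,
                                  length_tolerance = 0,
                                  max_tag_mismatch = 0, max_mismatch = 2,
                                  max_primer_mismatch = 2) {
  stopifnot(all(c("tag_id", "subset") %in% names(subset_map)))
  dm <- demultiplex(reads, mid_table, max_tag_mismatch)
  rejects <- list()
  if (nrow(dm$unassigned)) {
    rejects[["mid"]] <- data.frame(read_id = dm$unassigned$read_id,
                                   stage = "demultiplex",
                                   reason = "no_mid_match",
                                   stringsAsFactors = FALSE)
  }
  assignments <- list()
  n_trimmed <- 0L
  for (tag in names(dm$bins)) {
    bin <- dm$bins[[tag]]
    if (!nrow(bin)) next
    subset <- subset_map$subset[match(tag, subset_map$tag_id)]
    if (is.na(subset)) {
      rejects[[paste0("map_", tag)]] <-
        data.frame(read_id = bin$read_id, stage = "subset_map",
                   reason = "unmapped_mid", stringsAsFactors = FALSE)
      next
    }
    tr <- trim_reads(bin, primer_fwd, primer_rev, expected_insert_length,
                     length_tolerance, max_primer_mismatch)
    if (any(!tr$accepted)) {
      rejects[[paste0("trim_", tag)]] <-
        data.frame(read_id = tr$read_id[!tr$accepted], stage = "trim",
                   reason = tr$reason[!tr$accepted],
                   stringsAsFactors = FALSE)
    }
    n_trimmed <- n_trimmed + sum(tr$accepted)
    clusters <- collapse_identical(tr)
    if (!nrow(clusters)) next
    asg <- assign_clusters(clusters, reference, max_mismatch)
    asg$subset <- subset
    asg$mid <- tag
    assignments[[tag]] <- asg
  }
  assignments <- if (length(assignments)) {
    do.call(rbind, c(assignments, list(make.row.names = FALSE)))
  } else {
    data.frame(insert_sequence = character(0), read_count = integer(0),
               assigned_type = character(0), assigned = character(0),
               mismatches = integer(0), tie_size = integer(0),
               subset = character(0), mid = character(0))
  }
  ct <- count_table(assignments)
  rejects <- if (length(rejects)) {
    do.call(rbind, c(rejects, list(make.row.names = FALSE)))
  } else {
    data.frame(read_id = character(0), stage = character(0),
               reason = character(0))
  }
  log <- data.frame(
    stage = c("input", "demultiplexed", "trimmed", "assigned",
              "ambiguous_or_unassigned"),
    reads = c(nrow(reads), nrow(reads) - nrow(dm$unassigned), n_trimmed,
              sum(ct$counts$count), sum(ct$other$count)))
  structure(list(count_table = ct, assignments = assignments,
                 rejects = rejects, log = log),
            class = "amplicon_run")
}

#' @export
print.amplicon_run <- function(x, ...) {
  cat("<amplicon_run>\n")
  print(x$log, row.names = FALSE)
  invisible(x)
}
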