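#' Parse MHC class I allele nomenclature
#'
#' Splits names such as `"Mafa-B*134:02"`, `"HLA-C*04:01"` or the legacy
#' `"Mamu-B*072 g"` into species prefix, locus, allele-group and protein
#' fields. A trailing `" g"` (legacy lineage-group marker) is collapsed into
#' the group token, so `"Mamu-B*072 g"` and `"Mamu-B*072g"` are equivalent.
#'
#' @param name character vector of allele names.
#' @return data.frame with columns `name`, `locus` (e.g. `"Mafa-B"`),
#'   `group` and `lineage` (two-digit truncation, e.g. `"Mafa-B*134"`).
#' @export
parse_allele_name <- function(name) {
  pat <- "^([A-Za-z][A-Za-z0-9]*)-([A-Za-z][A-Za-z0-9]*)\\*([0-9]+)( ?g)?(:[0-9A-Za-z]+(:[0-9A-Za-z]+)*)?$"
  ok <- grepl(pat, name)
  if (any(!ok)) {
    stop("unparsable allele name(s): ",
         paste(sQuote(name[!ok]), collapse = ", "))
  }
  prefix <- sub(pat, "\\1", name)
  locus <- sub(pat, "\\2", name)
  group <- sub(pat, "\\3", name)
  gflag <- sub(pat, "\\4", name)
  group <- ifelse(nzchar(gflag), paste0(group, "g"), group)
  data.frame(
    name = name,
    locus = paste0(prefix, "-", locus),
    group = group,
    lineage = paste0(prefix, "-", locus, "*", group),
    stringsAsFactors = FALSE
  )
}

#' Two-digit (allele-group) lineage of an MHC allele name
#'
#' Truncates an allele name to the lineage level used when a short amplicon
#' cannot distinguish protein-level variants, e.g. `"Mafa-B*134:02"` becomes
#' `"Mafa-B*134"`. Idempotent: applying it to a lineage returns the lineage.
#'
#' @param name character vector of allele or lineage names.
#' @return character vector of lineage names.
#' @examples
#' lineage_of("Mafa-B*134:02") # "Mafa-B*134"
#' lineage_of("HLA-C*04:01")   # "HLA-C*04"
#' @export
lineage_of <- function(name) {
  parse_allele_name(name)$lineage
}

#' Construct a reference of MHC class I allele sequences
#'
#' @param name character vector of allele names (MHC nomenclature).
#' @param sequence character vector of cDNA sequences (A/C/G/T; case
#'   insensitive, stored uppercase).
#' @param window_start,window_end optional 1-based inclusive coordinates of
#'   the amplified region within each sequence (NA = whole sequence).
#' @return an object of class `mhc_reference` (a data.frame with columns
#'   `name`, `locus`, `lineage`, `sequence`, `window_start`, `window_end`).
#' @export
mhc_reference <- function(name, sequence, window_start = NA_integer_,
                          window_end = NA_integer_) {
  if (length(name) != length(sequence)) {
    stop("name and sequence must have the same length")
  }
  if (anyDuplicated(name)) {
    stop("duplicate allele name(s) in reference: ",
         paste(sQuote(unique(name[duplicated(name)])), collapse = ", "))
  }
  sequence <- toupper(sequence)
  if (any(!nzchar(sequence))) {
    stop("empty sequence for record ",
         sQuote(name[!nzchar(sequence)][1]))
  }
  bad <- first_non_acgt(sequence)
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    stop("non-ACGT character in record ", sQuote(name[i]),
         " at position ", bad[i])
  }
  parsed <- parse_allele_name(name)
  window_start <- rep_len(as.integer(window_start), length(name))
  window_end <- rep_len(as.integer(window_end), length(name))
  has_win <- !is.na(window_start) | !is.na(window_end)
  if (any(has_win)) {
    ws <- window_start[has_win]
    we <- window_end[has_win]
    if (any(is.na(ws) | is.na(we)) ||
        any(ws < 1 | we < ws | we > nchar(sequence[has_win]))) {
      stop("invalid amplicon window: need 1 <= start <= end <= sequence length")
    }
  }
  ref <- data.frame(
    name = name,
    locus = parsed$locus,
    lineage = parsed$lineage,
    sequence = sequence,
    window_start = window_start,
    window_end = window_end,
    stringsAsFactors = FALSE
  )
  class(ref) <- c("mhc_reference", "data.frame")
  ref
}

#' @export
print.mhc_reference <- function(x, ...) {
  cat("<mhc_reference> ", nrow(x), " allele(s), ",
      length(unique(x$lineage)), " lineage(s)\n", sep = "")
  print.data.frame(utils::head(data.frame(name = x$name, lineage = x$lineage,
                                          length = nchar(x$sequence)), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Amplicon-region sequences of a reference
#'
#' @param reference an `mhc_reference`.
#' @return named character vector of amplicon sequences (the windowed region
#'   when a window is set, otherwise the full sequence).
#' @export
amplicon_sequences <- function(reference) {
  s <- reference$sequence
  has_win <- !is.na(reference$window_start)
  s[has_win] <- substr(s[has_win], reference$window_start[has_win],
                       reference$window_end[has_win])
  stats::setNames(s, reference$name)
}

#' Read an allele reference from FASTA
#'
#' The allele name is the first whitespace-separated token of each header.
#' Duplicate names and non-ACGT characters are load errors.
#'
#' @param path path to a FASTA file.
#' @return an [mhc_reference].
#' @export
read_allele_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  mhc_reference(nm, as.character(ss))
}

#' Write an allele reference to FASTA
#'
#' Writes full sequences with the allele name as header; a round trip
#' through [read_allele_fasta()] preserves names and sequences.
#'
#' @param reference an `mhc_reference`.
#' @param path output file path.
#' @export
write_allele_fasta <- function(reference, path) {
  ss <- Biostrings::DNAStringSet(stats::setNames(reference$sequence,
                                                 reference$name))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a MID tag table
#'
#' Tab-delimited text with columns `tag_id` and `tag_sequence`; every tag
#' must be a distinct 10-bp A/C/G/T sequence.
#'
#' @param path path to the tab-delimited file.
#' @return data.frame with columns `tag_id`, `tag_sequence`.
#' @export
read_mid_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("tag_id", "tag_sequence") %in% names(x))) {
    stop("MID table needs columns tag_id, tag_sequence")
  }
  validate_mid_table(x[, c("tag_id", "tag_sequence")])
}

validate_mid_table <- function(x) {
  x$tag_sequence <- toupper(x$tag_sequence)
  if (any(nchar(x$tag_sequence) != 10)) {
    stop("MID tags must be exactly 10 bp")
  }
  if (any(!is_acgt(x$tag_sequence))) stop("MID tags must be A/C/G/T only")
  if (anyDuplicated(x$tag_sequence) || anyDuplicated(x$tag_id)) {
    stop("MID tag ids and sequences must be pairwise distinct")
  }
  x
}

#' Read a haplotype-to-allele table
#'
#' Tab-delimited text with columns `haplotype_id` and `alleles`
#' (comma-separated allele names). If a reference is supplied every listed
#' allele must resolve in it.
#'
#' @param path path to the tab-delimited file.
#' @param reference optional `mhc_reference` used to validate allele names.
#' @return named list mapping haplotype id to a character vector of allele
#'   names.
#' @export
read_haplotype_table <- function(path, reference = NULL) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("haplotype_id", "alleles") %in% names(x))) {
    stop("haplotype table needs columns haplotype_id, alleles")
  }
  if (anyDuplicated(x$haplotype_id)) stop("haplotype ids must be unique")
  out <- lapply(strsplit(x$alleles, ","), trimws)
  names(out) <- x$haplotype_id
  if (!is.null(reference)) {
    missing <- setdiff(unlist(out), reference$name)
    if (length(missing)) {
      stop("haplotype allele(s) not in reference: ",
           paste(sQuote(missing), collapse = ", "))
    }
  }
  out
}

#' Read a subset composition table
#'
#' Tab-delimited text with columns `subset` and `fraction`: the fraction of
#' whole PBMC contributed by each leukocyte subset. Fractions must be
#' non-negative and sum to at most 1.
#'
#' @param path path to the tab-delimited file.
#' @return named numeric vector of fractions.
#' @export
read_composition_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("subset", "fraction") %in% names(x))) {
    stop("composition table needs columns subset, fraction")
  }
  frac <- as.numeric(x$fraction)
  if (any(is.na(frac) | frac < 0)) stop("composition fractions must be >= 0")
  if (sum(frac) > 1 + 1e-9) stop("composition fractions must sum to <= 1")
  stats::setNames(frac, x$subset)
}
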