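`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Deterministically derive a sub-seed (< 2^31) from a base seed plus
# arbitrary string/integer labels, so independent simulation calls
# (per subset, per MID) consume independent streams.
derive_seed <- function(seed, ...) {
  h <- as.double(seed) %% 2147483629
  for (p in list(...)) {
    v <- if (is.character(p)) {
      u <- utf8ToInt(p)
      sum(u * seq_along(u))
    } else {
      as.double(p)
    }
    h <- (h * 131 + v) %% 2147483629
  }
  as.integer(h) + 1L
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(length) {
  paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
}

# Hamming distance between two equal-length strings (byte comparison).
str_hamming <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  if (length(ra) != length(rb)) {
    stop("hamming distance requires equal-length strings")
  }
  sum(ra != rb)
}

# Split equal-length strings into an n x L character matrix.
seq_char_matrix <- function(x) {
  L <- unique(nchar(x))
  if (length(L) != 1) stop("sequences must have equal length")
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), ncol = L, byrow = TRUE)
}

# Mismatch counts of each string in `x` (all equal length) against each
# string in `targets` (same length as x's): returns |x| x |targets| matrix.
mismatch_matrix <- function(x, targets) {
  X <- seq_char_matrix(x)
  out <- matrix(NA_integer_, nrow = length(x), ncol = length(targets))
  for (j in seq_along(targets)) {
    tj <- strsplit(targets[j], "", fixed = TRUE)[[1]]
    if (length(tj) != ncol(X)) stop("target length differs from query length")
    out[, j] <- as.integer(rowSums(X != matrix(tj, nrow = nrow(X),
                                               ncol = ncol(X), byrow = TRUE)))
  }
  out
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

is_acgt <- function(x) {
  !grepl("[^ACGT]", x)
}

# First offending character position in a sequence, or NA.
first_non_acgt <- function(x) {
  m <- regexpr("[^ACGT]", x)
  ifelse(m > 0, as.integer(m), NA_integer_)
}
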