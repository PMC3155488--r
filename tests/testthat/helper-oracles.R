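# Independent oracles, written from the textbook formulas and kept separate
# from the package's implementation paths.

oracle_hamming <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  stopifnot(length(x) == length(y))
  sum(x != y)
}

# Chi-square on a 2 x k table: E from row/column marginals,
# X^2 = sum (O-E)^2 / E, df = k - 1, upper-tail p.
oracle_chisq_2xk <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- ncol(tab) - 1
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE), expected = E)
}

oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p_value = 2 * pt(-abs(t), n - 1))
}

oracle_unpaired_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p_value = 2 * pt(-abs(t), df))
}

# One-way repeated measures decomposition by direct sums of squares.
oracle_rm_anova <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_treat <- n * sum((colMeans(m) - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_err <- ss_total - ss_subj - ss_treat
  df_e <- k - 1; df_r <- (k - 1) * (n - 1)
  F <- (ss_treat / df_e) / (ss_err / df_r)
  list(F = F, df_effect = df_e, df_error = df_r,
       p_value = pf(F, df_e, df_r, lower.tail = FALSE),
       ss_subjects = ss_subj, ss_treatment = ss_treat, ss_error = ss_err)
}

# Exhaustive position-by-position discriminative scan (independent loop).
oracle_discriminative <- function(gd, go) {
  L <- nchar(gd[1])
  pos <- integer(0); st <- character(0)
  for (j in seq_len(L)) {
    a <- unique(substr(gd, j, j))
    if (length(a) == 1 && !a %in% substr(go, j, j)) {
      pos <- c(pos, j); st <- c(st, a)
    }
  }
  list(positions = pos, states = st)
}

# Brute-force best-match assignment over a reference (equal lengths).
oracle_assign <- function(insert, ref, max_mismatch) {
  d <- vapply(amplicon_sequences(ref), oracle_hamming, numeric(1),
              a = insert)
  best <- min(d)
  cand <- which(d == best)
  if (best > max_mismatch) return(list(type = "unassigned", name = NA))
  if (length(cand) == 1) {
    return(list(type = "allele", name = ref$name[cand]))
  }
  lin <- unique(ref$lineage[cand])
  if (length(lin) == 1) return(list(type = "lineage", name = lin))
  list(type = "ambiguous", name = paste(sort(ref$name[cand]),
                                        collapse = ";"))
}

# Table 1 worked example: the two printed consensus 12-mers.
CLASS_IB_CONSENSUS <- "GCCGCGGACATG"
CD14_CONSENSUS <- "GCTGCGGATGAG"

# A small dual-subset ground truth used across pipeline tests.
small_truth <- function(seed = 1, error_rate = 0, n_alleles = 5,
                        dominant = 0.45) {
  ref <- make_toy_reference(n_alleles, 190, 5, seed = seed)
  rest <- (1 - dominant) / (n_alleles - 1)
  cd14 <- setNames(c(dominant, rep(rest, n_alleles - 1)), ref$name)
  cd4 <- setNames(c(0, rep(1 / (n_alleles - 1), n_alleles - 1)), ref$name)
  cd4 <- cd4 / sum(cd4)
  ground_truth(ref,
               subset_profiles = list(CD14 = cd14, CD4 = cd4),
               composition = c(CD14 = 0.2, CD4 = 0.8),
               error_rate = error_rate, seed = seed)
}
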