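#' Normalize counts to a per-subset transcript profile
#'
#' Implements the dual-MID normalization: the combined number of reads for
#' each allele from both MID tags divided by the total combined number of
#' reads for both MID tags. Per-MID fractions are also returned for
#' replicate display. Ambiguous and unassigned reads are excluded from both
#' numerator and denominator before this function is reached (they never
#' enter the count table's allele counts).
#'
#' @param ct a [count_table()] object.
#' @param subset subset id to normalize.
#' @return object of class `transcript_profile`: list with `subset`,
#'   `fractions` (named, sorted decreasing), `counts` (named combined read
#'   counts), `n_reads_total`, `per_mid_fractions` (MID x allele matrix)
#'   and `per_mid_counts`.
#' @export
normalize_profile <- function(ct, subset) {
  stopifnot(inherits(ct, "count_table"))
  rows <- ct$counts[ct$counts$subset == subset, , drop = FALSE]
  if (!nrow(rows) || sum(rows$count) == 0) {
    stop("empty subset: no assigned reads for ", sQuote(subset))
  }
  alleles <- sort(unique(rows$allele))
  mids <- sort(unique(rows$mid))
  per_mid_counts <- matrix(0, nrow = length(mids), ncol = length(alleles),
                           dimnames = list(mid = mids, allele = alleles))
  per_mid_counts[cbind(match(rows$mid, mids),
                       match(rows$allele, alleles))] <- rows$count
  counts <- colSums(per_mid_counts)
  total <- sum(counts)
  fractions <- counts / total
  mid_tot <- rowSums(per_mid_counts)
  per_mid_fractions <- per_mid_counts / ifelse(mid_tot > 0, mid_tot, NA)
  ord <- order(-fractions, names(fractions))
  structure(list(subset = subset,
                 fractions = fractions[ord],
                 counts = counts[ord],
                 n_reads_total = total,
                 per_mid_fractions = per_mid_fractions[, ord, drop = FALSE],
                 per_mid_counts = per_mid_counts[, ord, drop = FALSE]),
            class = "transcript_profile")
}

#' @export
print.transcript_profile <- function(x, digits = 3, ...) {
  cat("<transcript_profile> subset ", x$subset, ", ", x$n_reads_total,
      " reads\n", sep = "")
  print(round(x$fractions, digits))
  invisible(x)
}

#' Renormalize a profile after excluding a dominant allele
#'
#' Removes one allele's reads and rescales the remaining fractions to sum
#' to 1, preserving all pairwise ratios — the operation used to look at the
#' rest of the repertoire when one allele (e.g. a CD14-dominant one)
#' swamps the profile. Excluding an allele absent from the profile returns
#' the profile unchanged.
#'
#' @param profile a `transcript_profile`.
#' @param excluded_allele allele (or lineage group) name to remove.
#' @return a `transcript_profile` over the remaining alleles.
#' @export
renormalize_excluding <- function(profile, excluded_allele) {
  stopifnot(inherits(profile, "transcript_profile"))
  if (!excluded_allele %in% names(profile$fractions)) return(profile)
  keep <- setdiff(names(profile$fractions), excluded_allele)
  if (!length(keep)) stop("cannot exclude the only allele in the profile")
  counts <- profile$counts[keep]
  total <- sum(counts)
  if (total == 0) stop("no reads remain after exclusion")
  pmc <- profile$per_mid_counts[, keep, drop = FALSE]
  mid_tot <- rowSums(pmc)
  structure(list(subset = profile$subset,
                 fractions = counts / total,
                 counts = counts,
                 n_reads_total = total,
                 per_mid_fractions = pmc / ifelse(mid_tot > 0, mid_tot, NA),
                 per_mid_counts = pmc),
            class = "transcript_profile")
}

#' Chi-square test of an allele's frequency across cell subsets
#'
#' Builds the 2 x k contingency table of this allele's reads versus all
#' other assigned reads in each of k subsets (MIDs combined) and applies
#' the uncorrected chi-square test: X^2 = sum (O-E)^2/E with expectations
#' from the row/column marginals, df = k - 1, upper-tail p. A warning (not
#' an error) is issued when any expected cell count is below 5.
#'
#' @param ct a [count_table()] object.
#' @param allele allele (or lineage group) name.
#' @param subsets subsets to compare (default: all subsets in the table).
#' @return object of class `diff_result`: list with `allele`, `fractions`
#'   (per-subset), `statistic`, `df`, `p_value`, `table` (the 2 x k table).
#' @export
chi_square_across_subsets <- function(ct, allele, subsets = NULL) {
  stopifnot(inherits(ct, "count_table"))
  subsets <- subsets %||% sort(unique(ct$counts$subset))
  if (length(subsets) < 2) stop("need at least 2 subsets to compare")
  a <- o <- stats::setNames(numeric(length(subsets)), subsets)
  for (s in subsets) {
    rows <- ct$counts[ct$counts$subset == s, ]
    tot <- sum(rows$count)
    if (tot == 0) stop("subset ", sQuote(s), " has no assigned reads")
    a[s] <- sum(rows$count[rows$allele == allele])
    o[s] <- tot - a[s]
  }
  if (sum(a) == 0) {
    stop("allele ", sQuote(allele), " absent from all subsets")
  }
  tab <- rbind(allele = a, other = o)
  res <- chisq_from_table(tab)
  structure(list(allele = allele,
                 fractions = a / (a + o),
                 statistic = res$statistic,
                 df = res$df,
                 p_value = res$p_value,
                 table = tab),
            class = "diff_result")
}

#' Uncorrected chi-square test of a contingency table
#'
#' The shared computational core of [chi_square_across_subsets()]:
#' X^2 = sum (O-E)^2/E with expectations from the marginals, df =
#' (rows - 1)(cols - 1), upper-tail p, no continuity correction. Warns
#' when any expected count is below 5.
#'
#' @param tab numeric contingency table (matrix).
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
chisq_from_table <- function(tab) {
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(res$expected < 5)) {
    warning("expected count < 5 in ", sum(res$expected < 5),
            " cell(s); chi-square approximation may be poor")
  }
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value), expected = res$expected)
}

#' @export
print.diff_result <- function(x, ...) {
  cat("<diff_result> ", x$allele, ": X^2 = ", signif(x$statistic, 4),
      ", df = ", x$df, ", p = ", format.pval(x$p_value), "\n", sep = "")
  print(round(x$fractions, 4))
  invisible(x)
}

#' Gene-dosage comparison of an allele's fraction
#'
#' Compares the mean transcript fraction of an allele between animals
#' homozygous and heterozygous for the carrying haplotype. Under a pure
#' dosage effect the heterozygous mean is about half the homozygous mean.
#' No significance claim is attached.
#'
#' @param fraction named numeric vector: the allele's fraction per animal.
#' @param genotype named character vector (same animals):
#'   `"homozygous"` or `"heterozygous"`.
#' @return list with `mean_homozygous`, `mean_heterozygous`,
#'   `ratio_het_hom`, `n_homozygous`, `n_heterozygous`.
#' @export
dosage_compare <- function(fraction, genotype) {
  genotype <- genotype[names(fraction)]
  if (any(is.na(genotype))) stop("every animal needs a genotype")
  bad <- setdiff(unique(genotype), c("homozygous", "heterozygous"))
  if (length(bad)) stop("unknown genotype label(s): ",
                        paste(sQuote(bad), collapse = ", "))
  hom <- fraction[genotype == "homozygous"]
  het <- fraction[genotype == "heterozygous"]
  if (!length(hom) || !length(het)) {
    stop("need at least one animal per genotype class")
  }
  list(mean_homozygous = mean(hom), mean_heterozygous = mean(het),
       ratio_het_hom = mean(het) / mean(hom),
       n_homozygous = length(hom), n_heterozygous = length(het))
}

#' Check PBMC profile against the composition-weighted subset mixture
#'
#' An allele's PBMC fraction should equal the composition-weighted sum of
#' its per-subset fractions (e.g. a monocyte-restricted allele at 0.45 in
#' CD14+ cells contributing 20% of PBMC predicts 0.09 in whole PBMC).
#' Residuals are PBMC minus predicted, after renormalizing the composition
#' to sum to 1; allele sets are unioned with zeros for absences.
#'
#' @param pbmc_profile a `transcript_profile` (or named fraction vector)
#'   for whole PBMC.
#' @param subset_profiles named list of `transcript_profile`s (or named
#'   fraction vectors) per subset.
#' @param composition named numeric vector of subset fractions of PBMC
#'   (non-empty, positive total).
#' @return list with `residuals` (data.frame `allele`, `pbmc`, `predicted`,
#'   `residual`) and `max_abs_residual`.
#' @export
mixture_check <- function(pbmc_profile, subset_profiles, composition) {
  as_frac <- function(p) {
    if (inherits(p, "transcript_profile")) p$fractions else p
  }
  if (!length(composition) || sum(composition) <= 0) {
    stop("composition must be non-empty with positive total")
  }
  missing <- setdiff(names(composition), names(subset_profiles))
  if (length(missing)) {
    stop("no profile for subset(s): ",
         paste(sQuote(missing), collapse = ", "))
  }
  comp <- composition / sum(composition)
  pb <- as_frac(pbmc_profile)
  profs <- lapply(subset_profiles[names(comp)], as_frac)
  alleles <- sort(unique(c(names(pb), unlist(lapply(profs, names)))))
  predicted <- stats::setNames(numeric(length(alleles)), alleles)
  for (s in names(comp)) {
    p <- profs[[s]]
    predicted[names(p)] <- predicted[names(p)] + comp[[s]] * p
  }
  pbmc <- stats::setNames(numeric(length(alleles)), alleles)
  pbmc[names(pb)] <- pb
  res <- data.frame(allele = alleles, pbmc = unname(pbmc),
                    predicted = unname(predicted),
                    residual = unname(pbmc - predicted),
                    stringsAsFactors = FALSE)
  list(residuals = res, max_abs_residual = max(abs(res$residual)))
}

#' Flag alleles at the limit of detection
#'
#' An allele whose combined read support falls below `min_reads` borders on
#' the limit of detection: its presence in the profile is unreliable.
#'
#' @param fraction numeric vector of allele fractions.
#' @param n_reads_total total combined reads behind those fractions (> 0).
#' @param min_reads minimum read support (default 2).
#' @return logical vector: TRUE where the allele is below the limit.
#' @export
limit_of_detection <- function(fraction, n_reads_total, min_reads = 2) {
  if (n_reads_total <= 0) stop("n_reads_total must be positive")
  reads <- fraction * n_reads_total
  reads < min_reads - 1e-9
}
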