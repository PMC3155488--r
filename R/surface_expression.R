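#' Relative surface expression from fluorescent-peptide MFI
#'
#' The fluorescent-peptide readout: 100 x MFI(peptide) / MFI(no peptide).
#' A value of 100 means no binding above background; scale-invariant in
#' the common MFI scale.
#'
#' @param mfi_peptide,mfi_no_peptide positive MFI values (vectorized).
#' @return relative expression in percent.
#' @export
relative_expression <- function(mfi_peptide, mfi_no_peptide) {
  if (any(mfi_peptide <= 0) || any(mfi_no_peptide <= 0)) {
    stop("MFI values must be positive")
  }
  100 * mfi_peptide / mfi_no_peptide
}

#' Scale relative expression by the pan-MHC (W6/32) signal
#'
#' Adjusts peptide binding for the subset's total surface MHC class I:
#' rel_expr x (reference pan-MHC MFI / subset pan-MHC MFI). Scaling by the
#' subset's own pan-MHC MFI and then unscaling is the identity. Kept
#' separate from [relative_expression()] so the raw and pan-MHC-adjusted
#' readouts are never silently combined.
#'
#' @param rel_expr relative expression (percent).
#' @param w632_mfi_subset pan-MHC MFI of the subset (> 0).
#' @param w632_mfi_reference reference pan-MHC MFI (> 0); conventionally
#'   the animal's across-subset mean.
#' @return scaled relative expression.
#' @export
w632_scale <- function(rel_expr, w632_mfi_subset, w632_mfi_reference) {
  if (any(w632_mfi_subset <= 0) || any(w632_mfi_reference <= 0)) {
    stop("pan-MHC MFI values must be positive")
  }
  rel_expr * (w632_mfi_reference / w632_mfi_subset)
}

#' Compute per-(animal, subset) relative expression from an MFI table
#'
#' Pairs each test-peptide stain with the matching `no_peptide` stain and
#' applies [relative_expression()]; optionally adds the pan-MHC-scaled
#' variant using each animal's across-subset mean `pan_MHC` MFI as the
#' reference.
#'
#' @param mfi_table data.frame with columns `animal`, `subset`, `stain`,
#'   `mfi` (and optionally `haplotype`), e.g. from [simulate_mfi_table()].
#' @param peptide stain label of the test peptide.
#' @param w632 if TRUE also compute the pan-MHC-scaled value (requires
#'   `pan_MHC` stains).
#' @return data.frame with columns `animal`, `haplotype`, `subset`,
#'   `peptide`, `rel_expr_percent` and (if requested) `w632_scaled`.
#' @export
compute_relative_expression <- function(mfi_table, peptide, w632 = FALSE) {
  stopifnot(all(c("animal", "subset", "stain", "mfi") %in%
                  names(mfi_table)))
  key <- function(df) paste(df$animal, df$subset, sep = "\r")
  pep <- mfi_table[mfi_table$stain == peptide, ]
  bg <- mfi_table[mfi_table$stain == "no_peptide", ]
  if (!nrow(pep)) stop("no rows with stain ", sQuote(peptide))
  i <- match(key(pep), key(bg))
  if (any(is.na(i))) stop("missing no_peptide stain for some samples")
  out <- data.frame(
    animal = pep$animal,
    haplotype = if ("haplotype" %in% names(pep)) pep$haplotype
                else NA_character_,
    subset = pep$subset, peptide = peptide,
    rel_expr_percent = relative_expression(pep$mfi, bg$mfi[i]),
    stringsAsFactors = FALSE)
  if (w632) {
    pan <- mfi_table[mfi_table$stain == "pan_MHC", ]
    j <- match(key(pep), key(pan))
    if (any(is.na(j))) stop("missing pan_MHC stain for some samples")
    ref <- tapply(pan$mfi, pan$animal, mean)
    out$w632_scaled <- w632_scale(out$rel_expr_percent, pan$mfi[j],
                                  as.vector(ref[as.character(pep$animal)]))
  }
  out
}

#' Paired t test (by animal)
#'
#' t = mean(d) / (sd(d) / sqrt(n)) on the paired differences, df = n - 1,
#' two-sided p. Degenerate inputs are reported rather than erroring: all
#' differences zero gives t = 0, p = 1; constant non-zero differences give
#' an infinite t with p = 0, flagged `degenerate`.
#'
#' @param values_a,values_b numeric vectors paired by position (>= 2
#'   complete pairs).
#' @return list with `t`, `df`, `p_value`, `mean_diff`, `degenerate`.
#' @export
paired_t <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    stop("paired vectors must have equal length")
  }
  ok <- !is.na(values_a) & !is.na(values_b)
  a <- values_a[ok]; b <- values_b[ok]
  if (length(a) < 2) stop("need at least 2 complete pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, df = length(d) - 1L, p_value = 1, mean_diff = 0,
                  degenerate = TRUE))
    }
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1L, p_value = 0,
                mean_diff = mean(d), degenerate = TRUE))
  }
  res <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, mean_diff = unname(res$estimate),
       degenerate = FALSE)
}

#' Unpaired two-sample t test
#'
#' Classic equal-variance (pooled) form by default, df = n_a + n_b - 2;
#' the Welch variant is available behind `welch = TRUE`. Two-sided p.
#'
#' @param group_a,group_b numeric vectors (>= 2 values each).
#' @param welch use the Welch unequal-variance form.
#' @return list with `t`, `df`, `p_value`.
#' @export
unpaired_t <- function(group_a, group_b, welch = FALSE) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("need at least 2 values per group")
  }
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    dm <- mean(group_a) - mean(group_b)
    df <- if (welch) NA_real_ else length(group_a) + length(group_b) - 2L
    return(list(t = if (dm == 0) 0 else sign(dm) * Inf, df = df,
                p_value = if (dm == 0) 1 else 0))
  }
  res <- stats::t.test(group_a, group_b, var.equal = !welch)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}

#' One-way repeated-measures ANOVA
#'
#' Decomposes a complete animal x subset matrix into subject, treatment and
#' error sums of squares; F = MS_treatment / MS_error with df = (k - 1) and
#' (k - 1)(n - 1). With k = 2 this reduces to the paired t test (F = t^2).
#' Missing cells are an error (no imputation). An all-constant matrix
#' (SS_treatment = 0) is reported as F = 0, p = 1.
#'
#' @param values numeric matrix: rows = animals (>= 2), columns = subsets
#'   (>= 2), complete.
#' @return list with `F`, `df_effect`, `df_error`, `p_value`, and the
#'   sums of squares `ss_subjects`, `ss_treatment`, `ss_error`.
#' @export
rm_anova <- function(values) {
  values <- as.matrix(values)
  if (any(is.na(values))) stop("missing cells are not allowed")
  n <- nrow(values); k <- ncol(values)
  if (n < 2 || k < 2) stop("need >= 2 animals and >= 2 subsets")
  dat <- data.frame(y = as.vector(values),
                    subject = factor(rep(seq_len(n), times = k)),
                    treatment = factor(rep(seq_len(k), each = n)))
  fit <- stats::aov(y ~ treatment + Error(subject), data = dat)
  s <- summary(fit)
  within <- s[["Error: Within"]][[1]]
  rn <- trimws(rownames(within))
  ss_treat <- within[rn == "treatment", "Sum Sq"]
  ss_err <- within[rn == "Residuals", "Sum Sq"]
  ss_subj <- s[["Error: subject"]][[1]][1, "Sum Sq"]
  df_effect <- k - 1L
  df_error <- (k - 1L) * (n - 1L)
  if (ss_treat <= .Machine$double.eps * max(1, sum(values^2))) {
    Fv <- 0; p <- 1
  } else if (ss_err <= .Machine$double.eps * max(1, sum(values^2))) {
    Fv <- Inf; p <- 0
  } else {
    Fv <- (ss_treat / df_effect) / (ss_err / df_error)
    p <- stats::pf(Fv, df_effect, df_error, lower.tail = FALSE)
  }
  list(F = Fv, df_effect = df_effect, df_error = df_error, p_value = p,
       ss_subjects = ss_subj, ss_treatment = ss_treat, ss_error = ss_err)
}
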