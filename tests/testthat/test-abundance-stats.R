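make_ct <- function(...) {
  # build a count_table from (subset, mid, allele, count) rows
  df <- data.frame(...)
  count_table(data.frame(subset = df$subset, mid = df$mid,
                         assigned_type = "allele", assigned = df$allele,
                         read_count = df$count, stringsAsFactors = FALSE))
}

test_that("profiles divide combined dual-MID counts by the combined total", {
  ct <- make_ct(subset = "CD14",
                mid = rep(c("MID1", "MID2"), each = 2),
                allele = rep(c("A-A*01", "A-B*01"), 2),
                count = c(30, 70, 10, 90))
  p <- normalize_profile(ct, "CD14")
  expect_equal(unname(p$fractions[c("A-A*01", "A-B*01")]), c(0.20, 0.80))
  expect_equal(p$n_reads_total, 200)
  expect_equal(unname(p$per_mid_fractions["MID1", "A-A*01"]), 0.30)
  expect_equal(unname(p$per_mid_fractions["MID2", "A-A*01"]), 0.10)
  expect_equal(sum(p$fractions), 1, tolerance = 1e-12)

  single <- make_ct(subset = "S", mid = "MID1", allele = "A-A*01", count = 5)
  expect_equal(unname(normalize_profile(single, "S")$fractions), 1.0)
  expect_error(normalize_profile(ct, "CD8"), "empty subset")
})

test_that("profile estimates recover a planted dominant fraction", {
  truth <- small_truth(seed = 51, error_rate = 0)
  mids <- make_mid_tags(2, seed = 51)
  sim <- simulate_subset_reads(truth, "CD14", 1000, mids)
  run <- run_amplicon_pipeline(sim$reads, truth$reference, mids,
                               data.frame(tag_id = mids$tag_id,
                                          subset = "CD14"),
                               max_mismatch = 0)
  p <- normalize_profile(run$count_table, "CD14")
  dominant <- truth$reference$name[1]
  expect_lt(abs(p$fractions[dominant] - 0.45),
            3 * sqrt(0.45 * 0.55 / 2000))
})

test_that("exclusion renormalization preserves ratios and handles absences", {
  ct <- make_ct(subset = "S", mid = "MID1",
                allele = c("A-A*01", "A-B*01", "A-C*01"),
                count = c(50, 30, 20))
  p <- normalize_profile(ct, "S")
  r <- renormalize_excluding(p, "A-A*01")
  expect_equal(unname(r$fractions[c("A-B*01", "A-C*01")]), c(0.6, 0.4))
  expect_equal(sum(r$fractions), 1)
  # pairwise ratio preserved
  expect_equal(r$fractions[["A-B*01"]] / r$fractions[["A-C*01"]],
               p$fractions[["A-B*01"]] / p$fractions[["A-C*01"]])
  # absent allele: unchanged
  expect_identical(renormalize_excluding(p, "A-Z*99"), p)
  single <- normalize_profile(make_ct(subset = "S", mid = "MID1",
                                      allele = "A-A*01", count = 5), "S")
  expect_error(renormalize_excluding(single, "A-A*01"), "only allele")
})

test_that("chi-square across subsets matches the textbook formula", {
  ct_eq <- make_ct(subset = rep(c("CD4", "CD14"), each = 2),
                   mid = "MID1",
                   allele = rep(c("A-A*01", "A-B*01"), 2),
                   count = c(10, 90, 10, 90))
  res <- chi_square_across_subsets(ct_eq, "A-A*01")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  ct2 <- make_ct(subset = rep(c("S1", "S2"), each = 2),
                 mid = "MID1",
                 allele = rep(c("A-A*01", "A-B*01"), 2),
                 count = c(10, 90, 30, 70))
  res2 <- chi_square_across_subsets(ct2, "A-A*01")
  expect_equal(res2$statistic, 12.5)
  expect_equal(res2$df, 1)
  expect_equal(res2$p_value, pchisq(12.5, 1, lower.tail = FALSE))

  # df = k - 1 for k subsets
  ct5 <- make_ct(subset = rep(paste0("S", 1:5), each = 2),
                 mid = "MID1",
                 allele = rep(c("A-A*01", "A-B*01"), 5),
                 count = rep(c(20, 80), 5))
  expect_equal(chi_square_across_subsets(ct5, "A-A*01")$df, 4)

  expect_error(chi_square_across_subsets(ct2, "A-Z*99"), "absent")
  expect_warning(
    chi_square_across_subsets(
      make_ct(subset = rep(c("S1", "S2"), each = 2), mid = "MID1",
              allele = rep(c("A-A*01", "A-B*01"), 2),
              count = c(1, 20, 2, 19)), "A-A*01"),
    "expected count")
})

test_that("chi-square agrees with the direct-formula oracle on random tables", {
  set.seed(7)
  for (i in 1:200) {
    k <- sample(2:5, 1)
    a <- rpois(k, 30) + 1
    o <- rpois(k, 100) + 1
    ct <- make_ct(subset = rep(paste0("S", 1:k), each = 2), mid = "MID1",
                  allele = rep(c("A-A*01", "A-B*01"), k),
                  count = as.vector(rbind(a, o)))
    got <- suppressWarnings(chi_square_across_subsets(ct, "A-A*01"))
    want <- oracle_chisq_2xk(rbind(a, o))
    expect_equal(got$statistic, want$statistic, tolerance = 1e-12)
    expect_equal(got$df, want$df)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
  }
})

test_that("dosage comparison reports per-genotype means and the het/hom ratio", {
  frac <- c(cy1 = 0.40, cy2 = 0.20)
  gt <- c(cy1 = "homozygous", cy2 = "heterozygous")
  d <- dosage_compare(frac, gt)
  expect_equal(d$ratio_het_hom, 0.5)
  expect_equal(dosage_compare(c(a = 0.3, b = 0.3),
                              c(a = "homozygous",
                                b = "heterozygous"))$ratio_het_hom, 1.0)
  expect_error(dosage_compare(c(a = 0.3), c(a = "homozygous")),
               "per genotype")
})

test_that("a simulated halved gene dose is recovered from read counts", {
  est <- numeric(2)
  doses <- c(hom = 0.40, het = 0.20)
  for (i in 1:2) {
    ref <- make_toy_reference(4, 190, 5, seed = 61)
    f <- doses[i]
    prof <- setNames(c(f, rep((1 - f) / 3, 3)), ref$name)
    truth <- ground_truth(ref, list(CD14 = prof), error_rate = 0,
                          seed = 61 + i)
    mids <- make_mid_tags(2, seed = 61 + i)
    sim <- simulate_subset_reads(truth, "CD14", 1000, mids)
    run <- run_amplicon_pipeline(sim$reads, ref, mids,
                                 data.frame(tag_id = mids$tag_id,
                                            subset = "CD14"),
                                 max_mismatch = 0)
    est[i] <- normalize_profile(run$count_table,
                                "CD14")$fractions[ref$name[1]]
  }
  d <- dosage_compare(setNames(est, c("a1", "a2")),
                      c(a1 = "homozygous", a2 = "heterozygous"))
  # delta-method 3 SD bound on the ratio of two binomial proportions
  se_ratio <- 0.5 * sqrt(0.2 * 0.8 / 2000 / 0.2^2 +
                         0.4 * 0.6 / 2000 / 0.4^2)
  expect_lt(abs(d$ratio_het_hom - 0.5), 3 * se_ratio)
})

test_that("mixture residuals vanish for exact composition-weighted mixtures", {
  profiles <- list(CD4 = c("A-A*01" = 0.6, "A-B*01" = 0.4),
                   CD14 = c("A-A*01" = 0.1, "A-B*01" = 0.45,
                            "A-C*01" = 0.45))
  comp <- c(CD4 = 0.7, CD14 = 0.3)
  pbmc <- mixture_profile(profiles, comp)
  mc <- mixture_check(pbmc, profiles, comp)
  expect_equal(mc$max_abs_residual, 0, tolerance = 1e-12)

  # one-hot composition: residuals are pbmc minus that subset's profile
  mc2 <- mixture_check(pbmc, profiles, c(CD14 = 1))
  expect_equal(mc2$residuals$residual,
               unname(pbmc[mc2$residuals$allele] -
                        c(profiles$CD14, "A-Z" = 0)[mc2$residuals$allele]),
               tolerance = 1e-12)

  # a CD14-only allele at 0.45 with CD14 = 20% of PBMC predicts 0.09
  mc3 <- mixture_check(c("A-C*01" = 0.09, "A-A*01" = 0.455,
                         "A-B*01" = 0.455),
                       profiles, c(CD4 = 0.8, CD14 = 0.2))
  expect_equal(mc3$residuals$predicted[mc3$residuals$allele == "A-C*01"],
               0.09)
  expect_error(mixture_check(pbmc, profiles, numeric(0)), "non-empty")
})

test_that("limit-of-detection flags read support below the threshold", {
  expect_true(limit_of_detection(1 / 1000, 1000))
  expect_false(limit_of_detection(2 / 1000, 1000))
  expect_true(limit_of_detection(0, 1000))
  expect_equal(limit_of_detection(c(0.001, 0.05), 1000),
               c(TRUE, FALSE))
  expect_error(limit_of_detection(0.5, 0), "positive")
})
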