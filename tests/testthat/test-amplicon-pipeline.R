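test_that("demultiplexing bins by exact prefix and applies the strict-closer tie rule", {
  tags <- data.frame(tag_id = c("MID1", "MID2"),
                     tag_sequence = c("AAAAAAAAAA", "AAAAAAAACC"))
  reads <- data.frame(
    read_id = c("r1", "r2", "r3", "r4"),
    sequence = c("AAAAAAAAAAGGGG",   # exact MID1
                 "AAAAAAAACCGGGG",   # exact MID2
                 "AAAAAAAAACGGGG",   # 1 mismatch from both: tie
                 "TTTTTTTTTTGGGG"),  # matches nothing
    stringsAsFactors = FALSE)
  dm <- demultiplex(reads, tags, max_tag_mismatch = 1)
  expect_equal(dm$bins$MID1$read_id, "r1")
  expect_equal(dm$bins$MID2$read_id, "r2")
  expect_equal(dm$unassigned$read_id, c("r3", "r4"))
  # MID prefix is stripped from binned reads
  expect_equal(dm$bins$MID1$sequence, "GGGG")
  # exact matching leaves near-miss reads unassigned
  dm0 <- demultiplex(reads, tags, max_tag_mismatch = 0)
  expect_equal(dm0$unassigned$read_id, c("r3", "r4"))
  expect_error(demultiplex(reads, data.frame(tag_id = "T1",
                                             tag_sequence = "ACGT")),
               "10 bp")
})

test_that("demultiplexing is a partition that matches the emission log", {
  ref <- make_toy_reference(4, 190, 5, seed = 41)
  prof <- setNames(rep(0.25, 4), ref$name)
  truth <- ground_truth(ref, subset_profiles = stats::setNames(
    rep(list(prof), 6), paste0("S", 1:6)), error_rate = 0, seed = 41)
  mids <- make_mid_tags(12, seed = 41)
  sims <- lapply(1:6, function(i) {
    simulate_subset_reads(truth, paste0("S", i), 100,
                          mids[(2 * i - 1):(2 * i), ])
  })
  reads <- do.call(rbind, lapply(sims, `[[`, "reads"))
  emission <- do.call(rbind, lapply(sims, `[[`, "emission"))
  dm <- demultiplex(reads, mids)
  expect_equal(sum(vapply(dm$bins, nrow, integer(1))) + nrow(dm$unassigned),
               nrow(reads))
  expect_equal(nrow(dm$unassigned), 0L)
  bin_sizes <- vapply(dm$bins, nrow, integer(1))
  log_sizes <- table(factor(emission$mid, levels = mids$tag_id))
  expect_equal(unname(bin_sizes), as.vector(log_sizes))
  expect_equal(anyDuplicated(unlist(lapply(dm$bins, `[[`, "read_id"))), 0L)
})

test_that("trimming recovers the exact insert and enumerates rejection reasons", {
  pr <- default_primers()
  insert <- paste0(strrep("ACGT", 47), "AC")  # 190 bp
  good <- paste0(pr$fwd, insert, mhcsubsets:::revcomp(pr$rev))
  short <- paste0(pr$fwd, substr(insert, 1, 189), mhcsubsets:::revcomp(pr$rev))
  reads <- data.frame(
    read_id = c("good", "random", "no_rev", "short", "with_n"),
    sequence = c(good,
                 strrep("GA", 115),
                 paste0(pr$fwd, insert, strrep("A", nchar(pr$rev))),
                 short,
                 sub("A", "N", good)),
    stringsAsFactors = FALSE)
  tr <- trim_reads(reads, pr$fwd, pr$rev, expected_insert_length = 190,
                   length_tolerance = 0)
  expect_equal(tr$insert[1], insert)
  expect_true(tr$accepted[1])
  expect_equal(tr$reason[2], "no_fwd_primer")
  expect_equal(tr$reason[3], "no_rev_primer")
  expect_equal(tr$reason[4], "bad_length")
  expect_equal(tr$reason[5], "contains_N")
  # tolerance admits the boundary case
  tr1 <- trim_reads(reads[4, ], pr$fwd, pr$rev, 190, length_tolerance = 1)
  expect_true(tr1$accepted)
})

test_that("collapsing forms 100%-identity contigs with conserved counts", {
  cl <- collapse_identical(c(a = "ACGT", b = "ACGT", c = "ACGA"))
  expect_equal(cl$insert_sequence, c("ACGT", "ACGA"))
  expect_equal(cl$read_count, c(2L, 1L))
  expect_equal(cl$member_ids[[1]], c("a", "b"))
  expect_equal(nrow(collapse_identical(character(0))), 0L)

  # ties in read count break lexicographically
  cl2 <- collapse_identical(c("TTTT", "AAAA"))
  expect_equal(cl2$insert_sequence, c("AAAA", "TTTT"))

  ref <- make_toy_reference(4, 60, 3, seed = 17)
  truth <- ground_truth(ref, list(S = setNames(rep(0.25, 4), ref$name)),
                        error_rate = 0, seed = 17)
  sim <- simulate_subset_reads(truth, "S", 250, make_mid_tags(2, seed = 17))
  pr <- default_primers()
  tr <- trim_reads(data.frame(read_id = sim$reads$read_id,
                              sequence = substring(sim$reads$sequence, 11)),
                   pr$fwd, pr$rev, 60)
  cl3 <- collapse_identical(tr)
  expect_equal(nrow(cl3), 4L)  # one contig per allele at zero error
  expect_equal(sum(cl3$read_count), 500L)
})

test_that("assignment resolves unique hits, lineage ties and ambiguity", {
  ref <- mhc_reference(
    c("Mafa-B*134:01", "Mafa-B*134:02", "Mafa-B*075:01"),
    c("AAAAACCCCCGGGGG", "AAAAACCCCCGGGGG", "TTTTTGGGGGAAAAA"))
  a <- assign_clusters("AAAAACCCCCGGGGG", ref, max_mismatch = 2)
  expect_equal(a$assigned_type, "lineage")
  expect_equal(a$assigned, "Mafa-B*134")
  expect_equal(a$tie_size, 2L)
  expect_equal(a$mismatches, 0L)

  b <- assign_clusters("TTTTTGGGGGAAAAA", ref, max_mismatch = 2)
  expect_equal(b$assigned_type, "allele")
  expect_equal(b$assigned, "Mafa-B*075:01")
  expect_equal(b$tie_size, 1L)

  # cross-lineage equidistance is ambiguous
  ref2 <- mhc_reference(c("Mafa-B*001:01", "Mafa-B*002:01"),
                        c("AAAA", "AAAT"))
  c2 <- assign_clusters("AAAG", ref2, max_mismatch = 2)
  expect_equal(c2$assigned_type, "ambiguous")
  expect_equal(c2$assigned, "Mafa-B*001:01;Mafa-B*002:01")

  d <- assign_clusters("GGGG", ref2, max_mismatch = 2)
  expect_equal(d$assigned_type, "unassigned")
  expect_true(is.na(d$assigned))
  expect_error(assign_clusters("AAAA", ref2[0, ], 2), "non-empty")
})

test_that("a single substitution within the ceiling recovers the true allele", {
  ref <- make_toy_reference(5, 60, 5, seed = 23)
  s <- ref$sequence[3]
  substr(s, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                               substr(s, 10, 10))[1]
  a <- assign_clusters(s, ref, max_mismatch = 2)
  expect_equal(a$assigned, ref$name[3])
  expect_equal(a$mismatches, 1L)
})

test_that("assignment agrees with a brute-force scan on random instances", {
  set.seed(99)
  for (rep in 1:40) {
    n <- sample(2:6, 1)
    L <- sample(c(20, 30), 1)
    ref <- make_toy_reference(n, L, 0, seed = rep,
                              locus = sample(c("Mafa-B", "Mamu-A1"), 1))
    base <- ref$sequence[sample(n, 1)]
    nmut <- sample(0:4, 1)
    s <- strsplit(base, "")[[1]]
    if (nmut > 0) {
      pos <- sample(L, nmut)
      for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
    }
    query <- paste(s, collapse = "")
    got <- assign_clusters(query, ref, max_mismatch = 2)
    want <- oracle_assign(query, ref, max_mismatch = 2)
    expect_equal(got$assigned_type, want$type)
    if (want$type != "unassigned") expect_equal(got$assigned, want$name)
  }
})

test_that("count tables are read-weighted and keep ambiguous reads out of allele counts", {
  asg <- data.frame(
    subset = "CD14", mid = "MID1",
    assigned_type = c("allele", "ambiguous", "unassigned"),
    assigned = c("Mafa-B*134:02", "Mafa-B*001:01;Mafa-B*002:01", NA),
    read_count = c(10L, 4L, 3L), stringsAsFactors = FALSE)
  ct <- count_table(asg)
  expect_equal(ct$counts$count, 10L)
  expect_equal(ct$counts$allele, "Mafa-B*134:02")
  expect_equal(sort(ct$other$category), c("ambiguous", "unassigned"))
  expect_equal(sum(ct$other$count), 7L)
})

test_that("the pipeline reproduces the emission log exactly at zero error", {
  truth <- small_truth(seed = 31, error_rate = 0)
  mids <- make_mid_tags(4, seed = 31)
  simA <- simulate_subset_reads(truth, "CD14", 300, mids[1:2, ])
  simB <- simulate_subset_reads(truth, "CD4", 300, mids[3:4, ])
  reads <- rbind(simA$reads, simB$reads)
  smap <- data.frame(tag_id = mids$tag_id,
                     subset = c("CD14", "CD14", "CD4", "CD4"))
  run <- run_amplicon_pipeline(reads, truth$reference, mids, smap,
                               max_mismatch = 0)
  expected <- emission_counts(rbind(simA$emission, simB$emission))
  got <- run$count_table$counts
  expect_equal(got, expected)
  expect_equal(nrow(run$rejects), 0L)
  expect_equal(sum(run$count_table$other$count), 0L)
})

test_that("fractions survive sequencing error within binomial bounds", {
  truth <- small_truth(seed = 37, error_rate = 0.005)
  mids <- make_mid_tags(2, seed = 37)
  sim <- simulate_subset_reads(truth, "CD14", 1000, mids)
  smap <- data.frame(tag_id = mids$tag_id, subset = "CD14")
  run <- run_amplicon_pipeline(sim$reads, truth$reference, mids, smap,
                               max_mismatch = 2)
  prof <- normalize_profile(run$count_table, "CD14")
  truefrac <- truth$subset_profiles$CD14
  for (al in names(truefrac)) {
    se <- sqrt(truefrac[al] * (1 - truefrac[al]) / 2000)
    expect_lt(abs(prof$fractions[al] - truefrac[al]), 3 * se + 1e-12)
  }
})
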