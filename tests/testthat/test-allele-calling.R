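test_that("star alignment rows ungap to their source reads", {
  set.seed(41)
  base <- random_dna(120)
  with_del <- paste0(substr(base, 1, 49), substr(base, 57, 120)) # 7-bp deletion
  reads <- reads_from_seqs(c(base, with_del), c(3L, 3L))
  aln <- align_group(read_group(reads))
  expect_identical(length(unique(nchar(aln$rows))), 1L)
  for (i in seq_along(aln$ids)) {
    expect_identical(gsub("-", "", aln$rows[i]),
                     reads$bases[match(aln$ids[i], reads$read_id)])
  }
  # the deletion shows up as a 7-column gap block in the carrier rows
  gap_rows <- grepl("-{7}", aln$rows)
  expect_identical(sum(gap_rows), 3L)
  # identical reads align without gaps
  same <- align_group(read_group(reads_from_seqs(base, 5L)))
  expect_false(any(grepl("-", same$rows)))
})

test_that("alleles split at >= min_diff sites and merge below it", {
  set.seed(42)
  a1 <- random_dna(150)
  a2 <- mutate_seq(a1, pos = c(40, 90))      # 2 differences: distinct
  a3 <- mutate_seq(a1, pos = 75)             # 1 difference: merges
  two <- call_alleles(align_group(read_group(reads_from_seqs(c(a1, a2),
                                                             c(10L, 10L)))))
  expect_identical(nrow(two), 2L)
  expect_setequal(two$consensus, c(a1, a2))
  expect_identical(sum(two$support_count), 20L)
  one <- call_alleles(align_group(read_group(reads_from_seqs(c(a1, a3),
                                                             c(10L, 10L)))))
  expect_identical(nrow(one), 1L)
  expect_identical(one$support_count, 20L)
  mono <- call_alleles(align_group(read_group(reads_from_seqs(a1, 20L))))
  expect_identical(nrow(mono), 1L)
  expect_identical(mono$support_count, 20L)
  expect_false(mono$low_support)
})

test_that("support is conserved and raising min_diff never adds alleles", {
  set.seed(43)
  a1 <- random_dna(160)
  a2 <- mutate_seq(a1, pos = c(30, 80, 130))
  a3 <- mutate_seq(a1, pos = c(55, 110))
  reads <- reads_from_seqs(c(a1, a2, a3), c(12L, 9L, 6L))
  aln <- align_group(read_group(reads))
  prev <- Inf
  for (md in 1:4) {
    calls <- call_alleles(aln, allele_params(min_diff = md))
    expect_identical(sum(calls$support_count), nrow(reads))
    n_unflagged <- sum(!calls$low_support)
    expect_lte(n_unflagged, prev)
    prev <- n_unflagged
  }
})

test_that("low-support and minority clusters are flagged, not dropped", {
  set.seed(44)
  a1 <- random_dna(150)
  a2 <- mutate_seq(a1, pos = c(50, 100))
  calls <- call_alleles(align_group(read_group(
    reads_from_seqs(c(a1, a2), c(30L, 1L)))))
  expect_identical(nrow(calls), 2L)
  expect_identical(calls$low_support, c(FALSE, TRUE))
  expect_identical(sum(calls$support_count), 31L)
})

test_that("fixed differences and shared polymorphisms are counted per column", {
  expect_identical(fixed_differences("ACGT", "ACGA")[c("fixed", "shared")],
                   list(fixed = 1L, shared = 0L))
  fs <- fixed_differences(c("ACGT", "ACGC"), c("ATGT", "ATGC"))
  expect_identical(fs$fixed, 1L)
  expect_identical(fs$shared, 1L)
  expect_identical(fixed_differences("ACGT", "ACGT")[c("fixed", "shared")],
                   list(fixed = 0L, shared = 0L))
  # gap columns are tallied separately, not as base differences
  gp <- fixed_differences("AC-T", "ACGT")
  expect_identical(gp$fixed, 0L)
  expect_identical(gp$indel_columns, 3L)
  expect_error(fixed_differences("ACGT", "ACG"), "equal column")
})

test_that("copy partition recovers the simulated copies and diagnostics", {
  set.seed(45)
  core <- random_dna(300)
  fixed_pos <- sample(300, 19)
  b_core <- mutate_seq(core, pos = fixed_pos)
  # a 7-bp deletion clear of the substituted positions
  del_start <- 150
  while (any(abs(fixed_pos - del_start) < 10)) del_start <- del_start + 11
  b1 <- paste0(substr(b_core, 1, del_start - 1),
               substr(b_core, del_start + 7, 300))
  a1 <- core
  a2 <- mutate_seq(core, pos = setdiff(c(20, 70, 120), fixed_pos))
  calls <- calls_from_seqs(c(a1, a2, b1), c(10L, 8L, 30L))
  part <- partition_copies(calls)
  expect_true(part$separable)
  expect_identical(part$fixed_difference_count, 19L)
  expect_identical(part$shared_polymorphism_count, 0L)
  expect_identical(part$calls$copy_label, c("A", "A", "B"))  # B = more reads
  expect_identical(part$diagnostic_indels$length, 7L)
  # identical allele sets cannot be separated
  same <- calls_from_seqs(c(a1, a1), c(10L, 10L))
  expect_warning(p2 <- partition_copies(same), "not separable")
  expect_false(p2$separable)
  expect_true(all(p2$calls$copy_label == "unassigned"))
})

test_that("indel coding scores shared indels and skips the exclusions", {
  rows <- c(s1 = "ACGTACG-------TACGTACGTT",
            s2 = "ACGTACG-------TACGTACGTT",
            s3 = "ACGTACG-------TACGTACGTT",
            s4 = "ACGTACGTTTGGGCTACGTACGTT",
            s5 = "ACGTACGTTTGGGCTACGTACGTT",
            s6 = "ACGTACGTTTGGGCTACGTACGTT")
  out <- code_indels(rows)
  expect_identical(nrow(out$indels), 1L)
  expect_identical(out$indels$length, 7L)
  expect_identical(unname(substr(out$extended, 25, 25)),
                   c("c", "c", "c", "a", "a", "a"))
  # singleton indel: not scored
  single <- c(a = "ACGTAC---GTACGT", b = "ACGTACGGGGTACGT",
              c = "ACGTACGGGGTACGT", d = "ACGTACGGGGTACGT")
  expect_identical(nrow(code_indels(single)$indels), 0L)
  # length variation inside an 8-bp poly-A run: not scored
  polya <- c(a = "GCGTAAAAAAAA--GCGTACGTAC", b = "GCGTAAAAAAAA--GCGTACGTAC",
             c = "GCGTAAAAAAAAAAGCGTACGTAC", d = "GCGTAAAAAAAAAAGCGTACGTAC")
  expect_identical(nrow(code_indels(polya)$indels), 0L)
})

test_that("error rate is counted over non-N calls at gap-free columns", {
  set.seed(46)
  hap <- random_dna(200)
  reads <- reads_from_seqs(hap, 10L)
  clean <- estimate_error_rate(list(align_group(read_group(reads))))
  expect_identical(clean$rate, 0)
  expect_identical(clean$denominator, 2000L)
  # plant exactly 26 single-base errors across the group
  bases <- rep(hap, 10)
  err_at <- cbind(read = sample(10, 26, replace = TRUE),
                  pos = sample(200, 26))
  err_at <- err_at[!duplicated(err_at), , drop = FALSE]
  for (i in seq_len(nrow(err_at))) {
    bases[err_at[i, "read"]] <- mutate_seq(bases[err_at[i, "read"]],
                                           pos = err_at[i, "pos"])
  }
  noisy <- qualified_reads(sprintf("e%02d", 1:10), bases, 35L)
  est <- estimate_error_rate(list(align_group(read_group(noisy))))
  expect_identical(est$numerator, nrow(err_at))
  expect_equal(est$rate, nrow(err_at) / 2000)
})
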