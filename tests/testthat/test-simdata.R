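small_cfg <- function(...) {
  sim_config(n_samples = 3L, reads_mean = 25, dropout = 0, ...)
}

test_that("the same seed reproduces the dataset exactly", {
  s1 <- simulate_dataset(small_cfg(seed = 7L))
  s2 <- simulate_dataset(small_cfg(seed = 7L))
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_dataset(small_cfg(seed = 8L))
  expect_false(identical(s1$reads$bases, s3$reads$bases))
})

test_that("every read has exactly one truth record and counts reconcile", {
  sim <- simulate_dataset(small_cfg(seed = 9L))
  expect_identical(sort(sim$reads$read_id), sort(sim$truth$reads$read_id))
  expect_identical(anyDuplicated(sim$truth$reads$read_id), 0L)
  # truth alleles cover every non-chimeric read's source
  src <- sim$truth$reads[sim$truth$reads$source == "allele", ]
  expect_true(all(paste(src$sample, src$region, src$allele_seq) %in%
                  paste(sim$truth$alleles$sample, sim$truth$alleles$region,
                        sim$truth$alleles$sequence)))
})

test_that("error injection is binomial at the configured rate", {
  set.seed(61)
  n_bases <- 0L
  n_errors <- 0L
  for (i in 1:40) {
    b <- random_dna(2500)
    out <- inject_errors(b, rep(35L, 2500), rate = 0.005)
    n_bases <- n_bases + 2500L
    n_errors <- n_errors + length(out$error_pos)
    # errors really differ from the original
    orig <- strsplit(b, "")[[1]]
    new <- strsplit(out$bases, "")[[1]]
    expect_identical(which(orig != new), as.integer(sort(out$error_pos)))
  }
  expected <- n_bases * 0.005
  expect_lt(abs(n_errors - expected), 3 * sqrt(n_bases * 0.005 * 0.995))
  clean <- inject_errors("ACGT", rep(35L, 4), rate = 0)
  expect_identical(clean$bases, "ACGT")
  expect_length(clean$error_pos, 0L)
})

test_that("chimera construction switches template at a homologous column", {
  set.seed(62)
  p1 <- random_dna(300)
  p2 <- mutate_seq(p1, k = 12)
  ch <- inject_chimera(p1, p2, min_segment = 30L)
  k <- ch$breakpoint
  expect_identical(substr(ch$sequence, 1, k), substr(p1, 1, k))
  expect_identical(substr(ch$sequence, k + 1, 300), substr(p2, k + 1, 300))
  expect_gte(k, 30L)
  expect_lte(k, 270L)
  expect_error(inject_chimera(p1, p1), "distinct")
})

test_that("injected chimera fraction matches the configured rate", {
  sim <- simulate_dataset(sim_config(n_samples = 8L, reads_mean = 60,
                                     chimera_rate = 0.05, dropout = 0,
                                     seed = 63L))
  tr <- sim$truth$reads
  # chimeras only arise in cells with >= 2 distinct alleles (nuclear regions)
  eligible <- tr$region %in% sim$regions$name[sim$regions$expected_copies == 2]
  frac <- mean(tr$source[eligible] == "chimera")
  n <- sum(eligible)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("region designs surface in the truth alleles", {
  sim <- simulate_dataset(small_cfg(seed = 64L))
  truth <- sim$truth$alleles
  # plastid regions: one haplotype per sample
  for (rn in sim$regions$name[sim$regions$expected_copies == 1]) {
    per_sample <- table(truth$sample[truth$region == rn])
    expect_true(all(per_sample == 1L))
  }
  # nuclear regions carry both copies and the B copy is shorter where
  # diagnostic deletions were applied
  dmc <- truth[truth$region == "nucDMC1", ]
  expect_setequal(unique(dmc$copy), c("A", "B"))
  expect_identical(unique(nchar(dmc$sequence[dmc$copy == "A"])) -
                     unique(nchar(dmc$sequence[dmc$copy == "B"])), 7L)
})
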