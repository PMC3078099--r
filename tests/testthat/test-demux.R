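make_layout <- function(word, fwd, insert, rev) {
  paste0(word, "T", fwd, insert, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(rev))), "A")
}

test_that("reads are assigned to the right region and orientation", {
  set.seed(31)
  regions <- gene_regions(c("locus1", "locus2"),
                          c(random_dna(20), random_dna(20)),
                          c(random_dna(20), random_dna(20)),
                          expected_copies = c(1L, 1L))
  insert <- random_dna(200)
  fwd_read <- make_layout("AAAA", regions$fwd_primer[1], insert,
                          regions$rev_primer[1])
  rev_read <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fwd_read)))
  noise <- random_dna(200)
  reads <- qualified_reads(c("f", "r", "x"), c(fwd_read, rev_read, noise), 35L)
  asn <- assign_region(reads, regions)
  expect_identical(asn$status, c("ok", "ok", "unassigned"))
  expect_identical(asn$region[1:2], c("locus1", "locus1"))
  expect_identical(asn$orientation[1:2], c("forward", "reverse"))
})

test_that("a one-mismatch primer still assigns; duplicate regions are ambiguous", {
  set.seed(32)
  fwd <- random_dna(20)
  regions <- gene_regions("locus1", fwd, random_dna(20))
  insert <- random_dna(150)
  read <- make_layout("AAAA", mutate_seq(fwd, 1), insert, regions$rev_primer)
  asn <- assign_region(qualified_reads("m", read, 35L), regions)
  expect_identical(asn$status, "ok")
  dup <- gene_regions(c("la", "lb"), rep(fwd, 2),
                      c(random_dna(20), random_dna(20)),
                      expected_copies = c(1L, 1L))
  asn2 <- assign_region(qualified_reads("d", make_layout("AAAA", fwd, insert,
                                                         dup$rev_primer[1]), 35L),
                        dup)
  expect_identical(asn2$status, "ambiguous")
})

test_that("trimming recovers the exact insert and resolves the sample", {
  set.seed(33)
  regions <- gene_regions("locus1", random_dna(20), random_dna(20))
  sheet <- sample_sheet(c("AAAA", "ACGC"), c("S1", "S2"))
  insert <- random_dna(180)
  reads <- qualified_reads(
    c("good", "frag", "badsum"),
    c(make_layout("ACGC", regions$fwd_primer, insert, regions$rev_primer),
      # barcode clipped off (fragmented 5' end): primer found too early
      substr(make_layout("AAAA", regions$fwd_primer, insert,
                         regions$rev_primer), 4, 400),
      make_layout("AAAC", regions$fwd_primer, insert, regions$rev_primer)),
    35L)
  tr <- trim_to_insert(reads, regions[1, ], sheet)
  expect_identical(tr$assignments$status,
                   c("ok", "word_missing", "checksum_fail"))
  expect_identical(tr$assignments$sample_id[1], "S2")
  expect_identical(tr$reads$bases, insert)
  expect_identical(lengths(tr$reads$quals), nchar(insert))
})

test_that("orientation flip reverse-complements bases and reverses qualities", {
  r <- qualified_reads("r", "AACGT", list(c(1L, 2L, 3L, 4L, 5L)))
  o <- orient_reads(r, "reverse")
  expect_identical(o$bases, "ACGTT")
  expect_identical(o$quals[[1]], c(5L, 4L, 3L, 2L, 1L))
  expect_identical(orient_reads(r, "forward"), r)
})
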