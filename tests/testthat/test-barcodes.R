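test_that("checksum base complements the base-index sum mod 4", {
  # hand evaluations of the scheme (A=0, C=1, G=2, T=3)
  expect_identical(checksum_base("AAA"), "A")   # 0 -> 0
  expect_identical(checksum_base("ACG"), "C")   # 0+1+2 = 3 -> (4-3) %% 4 = 1
  expect_identical(checksum_base("TTT"), "T")   # 9 %% 4 = 1 -> 3
  for (code in c("AAA", "ACG", "TTT", "GGC", "CAT")) {
    idx <- match(strsplit(paste0(code, checksum_base(code)), "")[[1]],
                 c("A", "C", "G", "T")) - 1L
    expect_identical(sum(idx) %% 4L, 0L)
  }
  expect_error(checksum_base("AXA"), "non-ACGT")
  expect_error(checksum_base("AA"), "3 bases")
})

test_that("vocabulary is exactly the 64 checksum-valid words of all 256 4-mers", {
  words <- generate_barcode_words()
  expect_length(words, 64L)
  expect_identical(words, sort(words))
  expect_identical(words[1], "AAAA")
  expect_false(anyDuplicated(words) > 0)
  all_4mers <- do.call(paste0, expand.grid(c("A", "C", "G", "T"),
                                           c("A", "C", "G", "T"),
                                           c("A", "C", "G", "T"),
                                           c("A", "C", "G", "T"),
                                           stringsAsFactors = FALSE))
  valid <- vapply(all_4mers, validate_word, logical(1))
  expect_identical(sum(valid), 64L)
  expect_setequal(all_4mers[valid], words)
})

test_that("every single-base substitution of a valid word is rejected", {
  words <- generate_barcode_words()
  n_checked <- 0L
  for (word in words) {
    for (i in 1:4) {
      for (b in setdiff(c("A", "C", "G", "T"), substr(word, i, i))) {
        mutant <- word
        substr(mutant, i, i) <- b
        expect_false(validate_word(mutant))
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_identical(n_checked, 768L)
})

test_that("words containing N or of wrong length are handled", {
  expect_false(validate_word("AANA"))
  expect_error(validate_word("AAAAA"), "4 bases")
  expect_error(validate_word("AXAA"), "ACGTN")
})

test_that("deconvolve maps valid known words and reports rejection reasons", {
  sheet <- sample_sheet(c("AAAA", "ACGC"), c("S1", "S2"))
  expect_identical(deconvolve("AAAA", sheet),
                   list(sample_id = "S1", status = "ok"))
  expect_identical(deconvolve("AAAC", sheet)$status, "checksum_fail")
  # valid checksum but not on the sheet
  expect_identical(deconvolve("AAGG", sheet)$status, "unknown_word")
  expect_identical(deconvolve(NA_character_, sheet)$status, "word_missing")
  expect_identical(deconvolve("AANA", sheet)$status, "checksum_fail")
})

test_that("sample sheets enforce validity, uniqueness and the 64-entry cap", {
  words <- generate_barcode_words()
  expect_silent(sample_sheet(words, sprintf("S%02d", 1:64)))
  expect_error(sample_sheet(c("AAAA", "AAAA"), c("a", "b")), "duplicate")
  expect_error(sample_sheet(c("AAAC"), "a"), "invalid")
  expect_error(sample_sheet(rep(words, 2)[1:65], sprintf("S%02d", 1:65)),
               "64")
})
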