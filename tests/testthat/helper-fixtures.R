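# Small fixture builders shared across test files.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute `k` random positions (or the given positions) of a sequence
mutate_seq <- function(seq, k = 1L, pos = NULL) {
  ch <- strsplit(seq, "")[[1]]
  if (is.null(pos)) pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# a read group of `counts[i]` exact copies of each sequence in `seqs`
reads_from_seqs <- function(seqs, counts, qual = 35L, prefix = "r") {
  bases <- rep(seqs, counts)
  qualified_reads(sprintf("%s%03d", prefix, seq_along(bases)), bases, qual)
}

# one aligned-call tibble row per sequence, as call_alleles would emit
calls_from_seqs <- function(seqs, supports, sample = "S", region = "R") {
  n_total <- sum(supports)
  tibble::tibble(
    sample = sample, region = region,
    allele_label = paste0("al", seq_along(seqs)),
    consensus = seqs, aligned_consensus = NA_character_,
    support_count = as.integer(supports),
    supporting_read_ids = lapply(seq_along(seqs), function(i) character(0)),
    fraction = supports / n_total,
    copy_label = "unassigned",
    low_support = supports < 2L | supports / n_total < 0.05
  )
}
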