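# Region assignment by primer matching, read orientation, and trimming of
# barcode word, ligation bases and primers to expose the amplicon insert.
#
# Read layout at the 5' end of an oriented read (sequencing starts at the
# barcode; the library adapter is the sequencing primer and is not read):
#   [4-bp barcode word] [ligation T] [forward primer] [insert] ...
# and at the 3' end, when the read is long enough:
#   ... [insert] [revcomp(reverse primer)] [ligation A] [adapter remnant]

#' Demultiplexing parameters
#'
#' @param max_mismatch Substitutions tolerated in a primer match (default 1).
#' @param search_window Primer search window at the read start, in bases
#'   (default 40).
#' @return A `demux_params` list.
#' @export
demux_params <- function(max_mismatch = 1L, search_window = 40L) {
  stopifnot(max_mismatch >= 0L, search_window >= 1L)
  structure(list(max_mismatch = as.integer(max_mismatch),
                 search_window = as.integer(search_window)),
            class = "demux_params")
}

# counts of best-mismatch primer hits in the first `window` bases of each
# sequence; returns the per-read minimum mismatch count (Inf if no hit)
prefix_hit_mm <- function(seqs, primer, p) {
  pre <- Biostrings::subseq(seqs, 1L,
                            pmin(Biostrings::width(seqs), p$search_window))
  mm <- rep(Inf, length(seqs))
  wide <- Biostrings::width(pre) >= nchar(primer)
  if (!any(wide)) return(mm)
  for (k in 0:p$max_mismatch) {
    hit <- Biostrings::vcountPattern(primer, pre[wide], max.mismatch = k) > 0L
    mm[which(wide)[hit]] <- pmin(mm[which(wide)[hit]], k)
  }
  mm
}

#' Assign reads to gene regions and orientations
#'
#' For each region, the forward primer and the reverse complement of the
#' reverse primer are searched within the first `search_window` bases of each
#' read and of its reverse complement, allowing up to `max_mismatch`
#' substitutions. A read is assigned to the unique best-scoring
#' (region, orientation); equally good hits in two regions or orientations
#' are dropped as ambiguous.
#'
#' @param reads A `qreads` tibble.
#' @param regions Gene-region tibble (see [gene_regions()]).
#' @param p [demux_params()].
#' @return Tibble with one row per read: `read_id`, `region`, `orientation`
#'   (`"forward"`/`"reverse"`) and `status` (`"ok"`, `"unassigned"`,
#'   `"ambiguous"`).
#' @export
assign_region <- function(reads, regions, p = demux_params()) {
  reads <- validate_qreads(reads)
  n <- nrow(reads)
  fwd <- Biostrings::DNAStringSet(if (n) reads$bases else character(0))
  rev <- Biostrings::reverseComplement(fwd)
  best_mm <- matrix(Inf, nrow = n, ncol = 2L * nrow(regions))
  for (r in seq_len(nrow(regions))) {
    probes <- c(regions$fwd_primer[r], revcomp(regions$rev_primer[r]))
    mm_f <- pmin(prefix_hit_mm(fwd, probes[1], p), prefix_hit_mm(fwd, probes[2], p))
    mm_r <- pmin(prefix_hit_mm(rev, probes[1], p), prefix_hit_mm(rev, probes[2], p))
    best_mm[, 2L * r - 1L] <- mm_f
    best_mm[, 2L * r] <- mm_r
  }
  region <- rep(NA_character_, n)
  orientation <- rep(NA_character_, n)
  status <- rep("unassigned", n)
  if (n) {
    row_best <- apply(best_mm, 1L, min)
    for (i in which(is.finite(row_best))) {
      hits <- which(best_mm[i, ] == row_best[i])
      if (length(hits) > 1L) {
        status[i] <- "ambiguous"
      } else {
        region[i] <- regions$name[ceiling(hits / 2)]
        orientation[i] <- if (hits %% 2L == 1L) "forward" else "reverse"
        status[i] <- "ok"
      }
    }
  }
  tibble::tibble(read_id = reads$read_id, region = region,
                 orientation = orientation, status = status)
}

#' Orient reads to the canonical forward layout
#'
#' Reverse-orientation reads are reverse-complemented (and their qualities
#' reversed) so that the barcode word, when present, lies at the 5' end.
#'
#' @param reads A `qreads` tibble.
#' @param orientation Character vector, `"forward"` or `"reverse"` per read.
#' @return Oriented `qreads` tibble.
#' @export
orient_reads <- function(reads, orientation) {
  reads <- validate_qreads(reads)
  flip <- which(orientation == "reverse")
  if (length(flip)) {
    reads$bases[flip] <- revcomp(reads$bases[flip])
    reads$quals[flip] <- lapply(reads$quals[flip], rev)
  }
  reads
}

#' Trim an oriented read to its amplicon insert
#'
#' Locates the forward primer, extracts the 4-bp barcode word immediately
#' 5' of the ligation T, resolves the sample via [deconvolve()], and removes
#' word, ligation bases, primers and any 3' remnant beyond the reverse
#' primer. Reads starting inside the primer (fragmented; no barcode
#' reachable) are rejected with status `word_missing`.
#'
#' @param reads Oriented `qreads` tibble (forward layout).
#' @param region One row of a gene-region tibble.
#' @param sheet Sample sheet tibble.
#' @param p [demux_params()].
#' @return A list: `reads` (trimmed inserts, only successful rows, with the
#'   word/sample attached via the `assignments` tibble) and `assignments`
#'   (per input read: `read_id`, `sample_id`, `status` among `"ok"`,
#'   `"word_missing"`, `"checksum_fail"`, `"unknown_word"`, `"no_primer"`,
#'   `"empty_insert"`).
#' @export
trim_to_insert <- function(reads, region, sheet, p = demux_params()) {
  reads <- validate_qreads(reads)
  n <- nrow(reads)
  sample_id <- rep(NA_character_, n)
  status <- rep(NA_character_, n)
  out_bases <- character(n)
  out_quals <- vector("list", n)
  fwd <- region$fwd_primer
  rc_rev <- revcomp(region$rev_primer)
  seqs <- Biostrings::DNAStringSet(if (n) reads$bases else character(0))
  widths <- Biostrings::width(seqs)
  lim <- pmin(widths, p$search_window + nchar(fwd) - 1L)
  fwd_starts <- rep(NA_integer_, n)
  searchable <- which(lim >= nchar(fwd))
  if (length(searchable)) {
    mi <- Biostrings::vmatchPattern(fwd, Biostrings::subseq(seqs[searchable],
                                                            1L, lim[searchable]),
                                    max.mismatch = p$max_mismatch)
    sl <- Biostrings::startIndex(mi)
    hitn <- lengths(sl) > 0L
    fwd_starts[searchable[hitn]] <- vapply(sl[hitn], `[[`, integer(1), 1L)
  }
  # reverse-primer remnant: last match in the region 3' of the fwd primer
  tail_starts <- rep(NA_integer_, n)
  with_fwd <- which(!is.na(fwd_starts))
  if (length(with_fwd)) {
    t_from <- pmin(fwd_starts[with_fwd] + nchar(fwd), widths[with_fwd])
    ok_tail <- widths[with_fwd] - t_from + 1L >= nchar(rc_rev)
    sub_idx <- with_fwd[ok_tail]
    if (length(sub_idx)) {
      mi <- Biostrings::vmatchPattern(
        rc_rev, Biostrings::subseq(seqs[sub_idx], t_from[ok_tail]),
        max.mismatch = p$max_mismatch)
      sl <- Biostrings::startIndex(mi)
      hitn <- lengths(sl) > 0L
      tail_starts[sub_idx[hitn]] <-
        vapply(sl[hitn], function(v) v[length(v)], integer(1)) +
        t_from[ok_tail][hitn] - 1L
    }
  }
  for (i in seq_len(n)) {
    b <- reads$bases[i]
    m <- fwd_starts[i]
    if (is.na(m)) {
      status[i] <- "no_primer"
      next
    }
    if (m < 6L) {                      # word (4) + ligation T (1) must precede
      status[i] <- "word_missing"
      next
    }
    if (substr(b, m - 1L, m - 1L) != "T") {
      status[i] <- "word_missing"      # ligation structure broken
      next
    }
    word <- substr(b, m - 5L, m - 2L)
    dec <- deconvolve(word, sheet)
    status[i] <- dec$status
    if (dec$status != "ok") next
    ins_start <- m + nchar(fwd)
    ins_end <- if (!is.na(tail_starts[i])) tail_starts[i] - 1L else nchar(b)
    if (ins_end < ins_start) {
      status[i] <- "empty_insert"
      next
    }
    sample_id[i] <- dec$sample_id
    out_bases[i] <- substr(b, ins_start, ins_end)
    out_quals[[i]] <- reads$quals[[i]][ins_start:ins_end]
  }
  ok <- which(status == "ok")
  list(
    reads = qualified_reads(reads$read_id[ok], out_bases[ok], out_quals[ok]),
    assignments = tibble::tibble(read_id = reads$read_id,
                                 sample_id = sample_id, status = status)
  )
}
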