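# Quality control: trim low-quality read ends, mask unreliable base calls
# with N, remove short sequences. Masked bases are later ignored by the
# aligner, the allele caller and the error-rate estimator.

#' Quality-control parameters
#'
#' @param mask_quality Phred threshold below which bases are masked to N
#'   (default 15).
#' @param end_window Sliding-window length in bases for end trimming
#'   (default 10).
#' @param end_mean_quality Minimum window mean quality at the read ends
#'   (default 15).
#' @param min_length Minimum read length retained after trimming (default
#'   100 bp).
#' @return A `qc_params` list.
#' @export
qc_params <- function(mask_quality = 15L, end_window = 10L,
                      end_mean_quality = 15, min_length = 100L) {
  stopifnot(mask_quality >= 0, end_window >= 1, end_mean_quality >= 0,
            min_length >= 0)
  structure(list(mask_quality = as.integer(mask_quality),
                 end_window = as.integer(end_window),
                 end_mean_quality = end_mean_quality,
                 min_length = as.integer(min_length)),
            class = "qc_params")
}

# The trimming window advances inward in whole-window steps from each end;
# the slice from the start of the first acceptable left window to the end of
# the first acceptable right window is kept.
trim_ends_one <- function(bases, quals, p) {
  n <- length(quals)
  empty <- list(bases = "", quals = integer(0))
  if (n == 0L) return(empty)
  w <- p$end_window
  start <- NA_integer_
  for (s in seq(1L, n, by = w)) {
    if (mean(quals[s:min(s + w - 1L, n)]) >= p$end_mean_quality) {
      start <- s
      break
    }
  }
  if (is.na(start)) return(empty)
  end <- NA_integer_
  for (e in seq(n, 1L, by = -w)) {
    if (mean(quals[max(e - w + 1L, 1L):e]) >= p$end_mean_quality) {
      end <- e
      break
    }
  }
  if (is.na(end) || end < start) return(empty)
  list(bases = substr(bases, start, end), quals = quals[start:end])
}

#' Trim low-quality read ends
#'
#' From each end, a sliding window of `end_window` bases advances inward
#' until its mean quality reaches `end_mean_quality`; the enclosed slice is
#' kept. A read may be consumed entirely (empty result; removed later by the
#' length filter).
#'
#' @param reads A `qreads` tibble.
#' @param p [qc_params()].
#' @return Trimmed `qreads` tibble (same rows, possibly empty reads).
#' @export
trim_ends <- function(reads, p = qc_params()) {
  reads <- validate_qreads(reads)
  out <- Map(trim_ends_one, reads$bases, reads$quals, list(p))
  reads$bases <- unname(vapply(out, `[[`, character(1), "bases"))
  reads$quals <- unname(lapply(out, `[[`, "quals"))
  validate_qreads(reads)
}

#' Mask unreliable base calls with N
#'
#' Bases whose phred quality is below `mask_quality` are replaced by N.
#' Qualities and read lengths are unchanged.
#'
#' @inheritParams trim_ends
#' @return Masked `qreads` tibble.
#' @export
mask_low_quality <- function(reads, p = qc_params()) {
  reads <- validate_qreads(reads)
  reads$bases <- mapply(function(b, q) {
    low <- which(q < p$mask_quality)
    if (!length(low)) return(b)
    ch <- strsplit(b, "")[[1]]
    ch[low] <- "N"
    paste(ch, collapse = "")
  }, reads$bases, reads$quals, USE.NAMES = FALSE)
  validate_qreads(reads)
}

#' Remove short sequences
#'
#' @inheritParams trim_ends
#' @return A list with `retained` (`qreads` of length >= `min_length`) and
#'   `discarded` (integer count).
#' @export
length_filter <- function(reads, p = qc_params()) {
  reads <- validate_qreads(reads)
  keep <- nchar(reads$bases) >= p$min_length
  list(retained = reads[keep, , drop = FALSE], discarded = sum(!keep))
}

#' Full quality-control pass
#'
#' End trimming, N-masking and length filtering in the standard order.
#'
#' @inheritParams trim_ends
#' @return As [length_filter()].
#' @export
qc_reads <- function(reads, p = qc_params()) {
  length_filter(mask_low_quality(trim_ends(reads, p), p), p)
}
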