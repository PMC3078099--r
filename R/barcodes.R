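BASES <- c("A", "C", "G", "T")

base_index <- function(x) {
  idx <- match(x, BASES) - 1L
  if (anyNA(idx)) {
    stop("non-ACGT symbol in barcode: '", paste(x[is.na(idx)], collapse = ","), "'")
  }
  idx
}

#' Checksum base for a 3-bp barcode
#'
#' The sample barcodes are 3-bp words followed by a checksum base chosen so
#' that the base-index sum of all four positions (A=0, C=1, G=2, T=3) is
#' congruent to 0 modulo 4. Any single-base substitution in the 4-bp word
#' changes the sum modulo 4 and is therefore detectable.
#'
#' @param code A single 3-character string over A/C/G/T.
#' @return A single base ("A", "C", "G" or "T").
#' @examples
#' checksum_base("AAA") # "A"
#' checksum_base("ACG") # "C"
#' @export
checksum_base <- function(code) {
  stopifnot(is.character(code), length(code) == 1L)
  if (nchar(code) != 3L) stop("barcode code must be exactly 3 bases, got '", code, "'")
  idx <- base_index(strsplit(code, "")[[1]])
  BASES[((4L - sum(idx)) %% 4L) + 1L]
}

#' Generate the full checksum-protected barcode vocabulary
#'
#' All 4^3 = 64 valid 4-bp words (3-bp code + checksum base), sorted
#' lexicographically. These are the only 64 of the 256 possible 4-mers whose
#' base-index sum is 0 mod 4.
#'
#' @return Character vector of 64 four-base words.
#' @export
generate_barcode_words <- function() {
  codes <- do.call(paste0, expand.grid(BASES, BASES, BASES,
                                       KEEP.OUT.ATTRS = FALSE,
                                       stringsAsFactors = FALSE)[, 3:1])
  words <- vapply(codes, function(c) paste0(c, checksum_base(c)), character(1),
                  USE.NAMES = FALSE)
  sort(words)
}

#' Validate a 4-bp barcode word against its checksum
#'
#' @param word A single 4-character string over A/C/G/T/N. Words containing
#'   N always fail (an uncalled base cannot be verified).
#' @return `TRUE` if the fourth base equals the checksum of the first three.
#' @export
validate_word <- function(word) {
  stopifnot(is.character(word), length(word) == 1L)
  if (nchar(word) != 4L) stop("barcode word must be exactly 4 bases, got '", word, "'")
  chars <- strsplit(word, "")[[1]]
  if (any(!chars %in% c(BASES, "N"))) {
    stop("barcode word contains symbol outside ACGTN: '", word, "'")
  }
  if (any(chars == "N")) return(FALSE)
  chars[4] == checksum_base(substr(word, 1, 3))
}

#' Read or construct a sample sheet
#'
#' A sample sheet maps valid barcode words to sample identifiers. At most 64
#' entries are possible (the size of the checksum-protected vocabulary).
#'
#' @param words Character vector of 4-bp barcode words.
#' @param sample_ids Character vector of sample identifiers, same length.
#' @return A tibble with columns `word` and `sample_id`.
#' @export
sample_sheet <- function(words, sample_ids) {
  stopifnot(length(words) == length(sample_ids))
  if (length(words) > 64L) stop("sample sheet cannot exceed 64 entries")
  ok <- vapply(words, validate_word, logical(1))
  if (!all(ok)) {
    stop("invalid barcode word(s) in sample sheet: ",
         paste(words[!ok], collapse = ", "))
  }
  if (anyDuplicated(words)) stop("duplicate barcode words in sample sheet")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in sample sheet")
  tibble::tibble(word = as.character(words), sample_id = as.character(sample_ids))
}

#' Assign a read to a sample by its barcode word
#'
#' Looks up the 4-bp word at the 5' end of an oriented read. Matching is
#' exact: reads whose word fails the checksum or is absent from the sheet are
#' rejected, never rescued.
#'
#' @param word The 4-bp word extracted from the read, or `NA` if the read was
#'   too short / started inside the primer.
#' @param sheet A sample sheet tibble (`word`, `sample_id`).
#' @return A list with `sample_id` (or `NA`) and `status`, one of
#'   `"ok"`, `"checksum_fail"`, `"unknown_word"`, `"word_missing"`.
#' @export
deconvolve <- function(word, sheet) {
  if (is.null(word) || is.na(word) || nchar(word) != 4L) {
    return(list(sample_id = NA_character_, status = "word_missing"))
  }
  chars <- strsplit(word, "")[[1]]
  if (any(!chars %in% c(BASES, "N")) || !validate_word(word)) {
    return(list(sample_id = NA_character_, status = "checksum_fail"))
  }
  hit <- match(word, sheet$word)
  if (is.na(hit)) {
    return(list(sample_id = NA_character_, status = "unknown_word"))
  }
  list(sample_id = sheet$sample_id[hit], status = "ok")
}
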