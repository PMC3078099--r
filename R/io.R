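# Read container and file formats: FASTA + 454-style .qual, FASTQ
# (Sanger phred+33), sample sheets and gene-region tables as headered TSV.

#' Construct a set of qualified reads
#'
#' The in-memory read container is a tibble with one row per read:
#' `read_id` (character), `bases` (character over A/C/G/T/N) and `quals`
#' (list of integer phred scores, one per base, each in 0..93).
#'
#' @param read_id Character vector of unique read identifiers.
#' @param bases Character vector of base strings.
#' @param quals List of integer vectors, one per read, or a single integer
#'   recycled to a constant quality for every base.
#' @return A `qreads` tibble.
#' @export
qualified_reads <- function(read_id, bases, quals = 30L) {
  read_id <- as.character(read_id)
  bases <- toupper(as.character(bases))
  stopifnot(length(read_id) == length(bases))
  if (!is.list(quals)) {
    quals <- lapply(nchar(bases), function(n) rep(as.integer(quals), n))
  }
  stopifnot(length(quals) == length(bases))
  quals <- lapply(quals, as.integer)
  x <- tibble::tibble(read_id = read_id, bases = bases, quals = quals)
  validate_qreads(x)
}

validate_qreads <- function(x) {
  stopifnot(is.data.frame(x), all(c("read_id", "bases", "quals") %in% names(x)))
  bad <- regexpr("[^ACGTN]", x$bases)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1]
    stop("read '", x$read_id[i], "' contains non-ACGTN symbol '",
         substr(x$bases[i], bad[i], bad[i]), "' at position ", bad[i])
  }
  len_ok <- nchar(x$bases) == lengths(x$quals)
  if (!all(len_ok)) {
    stop("read '", x$read_id[which(!len_ok)[1]],
         "': base and quality lengths differ")
  }
  rng <- unlist(x$quals, use.names = FALSE)
  if (length(rng) && (min(rng) < 0L || max(rng) > 93L)) {
    stop("quality scores must be integers in [0, 93]")
  }
  class(x) <- unique(c("qreads", class(x)))
  x
}

first_token <- function(x) sub("\\s.*$", "", x)

parse_qual_file <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr) && length(lines)) stop("QUAL file has no '>' records: ", path)
  rec <- cumsum(hdr)
  ids <- first_token(sub("^>", "", lines[hdr]))
  vals <- lapply(split(lines[!hdr], rec[!hdr]), function(ls) {
    as.integer(scan(text = paste(ls, collapse = " "), quiet = TRUE))
  })
  # records with no value lines (empty reads) still need an entry
  out <- rep(list(integer(0)), length(ids))
  present <- as.integer(names(vals))
  out[present] <- vals
  names(out) <- ids
  out
}

#' Read sequences from FASTA(+QUAL) or FASTQ
#'
#' Accepts either a FASTA file with an optional 454-style `.qual` companion
#' (per-base phred scores as whitespace-separated integers under matching
#' `>` headers), or a FASTQ file (phred+33). When a FASTA comes without a
#' QUAL file, every base receives a constant default quality and a warning
#' is issued.
#'
#' @param path Path to the FASTA or FASTQ file.
#' @param qual_path Optional path to the companion QUAL file (FASTA input
#'   only). Record ids must pair one-to-one, in order, with the FASTA ids.
#' @param default_qual Constant quality used when no QUAL file is given
#'   (default 30).
#' @return A `qreads` tibble (see [qualified_reads()]).
#' @export
read_sequences <- function(path, qual_path = NULL, default_qual = 30L) {
  if (!file.exists(path)) stop("no such file: ", path)
  head_line <- readLines(path, n = 1L)
  if (length(head_line) == 0L) {
    return(qualified_reads(character(0), character(0), list()))
  }
  first <- substr(head_line, 1, 1)
  if (identical(first, "@") && is.null(qual_path)) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
    quals <- lapply(as.character(S4Vectors::mcols(x)$qualities),
                    function(q) utf8ToInt(q) - 33L)
    return(qualified_reads(first_token(names(x)), as.character(x), quals))
  }
  x <- Biostrings::readBStringSet(path)
  ids <- first_token(names(x))
  bases <- toupper(as.character(x))
  if (is.null(qual_path)) {
    warning("no QUAL file given for ", path, "; assuming constant quality ",
            default_qual)
    return(qualified_reads(ids, bases, default_qual))
  }
  qrecs <- parse_qual_file(qual_path)
  if (length(qrecs) != length(ids) || any(names(qrecs) != ids)) {
    off <- if (length(qrecs) != length(ids)) {
      ids[min(length(qrecs) + 1L, length(ids))]
    } else {
      ids[which(names(qrecs) != ids)[1]]
    }
    stop("FASTA/QUAL record ids do not pair: first offending record '",
         off, "'")
  }
  qualified_reads(ids, bases, unname(qrecs))
}

#' Write sequences to FASTQ or FASTA(+QUAL)
#'
#' Inverse of [read_sequences()]: `read_sequences(write_sequences(x))`
#' reproduces ids, bases and qualities exactly.
#'
#' @param reads A `qreads` tibble.
#' @param path Output FASTA/FASTQ path.
#' @param format `"fastq"` or `"fasta"`.
#' @param qual_path QUAL output path; defaults to `path` with a `.qual`
#'   extension when `format = "fasta"`.
#' @return Invisibly, the paths written.
#' @export
write_sequences <- function(reads, path, format = c("fastq", "fasta"),
                            qual_path = NULL) {
  format <- match.arg(format)
  reads <- validate_qreads(reads)
  seqs <- Biostrings::DNAStringSet(if (nrow(reads)) reads$bases else character(0))
  names(seqs) <- reads$read_id
  if (format == "fastq") {
    qmax <- if (nrow(reads)) suppressWarnings(max(c(unlist(reads$quals), 0L))) else 0L
    if (qmax > 93L) stop("quality score ", qmax, " exceeds FASTQ range [0, 93]")
    qstr <- vapply(reads$quals, function(q) intToUtf8(q + 33L), character(1))
    Biostrings::writeXStringSet(seqs, path, format = "fastq",
                                qualities = Biostrings::BStringSet(qstr))
    return(invisible(path))
  }
  Biostrings::writeXStringSet(seqs, path, format = "fasta")
  if (is.null(qual_path)) qual_path <- paste0(sub("\\.[^.]*$", "", path), ".qual")
  con <- file(qual_path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(reads))) {
    writeLines(c(paste0(">", reads$read_id[i]),
                 paste(reads$quals[[i]], collapse = " ")), con)
  }
  invisible(c(path, qual_path))
}

#' Read a sample sheet TSV
#'
#' Headered TSV with columns `word` (4-bp checksum-protected barcode) and
#' `sample_id`.
#'
#' @param path TSV path.
#' @return Validated sample-sheet tibble.
#' @export
read_sample_sheet <- function(path) {
  d <- utils::read.delim(path, colClasses = "character")
  stopifnot(all(c("word", "sample_id") %in% names(d)))
  sample_sheet(d$word, d$sample_id)
}

#' Read a gene-region table TSV
#'
#' Headered TSV with columns `name`, `fwd_primer`, `rev_primer`,
#' `expected_len` (bp) and `expected_copies` (1 for plastid regions, 2 for
#' nuclear homeologue pairs).
#'
#' @param path TSV path.
#' @return Region tibble.
#' @export
read_region_table <- function(path) {
  d <- utils::read.delim(path, colClasses = "character")
  stopifnot(all(c("name", "fwd_primer", "rev_primer", "expected_copies") %in% names(d)))
  gene_regions(d$name, toupper(d$fwd_primer), toupper(d$rev_primer),
               if ("expected_len" %in% names(d)) as.integer(d$expected_len) else NA_integer_,
               as.integer(d$expected_copies))
}

#' Construct a gene-region table
#'
#' @param name Region names (unique).
#' @param fwd_primer,rev_primer Uppercase ACGT primer sequences.
#' @param expected_len Expected amplicon length in bp (may be `NA`).
#' @param expected_copies 1 (single-copy, e.g. plastid) or 2 (nuclear
#'   homeologue pair).
#' @return Region tibble.
#' @export
gene_regions <- function(name, fwd_primer, rev_primer, expected_len = NA_integer_,
                         expected_copies = 1L) {
  stopifnot(!anyDuplicated(name))
  if (any(!grepl("^[ACGT]+$", fwd_primer)) || any(!grepl("^[ACGT]+$", rev_primer))) {
    stop("primers must be nonempty uppercase ACGT strings")
  }
  if (!all(expected_copies %in% c(1L, 2L))) stop("expected_copies must be 1 or 2")
  tibble::tibble(name = as.character(name), fwd_primer = fwd_primer,
                 rev_primer = rev_primer,
                 expected_len = as.integer(expected_len),
                 expected_copies = as.integer(expected_copies))
}

#' Write a tibble as headered TSV
#' @param x Data frame. @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv_report <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
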