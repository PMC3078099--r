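# Star multiple alignment of one (sample, region) read group: the longest
# read is the pivot, every other read is pairwise-aligned to it with affine
# gap penalties, and the pairwise alignments are merged column-wise. N is
# scored as neutral (neither match nor mismatch) so masked bases never repel
# an alignment.

star_submat <- function() {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(-4, 5, 5, dimnames = list(letters, letters))
  diag(m) <- 2
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

#' Build a read group
#'
#' @param reads A `qreads` tibble of trimmed inserts.
#' @param sample,region Group identity.
#' @return A `read_group` list.
#' @export
read_group <- function(reads, sample = NA_character_, region = NA_character_) {
  reads <- validate_qreads(reads)
  structure(list(sample = sample, region = region, reads = reads),
            class = "read_group")
}

# parse one pairwise alignment (pattern row, subject row, subject start) into
# per-pivot-position characters and insertions keyed by preceding pivot position
project_onto_pivot <- function(pat, sub, sub_start, pivot_len) {
  pc <- strsplit(pat, "")[[1]]
  sc <- strsplit(sub, "")[[1]]
  cell <- rep("-", pivot_len)
  ins <- list()
  j <- sub_start - 1L            # last pivot position consumed
  buf <- character(0)
  for (k in seq_along(sc)) {
    if (sc[k] == "-") {
      buf <- c(buf, pc[k])       # insertion relative to pivot
    } else {
      if (length(buf)) {
        ins[[as.character(j)]] <- paste(buf, collapse = "")
        buf <- character(0)
      }
      j <- j + 1L
      cell[j] <- pc[k]
    }
  }
  if (length(buf)) ins[[as.character(j)]] <- paste(buf, collapse = "")
  list(cell = cell, ins = ins)
}

#' Star multiple alignment of a read group
#'
#' @param group A [read_group()] (>= 1 read).
#' @return A `group_alignment` list: `sample`, `region`, `ids`, `rows`
#'   (equal-length gapped strings over A/C/G/T/N/-), `mean_qual` (per read).
#'   Ungapping row i reproduces read i's bases.
#' @export
align_group <- function(group) {
  stopifnot(inherits(group, "read_group"))
  reads <- group$reads
  stopifnot(nrow(reads) >= 1L)
  mean_qual <- vapply(reads$quals, function(q) if (length(q)) mean(q) else 0,
                      numeric(1))
  ord <- order(-nchar(reads$bases), reads$read_id)
  pivot <- ord[1]
  others <- setdiff(seq_len(nrow(reads)), pivot)
  pivot_len <- nchar(reads$bases[pivot])
  proj <- vector("list", nrow(reads))
  proj[[pivot]] <- list(cell = strsplit(reads$bases[pivot], "")[[1]],
                        ins = list())
  if (length(others)) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(reads$bases[others]),
      subject = Biostrings::DNAString(reads$bases[pivot]),
      type = "global-local", substitutionMatrix = star_submat(),
      gapOpening = 6, gapExtension = 1)
    # pattern()/subject() give the gapped alignment strings directly; with
    # type = "global-local" the pattern is never clipped
    pats <- as.character(Biostrings::pattern(aln))
    subs <- as.character(Biostrings::subject(aln))
    starts <- Biostrings::start(Biostrings::subject(aln))
    for (k in seq_along(others)) {
      proj[[others[k]]] <- project_onto_pivot(pats[k], subs[k], starts[k],
                                              pivot_len)
    }
  }
  ins_len <- integer(pivot_len + 1L)   # insertion slot after pivot position 0..L
  for (pr in proj) {
    for (key in names(pr$ins)) {
      slot <- as.integer(key) + 1L
      ins_len[slot] <- max(ins_len[slot], nchar(pr$ins[[key]]))
    }
  }
  rows <- vapply(proj, function(pr) {
    pieces <- character(0)
    for (j in 0:pivot_len) {
      if (ins_len[j + 1L] > 0L) {
        s <- pr$ins[[as.character(j)]]
        if (is.null(s)) s <- ""
        pieces <- c(pieces, formatC(s, width = -ins_len[j + 1L], flag = "-"))
      }
      if (j < pivot_len) pieces <- c(pieces, pr$cell[j + 1L])
    }
    gsub(" ", "-", paste(pieces, collapse = ""))
  }, character(1))
  structure(list(sample = group$sample, region = group$region,
                 ids = reads$read_id, rows = rows, mean_qual = mean_qual),
            class = "group_alignment")
}

#' Alignment rows as a character matrix
#' @param aln A `group_alignment`.
#' @return Matrix (reads x columns) of single characters.
#' @export
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$rows, ""))
  rownames(m) <- aln$ids
  m
}

# majority character per column; N excluded; ties resolved by the mean
# quality of the supporting rows, then alphabetically ("-" sorts last)
column_consensus <- function(mat, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(mat))
  chars <- c("A", "C", "G", "T", "-")   # tie-break order: bases, then gap
  L <- ncol(mat)
  cnt <- matrix(0L, length(chars), L)
  wsum <- matrix(0, length(chars), L)
  for (i in seq_along(chars)) {
    hit <- mat == chars[i]
    cnt[i, ] <- colSums(hit)
    wsum[i, ] <- colSums(hit * weights)
  }
  vapply(seq_len(L), function(j) {
    cj <- cnt[, j]
    if (all(cj == 0L)) return("N")
    top <- which(cj == max(cj))
    if (length(top) > 1L) {
      mq <- wsum[top, j] / cj[top]
      top <- top[mq == max(mq)]
    }
    chars[top[1]]
  }, character(1))
}

ungap <- function(x) gsub("-", "", x)

# per-column flag: inside a mononucleotide run > `min_run` bp, measured on
# the ungapped consensus and mapped back to alignment columns
homopolymer_columns <- function(consensus_chars, min_run = 5L) {
  non_gap <- which(consensus_chars != "-")
  flag <- rep(FALSE, length(consensus_chars))
  if (length(non_gap) == 0L) return(flag)
  bases <- consensus_chars[non_gap]
  r <- rle(bases)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$lengths > min_run & r$values %in% c("A", "C", "G", "T"))) {
    flag[non_gap[starts[k]:ends[k]]] <- TRUE
  }
  flag
}
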