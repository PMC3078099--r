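# PCR-recombinant (chimera) detection by the two-criterion rule:
# (1) the candidate occurs in a minority of the group's reads, and
# (2) one end matches one common allele and the other end a different
# common allele, while no single common allele explains the whole candidate.

#' Chimera-scan parameters
#'
#' @param minority_threshold Candidates must hold less than this fraction of
#'   the group's reads (default 0.05, exclusive).
#' @param parent_tolerance Maximum mismatches allowed against a parent per
#'   matched segment (default 1).
#' @param min_segment Minimum bases matched to each parent (default 30).
#' @return A `chimera_params` list.
#' @export
chimera_params <- function(minority_threshold = 0.05, parent_tolerance = 1L,
                           min_segment = 30L) {
  stopifnot(minority_threshold > 0, minority_threshold < 1,
            parent_tolerance >= 0L, min_segment >= 1L)
  structure(list(minority_threshold = minority_threshold,
                 parent_tolerance = as.integer(parent_tolerance),
                 min_segment = as.integer(min_segment)),
            class = "chimera_params")
}

#' Scan a group's allele calls for PCR recombinants
#'
#' Candidates are calls holding less than `minority_threshold` of the
#' group's reads (including `low_support`-flagged calls); common alleles are
#' the unflagged calls at or above the threshold. All sequences are aligned
#' together; a candidate is a recombinant iff for some breakpoint its prefix
#' matches one common allele within `parent_tolerance` mismatches over at
#' least `min_segment` compared bases, its suffix matches a different common
#' allele likewise, and no single common allele matches the whole candidate
#' within `2 * parent_tolerance` mismatches. The reported breakpoint
#' interval is the 1-based closed range of alignment columns after which a
#' valid junction can lie.
#'
#' @param calls Allele-call tibble for one (sample, region) group.
#' @param p [chimera_params()].
#' @return Tibble of reports: `candidate`, `parent_1`, `parent_2`,
#'   `breakpoint_start`, `breakpoint_end`, `verdict`
#'   (`"recombinant"`/`"clean"`).
#' @export
detect_recombinants <- function(calls, p = chimera_params()) {
  empty <- tibble::tibble(candidate = character(0), parent_1 = character(0),
                          parent_2 = character(0),
                          breakpoint_start = integer(0),
                          breakpoint_end = integer(0), verdict = character(0))
  common <- which(!calls$low_support & calls$fraction >= p$minority_threshold)
  cand <- which(calls$fraction < p$minority_threshold)
  if (length(common) < 2L || length(cand) == 0L) return(empty)
  idx <- c(common, cand)
  ids <- calls$allele_label[idx]
  grp <- read_group(qualified_reads(ids, calls$consensus[idx]))
  mat <- alignment_matrix(align_group(grp))
  mat <- mat[match(ids, rownames(mat)), , drop = FALSE]
  ncol_a <- ncol(mat)
  out <- empty
  for (ci in seq_along(cand)) {
    cand_row <- mat[length(common) + ci, ]
    label <- calls$allele_label[cand[ci]]
    # per-parent column-wise mismatch / compared indicators
    mm <- list()
    cmpd <- list()
    whole_ok <- FALSE
    for (pi in seq_along(common)) {
      par_row <- mat[pi, ]
      comparable <- cand_row != "N" & par_row != "N" &
        !(cand_row == "-" & par_row == "-")
      mismatch <- comparable & cand_row != par_row
      mm[[pi]] <- cumsum(mismatch)
      cmpd[[pi]] <- cumsum(comparable & !mismatch)
      if (sum(mismatch) <= 2L * p$parent_tolerance) whole_ok <- TRUE
    }
    verdict_row <- tibble::tibble(candidate = label, parent_1 = NA_character_,
                                  parent_2 = NA_character_,
                                  breakpoint_start = NA_integer_,
                                  breakpoint_end = NA_integer_,
                                  verdict = "clean")
    if (!whole_ok) {
      best <- NULL
      for (x in seq_along(common)) {
        for (y in seq_along(common)) {
          if (x == y) next
          # breakpoint after column k: prefix 1..k vs parent x, suffix vs y
          ks <- seq_len(ncol_a - 1L)
          pre_mm <- mm[[x]][ks]
          pre_match <- cmpd[[x]][ks]
          suf_mm <- mm[[y]][ncol_a] - mm[[y]][ks]
          suf_match <- cmpd[[y]][ncol_a] - cmpd[[y]][ks]
          valid <- pre_mm <= p$parent_tolerance &
            suf_mm <= p$parent_tolerance &
            pre_match >= p$min_segment & suf_match >= p$min_segment
          if (any(valid)) {
            span <- range(ks[valid])
            if (is.null(best) || sum(valid) > best$n_valid) {
              best <- list(x = x, y = y, span = span, n_valid = sum(valid))
            }
          }
        }
      }
      if (!is.null(best)) {
        verdict_row <- tibble::tibble(
          candidate = label,
          parent_1 = calls$allele_label[common[best$x]],
          parent_2 = calls$allele_label[common[best$y]],
          breakpoint_start = best$span[1],
          breakpoint_end = best$span[2],
          verdict = "recombinant")
      }
    }
    out <- rbind(out, verdict_row)
  }
  out
}
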