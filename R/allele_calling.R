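# Allele calling for homeologous loci: cluster the reads of one
# (sample, region) alignment into haplotypes, require distinct alleles to
# differ consistently at >= min_diff base positions in more than
# `consistency` of the supporting reads, partition alleles into the two gene
# copies of an allopolyploid, and code indels for distance analyses.

#' Allele-calling parameters
#'
#' @param min_diff Minimum number of differing base positions between
#'   distinct alleles (default 2).
#' @param consistency Fraction of supporting reads that must carry an
#'   allele's base at each distinguishing column (default 0.80; the rule is
#'   strictly "more than" this fraction).
#' @param min_support Minimum reads supporting an unflagged allele
#'   (default 2).
#' @param minor_fraction_floor Alleles below this fraction of the group's
#'   reads are flagged `low_support` and handed to the chimera scanner
#'   (default 0.05, exclusive).
#' @return An `allele_params` list.
#' @export
allele_params <- function(min_diff = 2L, consistency = 0.80,
                          min_support = 2L, minor_fraction_floor = 0.05) {
  stopifnot(min_diff >= 1L, consistency > 0, consistency <= 1,
            min_support >= 1L, minor_fraction_floor >= 0,
            minor_fraction_floor < 1)
  structure(list(min_diff = as.integer(min_diff), consistency = consistency,
                 min_support = as.integer(min_support),
                 minor_fraction_floor = minor_fraction_floor),
            class = "allele_params")
}

# columns with >= 2 distinct non-N states (gap counts as a state)
variable_columns <- function(mat) {
  which(apply(mat, 2L, function(col) {
    length(unique(col[col != "N"])) >= 2L
  }))
}

# greedy N-insensitive haplotype grouping over the variable columns:
# reads are seeded in order of informativeness; a read joins the first
# cluster whose profile it does not contradict at any non-N position
group_haplotypes <- function(mat, var_cols, mean_qual) {
  n <- nrow(mat)
  if (length(var_cols) == 0L) return(rep(1L, n))
  sub <- mat[, var_cols, drop = FALSE]
  informative <- rowSums(sub != "N")
  ord <- order(-informative, -mean_qual, rownames(mat))
  profiles <- list()
  members <- list()
  assignment <- integer(n)
  for (i in ord) {
    row <- sub[i, ]
    placed <- FALSE
    for (cl in seq_along(profiles)) {
      pr <- profiles[[cl]]
      cmp <- row != "N" & pr != "N"
      if (all(row[cmp] == pr[cmp])) {
        pr[pr == "N"] <- row[pr == "N"]
        profiles[[cl]] <- pr
        members[[cl]] <- c(members[[cl]], i)
        assignment[i] <- cl
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      profiles[[length(profiles) + 1L]] <- row
      members[[length(members) + 1L]] <- i
      assignment[i] <- length(profiles)
    }
  }
  assignment
}

# count columns where two consensus strings differ, both non-N, optionally
# skipping homopolymer columns
consensus_diff <- function(c1, c2, skip = NULL) {
  cmp <- c1 != "N" & c2 != "N" & c1 != c2
  if (!is.null(skip)) cmp <- cmp & !skip
  sum(cmp)
}

#' Call distinct alleles from a group alignment
#'
#' Reads are grouped into haplotypes over the variable columns (N is
#' wildcard), cluster consensi are computed (majority base per column, N
#' excluded, ties broken by supporting-read mean quality then
#' alphabetically), clusters closer than `min_diff` non-homopolymer base
#' positions to a larger cluster are merged, and a surviving cluster is kept
#' distinct only if more than `consistency` of its gap-free, non-N member
#' reads carry the cluster base at every distinguishing column. Clusters
#' below `min_support` reads or below `minor_fraction_floor` of the group
#' are emitted flagged `low_support` (candidates for the chimera scanner).
#'
#' @param aln A `group_alignment` from [align_group()].
#' @param p [allele_params()].
#' @param expected_copies Expected gene copies (1 or 2); more than
#'   `2 * expected_copies` unflagged alleles triggers a warning.
#' @return Tibble of allele calls: `sample`, `region`, `allele_label`,
#'   `consensus` (ungapped), `aligned_consensus`, `support_count`,
#'   `supporting_read_ids` (list), `fraction`, `copy_label`, `low_support`.
#' @export
call_alleles <- function(aln, p = allele_params(), expected_copies = 2L) {
  stopifnot(inherits(aln, "group_alignment"))
  if (length(aln$ids) == 0L) return(empty_allele_calls())
  mat <- alignment_matrix(aln)
  full_cons <- column_consensus(mat, aln$mean_qual)
  hp_cols <- homopolymer_columns(full_cons)
  var_cols <- variable_columns(mat)
  assignment <- group_haplotypes(mat, var_cols, aln$mean_qual)

  cluster_consensus <- function(idx) {
    column_consensus(mat[idx, , drop = FALSE], aln$mean_qual[idx])
  }
  clusters <- split(seq_len(nrow(mat)), assignment)
  consensi <- lapply(clusters, cluster_consensus)

  # iteratively merge clusters whose consensus is within min_diff
  # non-homopolymer base positions of a larger (or equal, later-ranked)
  # cluster's consensus
  repeat {
    sizes <- lengths(clusters)
    if (length(clusters) <= 1L) break
    ord <- order(sizes, seq_along(clusters))   # smallest first
    merged <- FALSE
    for (ci in ord) {
      targets <- which(sizes > sizes[ci] | (sizes == sizes[ci] &
                                            seq_along(sizes) < ci))
      if (!length(targets)) next
      d <- vapply(targets, function(tj) {
        consensus_diff(consensi[[ci]], consensi[[tj]], skip = hp_cols)
      }, numeric(1))
      if (min(d) < p$min_diff) {
        tj <- targets[which.min(d)]
        clusters[[tj]] <- c(clusters[[tj]], clusters[[ci]])
        consensi[[tj]] <- cluster_consensus(clusters[[tj]])
        clusters[[ci]] <- NULL    # removal last: keeps tj valid above
        consensi[[ci]] <- NULL
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }

  # consistency rule: at each column distinguishing a cluster from another
  # surviving cluster, more than `consistency` of the cluster's gap-free,
  # non-N reads must carry the cluster base; failing clusters merge into
  # their nearest larger cluster
  repeat {
    if (length(clusters) <= 1L) break
    sizes <- lengths(clusters)
    failed <- NA_integer_
    for (ci in order(sizes, seq_along(clusters))) {
      others <- setdiff(seq_along(clusters), ci)
      if (!length(others)) next
      distinguishing <- sort(unique(unlist(lapply(others, function(oj) {
        which(consensi[[ci]] != "N" & consensi[[oj]] != "N" &
              consensi[[ci]] != consensi[[oj]] & !hp_cols)
      }))))
      ok <- all(vapply(distinguishing, function(col) {
        obs <- mat[clusters[[ci]], col]
        obs <- obs[obs != "N" & obs != "-"]
        cons_ch <- consensi[[ci]][col]
        if (cons_ch == "-") return(TRUE)   # gap support tracked by the block
        if (!length(obs)) return(TRUE)
        mean(obs == cons_ch) > p$consistency
      }, logical(1)))
      if (!ok) {
        failed <- ci
        break
      }
    }
    if (is.na(failed)) break
    sizes <- lengths(clusters)
    targets <- setdiff(seq_along(clusters), failed)
    d <- vapply(targets, function(tj) {
      consensus_diff(consensi[[failed]], consensi[[tj]], skip = hp_cols)
    }, numeric(1))
    tj <- targets[order(d, -sizes[targets])[1]]
    clusters[[tj]] <- c(clusters[[tj]], clusters[[failed]])
    consensi[[tj]] <- cluster_consensus(clusters[[tj]])
    clusters[[failed]] <- NULL    # removal last: keeps tj valid above
    consensi[[failed]] <- NULL
  }

  n_total <- nrow(mat)
  ord <- order(-lengths(clusters))
  calls <- tibble::tibble(
    sample = aln$sample,
    region = aln$region,
    allele_label = paste0("al", seq_along(ord)),
    consensus = unname(vapply(consensi[ord],
                              function(cc) ungap(paste(cc, collapse = "")),
                              character(1))),
    aligned_consensus = unname(vapply(consensi[ord], paste, character(1),
                                      collapse = "")),
    support_count = unname(lengths(clusters)[ord]),
    supporting_read_ids = unname(lapply(clusters[ord],
                                        function(idx) aln$ids[idx])),
    fraction = unname(lengths(clusters)[ord] / n_total)
  )
  calls$copy_label <- "unassigned"
  calls$low_support <- calls$support_count < p$min_support |
    calls$fraction < p$minor_fraction_floor
  n_unflagged <- sum(!calls$low_support)
  if (n_unflagged > 2L * expected_copies) {
    warning(sprintf("%s/%s: %d unflagged alleles exceed the %d expected",
                    aln$sample, aln$region, n_unflagged, 2L * expected_copies))
  }
  calls
}

empty_allele_calls <- function() {
  tibble::tibble(sample = character(0), region = character(0),
                 allele_label = character(0), consensus = character(0),
                 aligned_consensus = character(0), support_count = integer(0),
                 supporting_read_ids = list(), fraction = numeric(0),
                 copy_label = character(0), low_support = logical(0))
}

#' Fixed differences and shared polymorphisms between two allele groups
#'
#' Over aligned consensus sequences of equal column count: a fixed
#' difference is a column at which every member of group A carries one base
#' and every member of group B a different base (gap-involved columns are
#' excluded from the base count and tallied separately as indel columns); a
#' shared polymorphism is a column polymorphic within both groups with the
#' same segregating bases.
#'
#' @param group_a,group_b Character vectors of aligned sequences (equal
#'   nchar across all).
#' @return List with `fixed`, `shared` and `indel_columns` (columns with a
#'   fixed gap/base difference).
#' @export
fixed_differences <- function(group_a, group_b) {
  all_seq <- c(group_a, group_b)
  if (length(unique(nchar(all_seq))) != 1L) {
    stop("aligned sequences must have equal column counts")
  }
  ma <- do.call(rbind, strsplit(group_a, ""))
  mb <- do.call(rbind, strsplit(group_b, ""))
  fixed <- 0L
  shared <- 0L
  indel_cols <- integer(0)
  for (j in seq_len(ncol(ma))) {
    sa <- unique(ma[, j])
    sb <- unique(mb[, j])
    sa <- sa[sa != "N"]
    sb <- sb[sb != "N"]
    if (!length(sa) || !length(sb)) next
    if (length(sa) == 1L && length(sb) == 1L && sa != sb) {
      if (sa == "-" || sb == "-") {
        indel_cols <- c(indel_cols, j)
      } else {
        fixed <- fixed + 1L
      }
    } else if (length(sa) >= 2L && setequal(sa, sb)) {
      shared <- shared + 1L
    }
  }
  list(fixed = fixed, shared = shared, indel_columns = indel_cols)
}

#' Partition a region's alleles into homeologous copies A and B
#'
#' Aligns all allele consensi of one region across samples, clusters them by
#' single linkage on pairwise base differences, and cuts into two groups.
#' The group with more total supporting reads is labelled "B" (the
#' more-amplified copy). Reports fixed differences, shared polymorphisms
#' and diagnostic indel blocks between the copies. When the between-group
#' separation does not exceed the configured floor, all alleles are left
#' unassigned with a warning.
#'
#' @param calls Allele-call tibble for one region (all samples), as from
#'   [call_alleles()]; flagged `low_support` calls are ignored.
#' @param separation_floor Required ratio of between-group mean distance to
#'   within-group maximum distance (default 2).
#' @return A list: `calls` (input with `copy_label` filled),
#'   `fixed_difference_count`, `shared_polymorphism_count`,
#'   `diagnostic_indels` (tibble: `start`, `end`, `length`, 1-based closed
#'   alignment columns), `separable`.
#' @export
partition_copies <- function(calls, separation_floor = 2) {
  use <- which(!calls$low_support)
  if (length(use) < 2L) {
    calls$copy_label <- "unassigned"
    warning("fewer than 2 unflagged alleles; copies not separable")
    return(list(calls = calls, fixed_difference_count = NA_integer_,
                shared_polymorphism_count = NA_integer_,
                diagnostic_indels = empty_indel_tbl(), separable = FALSE))
  }
  seqs <- calls$consensus[use]
  grp <- read_group(qualified_reads(sprintf("allele%03d", seq_along(seqs)), seqs),
                    sample = "*", region = calls$region[1])
  aln <- align_group(grp)
  mat <- alignment_matrix(aln)
  ord <- match(sprintf("allele%03d", seq_along(seqs)), aln$ids)
  mat <- mat[ord, , drop = FALSE]     # restore input order
  nseq <- length(seqs)
  dmat <- matrix(0, nseq, nseq)
  for (i in seq_len(nseq - 1L)) {
    for (j in (i + 1L):nseq) {
      ci <- mat[i, ]
      cj <- mat[j, ]
      dmat[i, j] <- dmat[j, i] <-
        sum(ci != cj & ci != "N" & cj != "N" & ci != "-" & cj != "-")
    }
  }
  hc <- hclust(stats::as.dist(dmat), method = "single")
  side <- cutree(hc, k = 2L)
  within <- dmat[outer(side, side, "==") & upper.tri(dmat)]
  between <- dmat[outer(side, side, "!=")]
  within_max <- if (length(within)) max(within) else 0
  between_mean <- mean(between)
  separable <- between_mean > 0 && between_mean >= separation_floor * within_max
  if (!separable) {
    calls$copy_label <- "unassigned"
    warning("region ", calls$region[1], ": copies not separable")
    return(list(calls = calls, fixed_difference_count = NA_integer_,
                shared_polymorphism_count = NA_integer_,
                diagnostic_indels = empty_indel_tbl(), separable = FALSE))
  }
  support <- tapply(calls$support_count[use], side, sum)
  b_side <- as.integer(names(support)[which.max(support)])
  labels <- ifelse(side == b_side, "B", "A")
  calls$copy_label[use] <- labels
  rows_a <- apply(mat[labels == "A", , drop = FALSE], 1L, paste, collapse = "")
  rows_b <- apply(mat[labels == "B", , drop = FALSE], 1L, paste, collapse = "")
  fd <- fixed_differences(rows_a, rows_b)
  indels <- empty_indel_tbl()
  if (length(fd$indel_columns)) {
    blocks <- split(fd$indel_columns,
                    cumsum(c(TRUE, diff(fd$indel_columns) != 1L)))
    indels <- tibble::tibble(
      start = unname(vapply(blocks, min, integer(1))),
      end = unname(vapply(blocks, max, integer(1))),
      length = unname(vapply(blocks, length, integer(1)))
    )
  }
  list(calls = calls, fixed_difference_count = fd$fixed,
       shared_polymorphism_count = fd$shared, diagnostic_indels = indels,
       separable = TRUE)
}

empty_indel_tbl <- function() {
  tibble::tibble(start = integer(0), end = integer(0), length = integer(0))
}

#' Code indels as binary characters appended to an alignment
#'
#' Each scored indel (a gap block shared with identical start and end
#' columns) appends one column to every sequence: `a` when the indel is
#' absent, `c` when present, weighting indels as transversions in downstream
#' distance analyses. Length variation inside mononucleotide runs longer
#' than 5 bp is not scored (no reliable consensus in such regions), and
#' indels observed in a single sequence are not scored (possible PCR
#' artefacts).
#'
#' @param rows Named character vector of aligned sequences (>= 2, equal
#'   nchar).
#' @param max_homopolymer Runs longer than this are excluded (default 5).
#' @return List: `extended` (sequences with appended a/c codes), `indels`
#'   (tibble: `start`, `end`, `length`, `carriers` list).
#' @export
code_indels <- function(rows, max_homopolymer = 5L) {
  stopifnot(length(rows) >= 2L, length(unique(nchar(rows))) == 1L)
  mat <- do.call(rbind, strsplit(rows, ""))
  cons <- column_consensus(mat)
  # gap blocks per sequence, keyed by start:end
  blocks <- list()
  for (i in seq_len(nrow(mat))) {
    g <- rle(mat[i, ] == "-")
    ends <- cumsum(g$lengths)
    starts <- ends - g$lengths + 1L
    for (k in which(g$values)) {
      key <- paste(starts[k], ends[k], sep = ":")
      blocks[[key]] <- c(blocks[[key]], i)
    }
  }
  starts <- integer(0)
  ends <- integer(0)
  carrier_sets <- list()
  codes <- NULL
  for (key in names(blocks)) {
    se <- as.integer(strsplit(key, ":")[[1]])
    carriers <- blocks[[key]]
    non_carriers <- setdiff(seq_len(nrow(mat)), carriers)
    if (length(carriers) < 2L || length(non_carriers) < 2L) next  # singleton event
    # homopolymer exclusion: if the block's non-carrier content is a single
    # repeated base and the surrounding consensus run exceeds the limit
    content <- unique(as.vector(mat[non_carriers, se[1]:se[2]]))
    content <- content[!content %in% c("N", "-")]
    if (length(content) == 1L) {
      run <- block_run_length(cons, se[1], se[2], content)
      if (run > max_homopolymer) next
    }
    col <- ifelse(seq_len(nrow(mat)) %in% carriers, "c", "a")
    codes <- cbind(codes, col)
    starts <- c(starts, se[1])
    ends <- c(ends, se[2])
    carrier_sets <- c(carrier_sets, list(carriers))
  }
  scored <- tibble::tibble(start = starts, end = ends,
                           length = ends - starts + 1L,
                           carriers = carrier_sets)
  extended <- rows
  if (!is.null(codes)) {
    extended <- paste0(rows, apply(codes, 1L, paste, collapse = ""))
    names(extended) <- names(rows)
  }
  list(extended = extended, indels = scored)
}

# length of the mononucleotide run of `base` in the ungapped consensus
# spanning the alignment columns start..end
block_run_length <- function(cons, start, end, base) {
  run <- max(0L, sum(cons[start:end] == base))
  j <- start - 1L
  while (j >= 1L) {
    if (cons[j] == "-") { j <- j - 1L; next }
    if (cons[j] == base) { run <- run + 1L; j <- j - 1L } else break
  }
  j <- end + 1L
  while (j <= length(cons)) {
    if (cons[j] == "-") { j <- j + 1L; next }
    if (cons[j] == base) { run <- run + 1L; j <- j + 1L } else break
  }
  run
}

#' Estimate the sequencing error rate from single-copy alignments
#'
#' For alignments of a single-copy region (one true haplotype per sample),
#' every non-consensus base call at a gap-free column is counted as an
#' error. N-masked bases and columns containing length variation are
#' excluded.
#'
#' @param alignments List of `group_alignment` objects.
#' @return List: `numerator` (mismatching calls), `denominator` (non-N calls
#'   surveyed), `rate`.
#' @export
estimate_error_rate <- function(alignments) {
  num <- 0L
  den <- 0L
  for (aln in alignments) {
    if (length(aln$ids) == 0L) next
    mat <- alignment_matrix(aln)
    keep <- which(apply(mat, 2L, function(col) all(col != "-")))
    if (!length(keep)) next
    cons <- column_consensus(mat[, keep, drop = FALSE], aln$mean_qual)
    for (k in seq_along(keep)) {
      col <- mat[, keep[k]]
      obs <- col[col != "N"]
      den <- den + length(obs)
      num <- num + sum(obs != cons[k])
    }
  }
  if (den == 0L) stop("no surveyable bases; error rate undefined")
  list(numerator = num, denominator = den, rate = num / den)
}
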