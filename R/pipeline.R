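# Full workflow: region assignment -> barcode deconvolution -> quality
# control -> grouping -> alignment -> allele calling -> chimera flagging ->
# copy partition -> reports. Every read leaving the pipeline is accounted
# for with a stage and a reason.

#' Pipeline configuration
#'
#' Bundles the per-stage parameter objects. Defaults follow the package's
#' standard workflow: Q15 masking, >=2-bp allele differences at >80%
#' consistency, <5% minority threshold for chimera candidates.
#'
#' @param demux [demux_params()].
#' @param qc [qc_params()].
#' @param alleles [allele_params()].
#' @param chimera [chimera_params()].
#' @param seed Optional integer seed (recorded; the pipeline itself is
#'   deterministic).
#' @return A `run_config` list.
#' @export
run_config <- function(demux = demux_params(), qc = qc_params(),
                       alleles = allele_params(), chimera = chimera_params(),
                       seed = NULL) {
  structure(list(demux = demux, qc = qc, alleles = alleles,
                 chimera = chimera, seed = seed), class = "run_config")
}

#' Run the full deconvolution / allele-calling pipeline
#'
#' @param reads A `qreads` tibble, or a path readable by
#'   [read_sequences()].
#' @param sheet Sample sheet tibble or TSV path.
#' @param regions Gene-region tibble or TSV path.
#' @param config [run_config()].
#' @return A `polyamp_run` list:
#'   \describe{
#'     \item{allele_calls}{tibble over all (sample, region) groups, chimera
#'       verdicts joined in (`recombinant_suspect`).}
#'     \item{count_matrix}{tibble of post-QC read counts per
#'       (sample, region).}
#'     \item{chimera_reports}{all chimera-scan reports.}
#'     \item{partitions}{per nuclear region, the [partition_copies()]
#'       result.}
#'     \item{alignments}{per-group `group_alignment` objects (named
#'       `sample|region`), e.g. for [estimate_error_rate()].}
#'     \item{read_assignments}{tibble of final (read_id, sample, region).}
#'     \item{attrition}{per-stage discard accounting: stage, reason, n.}
#'     \item{discards}{one row per discarded read: read_id, stage, reason.}
#'   }
#' @export
run_pipeline <- function(reads, sheet, regions, config = run_config()) {
  if (is.character(reads)) reads <- read_sequences(reads)
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  if (is.character(regions)) regions <- read_region_table(regions)
  reads <- validate_qreads(reads)
  discards <- list()
  note_discards <- function(ids, stage, reason) {
    if (length(ids)) {
      discards[[length(discards) + 1L]] <<-
        tibble::tibble(read_id = ids, stage = stage, reason = reason)
    }
  }

  asn <- assign_region(reads, regions, config$demux)
  for (st in c("unassigned", "ambiguous")) {
    note_discards(asn$read_id[asn$status == st], "assign_region", st)
  }

  groups <- list()          # key: sample||region -> qreads
  counts <- list()
  for (r in seq_len(nrow(regions))) {
    in_region <- which(asn$status == "ok" & asn$region == regions$name[r])
    if (!length(in_region)) next
    oriented <- orient_reads(reads[in_region, , drop = FALSE],
                             asn$orientation[in_region])
    tr <- trim_to_insert(oriented, regions[r, ], sheet, config$demux)
    bad <- tr$assignments$status != "ok"
    for (st in unique(tr$assignments$status[bad])) {
      note_discards(tr$assignments$read_id[tr$assignments$status == st &
                                             bad], "deconvolve", st)
    }
    ok_assign <- tr$assignments[!bad, , drop = FALSE]
    qc_in <- tr$reads
    qcr <- qc_reads(qc_in, config$qc)
    dropped <- setdiff(qc_in$read_id, qcr$retained$read_id)
    note_discards(dropped, "qc", "short_after_trim")
    kept <- qcr$retained
    kept_samples <- ok_assign$sample_id[match(kept$read_id, ok_assign$read_id)]
    for (s in unique(kept_samples)) {
      key <- paste(s, regions$name[r], sep = "\r")
      groups[[key]] <- kept[kept_samples == s, , drop = FALSE]
    }
  }

  calls <- empty_allele_calls()
  calls$recombinant_suspect <- logical(0)
  chim_all <- NULL
  count_rows <- list()
  alignments <- list()
  for (key in names(groups)) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    s <- parts[1]
    rname <- parts[2]
    g <- groups[[key]]
    count_rows[[key]] <- tibble::tibble(sample = s, region = rname,
                                        n_reads = nrow(g))
    aln <- align_group(read_group(g, sample = s, region = rname))
    alignments[[paste(s, rname, sep = "|")]] <- aln
    exp_copies <- regions$expected_copies[match(rname, regions$name)]
    cl <- call_alleles(aln, config$alleles, expected_copies = exp_copies)
    rep_tbl <- detect_recombinants(cl, config$chimera)
    cl$recombinant_suspect <- FALSE
    if (nrow(rep_tbl)) {
      rec <- rep_tbl$candidate[rep_tbl$verdict == "recombinant"]
      cl$recombinant_suspect <- cl$allele_label %in% rec
      rep_tbl$sample <- s
      rep_tbl$region <- rname
      chim_all <- rbind(chim_all, rep_tbl)
    }
    calls <- rbind(calls, cl)
  }

  partitions <- list()
  for (rname in regions$name[regions$expected_copies == 2L]) {
    sel <- calls$region == rname & !calls$recombinant_suspect
    if (sum(sel & !calls$low_support) >= 2L) {
      part <- partition_copies(calls[sel, , drop = FALSE])
      calls$copy_label[sel] <- part$calls$copy_label
      partitions[[rname]] <- part
    }
  }
  # final labels: copy letter + rank within (sample, region, copy)
  calls <- relabel_alleles(calls)

  count_matrix <- if (length(count_rows)) {
    do.call(rbind, unname(count_rows))
  } else {
    tibble::tibble(sample = character(0), region = character(0),
                   n_reads = integer(0))
  }
  attrition <- if (length(discards)) {
    d <- do.call(rbind, discards)
    stats::aggregate(list(n = d$read_id), by = list(stage = d$stage,
                                                    reason = d$reason), length)
  } else {
    data.frame(stage = character(0), reason = character(0), n = integer(0))
  }
  read_assignments <- if (length(alignments)) {
    do.call(rbind, lapply(names(alignments), function(k) {
      a <- alignments[[k]]
      tibble::tibble(read_id = a$ids, sample = a$sample, region = a$region)
    }))
  } else {
    tibble::tibble(read_id = character(0), sample = character(0),
                   region = character(0))
  }
  structure(list(allele_calls = calls, count_matrix = count_matrix,
                 chimera_reports = chim_all, partitions = partitions,
                 alignments = alignments,
                 read_assignments = read_assignments,
                 attrition = tibble::as_tibble(attrition),
                 discards = if (length(discards)) do.call(rbind, discards) else
                   tibble::tibble(read_id = character(0), stage = character(0),
                                  reason = character(0)),
                 n_input_reads = nrow(reads)),
            class = "polyamp_run")
}

relabel_alleles <- function(calls) {
  if (!nrow(calls)) return(calls)
  key <- paste(calls$sample, calls$region, calls$copy_label)
  for (k in unique(key)) {
    idx <- which(key == k)
    idx <- idx[order(-calls$support_count[idx])]
    letter <- calls$copy_label[idx[1]]
    prefix <- if (letter %in% c("A", "B")) letter else "U"
    calls$allele_label[idx] <- paste0(prefix, seq_along(idx))
  }
  calls
}

#' Write pipeline reports to a directory
#'
#' Emits `alleles.tsv`, `alleles.fasta` (headers
#' `sample|region|copy|allele|support`), `counts.tsv`, `chimeras.tsv` and
#' `attrition.tsv`.
#'
#' @param run A `polyamp_run` result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_run_reports <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  calls <- run$allele_calls
  flat <- calls[, c("sample", "region", "allele_label", "copy_label",
                    "support_count", "fraction", "low_support",
                    "recombinant_suspect", "consensus")]
  write_tsv_report(flat, file.path(dir, "alleles.tsv"))
  if (nrow(calls)) {
    headers <- sprintf("%s|%s|%s|%s|%d", calls$sample, calls$region,
                       calls$copy_label, calls$allele_label,
                       calls$support_count)
    write_sequences(qualified_reads(headers, calls$consensus),
                    file.path(dir, "alleles.fasta"), format = "fasta")
  }
  write_tsv_report(run$count_matrix, file.path(dir, "counts.tsv"))
  if (!is.null(run$chimera_reports)) {
    write_tsv_report(run$chimera_reports, file.path(dir, "chimeras.tsv"))
  }
  write_tsv_report(run$attrition, file.path(dir, "attrition.tsv"))
  invisible(dir)
}
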