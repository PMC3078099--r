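# Synthetic barcoded polyploid amplicon datasets with full truth tables.
# The generator emulates a pooled 454-style run over allotetraploid samples:
# single-copy plastid regions and two-copy nuclear regions whose homeologues
# are separated by fixed substitutions and diagnostic indels, up to two
# alleles per copy, uneven per-copy amplification (B:A ratio), per-base
# sequencing errors with a quality model, PCR chimeras, and negative-
# binomial read yields with occasional cell dropout.

random_seq <- function(n, gc = 0.45) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

substitute_at <- function(seq, pos) {
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

delete_at <- function(seq, start, len) {
  paste0(substr(seq, 1, start - 1), substr(seq, start + len, nchar(seq)))
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions the package targets: 16 tetraploid
#' samples, three single-copy plastid regions and two nuclear regions whose
#' homeologous copies differ by ~4% and ~8.5% fixed substitutions plus
#' diagnostic indels (a 7-bp indel for the DMC1-like region; 1-4-bp indels
#' for the CDO504-like region), B:A read ratios 1.29 and 1.87, negative-
#' binomial read counts per (sample, region) cell, 0.5% raw per-base error
#' with ~70% of errors falling below the Q15 masking threshold (residual
#' post-mask error ~0.15%), 3% PCR chimeras and occasional cell dropout.
#'
#' @param n_samples Number of samples (<= 64, the barcode vocabulary size).
#' @param regions Region-design tibble; `sim_regions()` gives the default.
#' @param reads_mean,reads_dispersion Negative-binomial mean and size for
#'   reads per (sample, region) cell.
#' @param alleles_per_copy Alleles segregating per gene copy (1 or 2).
#' @param intra_copy_diff Substitutions separating the two alleles of one
#'   copy (>= the caller's `min_diff`; default 3).
#' @param het_prob Probability a sample is heterozygous at a copy.
#' @param error_rate Raw per-base substitution error probability.
#' @param error_masked_frac Fraction of erroneous bases drawn with quality
#'   below 15 (so QC masking removes them).
#' @param chimera_rate Per-read probability of being a PCR chimera.
#' @param dropout Per-cell probability of yielding zero reads.
#' @param truncate_reads If `TRUE`, read lengths are drawn from a normal
#'   with `read_len_mean`/`read_len_sd` (truncated to the amplicon length);
#'   default emits full-length amplicon reads.
#' @param read_len_mean,read_len_sd Truncation model parameters (278/153).
#' @param min_segment Minimum distance of chimera breakpoints from either
#'   amplicon end (default 30).
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 16L, regions = sim_regions(),
                       reads_mean = 50, reads_dispersion = 8,
                       alleles_per_copy = 2L, intra_copy_diff = 3L,
                       het_prob = 0.6, error_rate = 0.005,
                       error_masked_frac = 0.7, chimera_rate = 0.03,
                       dropout = 0.02, truncate_reads = FALSE,
                       read_len_mean = 278, read_len_sd = 153,
                       min_segment = 30L, seed = 1L) {
  stopifnot(n_samples >= 1L, n_samples <= 64L,
            error_rate >= 0, error_rate < 1, chimera_rate >= 0,
            chimera_rate <= 1, dropout >= 0, dropout <= 1,
            error_masked_frac >= 0, error_masked_frac <= 1,
            alleles_per_copy %in% c(1L, 2L))
  structure(as.list(environment()), class = "sim_config")
}

#' Default simulated region designs
#'
#' Three single-copy plastid-like regions and two nuclear two-copy regions:
#' "nucDMC1" with 4% inter-copy divergence and one 7-bp diagnostic indel,
#' "nucCDO504" with 8.5% divergence and four 1-4-bp indels.
#'
#' @return Tibble: `name`, `core_len`, `expected_copies`, `divergence`,
#'   `indel_lens` (list), `copy_ratio` (B:A).
#' @export
sim_regions <- function() {
  tibble::tibble(
    name = c("cpTrnLF", "cpRpl32TrnL", "cpTrnHPsbA", "nucDMC1", "nucCDO504"),
    core_len = c(420L, 430L, 410L, 440L, 415L),
    expected_copies = c(1L, 1L, 1L, 2L, 2L),
    divergence = c(0, 0, 0, 0.04, 0.085),
    indel_lens = list(integer(0), integer(0), integer(0), 7L, c(1L, 2L, 3L, 4L)),
    copy_ratio = c(NA, NA, NA, 1.29, 1.87)
  )
}

#' Inject substitution errors into a read
#'
#' Each base is substituted independently with probability `rate` (uniform
#' over the three alternatives). Erroneous bases receive a quality drawn
#' from the error model: with probability `masked_frac` a quality below the
#' masking threshold (2-14), otherwise 15-25; correct bases keep qualities
#' of 30-40.
#'
#' @param bases Base string.
#' @param quals Integer qualities (same length).
#' @param rate Per-base error probability in \[0, 1).
#' @param masked_frac Fraction of errors pushed below Q15.
#' @return List: `bases`, `quals`, `error_pos` (1-based positions).
#' @export
inject_errors <- function(bases, quals, rate, masked_frac = 0.7) {
  stopifnot(rate >= 0, rate < 1)
  n <- nchar(bases)
  hit <- which(runif(n) < rate)
  if (length(hit)) {
    ch <- strsplit(bases, "")[[1]]
    for (p in hit) {
      if (ch[p] %in% c("A", "C", "G", "T")) {
        ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      }
      quals[p] <- if (runif(1) < masked_frac) sample(2:14, 1) else sample(15:25, 1)
    }
    bases <- paste(ch, collapse = "")
  }
  list(bases = bases, quals = quals, error_pos = hit)
}

#' Build a single-junction PCR chimera from two parent sequences
#'
#' The parents are pairwise-aligned and the template switches at a
#' homologous position: the breakpoint column is uniform over interior
#' alignment columns at least `min_segment` columns from both ends, and the
#' product is parent 1's bases up to that column joined to parent 2's bases
#' after it.
#'
#' @param parent1,parent2 Distinct parent sequences.
#' @param min_segment Minimum distance of the breakpoint column from either
#'   alignment end.
#' @return List: `sequence`, `breakpoint` (1-based position in parent 1
#'   after which the template switches).
#' @export
inject_chimera <- function(parent1, parent2, min_segment = 30L) {
  if (identical(parent1, parent2)) stop("chimera parents must be distinct")
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(parent1),
    subject = Biostrings::DNAString(parent2),
    type = "global", substitutionMatrix = star_submat(),
    gapOpening = 6, gapExtension = 1)
  r1 <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  r2 <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  lo <- min_segment
  hi <- length(r1) - min_segment
  if (hi < lo) stop("parents too short for min_segment = ", min_segment)
  k <- sample(lo:hi, 1)
  prefix <- paste(r1[seq_len(k)][r1[seq_len(k)] != "-"], collapse = "")
  suffix <- paste(r2[(k + 1):length(r2)][r2[(k + 1):length(r2)] != "-"],
                  collapse = "")
  list(sequence = paste0(prefix, suffix), breakpoint = nchar(prefix))
}

#' Simulate a barcoded polyploid amplicon dataset
#'
#' Builds ancestral cores per region, derives homeologous copies by the
#' divergence spec (fixed substitutions at positions disjoint from all
#' intra-copy polymorphism, plus diagnostic deletions in copy B), derives
#' alleles per copy, assigns genotypes to samples, and emits reads laid out
#' as barcode word + ligation T + forward primer + core + revcomp(reverse
#' primer) + ligation A + adapter remnant, with errors and chimeras injected
#' at the configured rates. Roughly half of the reads are emitted
#' reverse-complemented.
#'
#' @param cfg A [sim_config()].
#' @return List: `reads` (`qreads` tibble), `sheet` (sample sheet),
#'   `regions` (gene-region table usable by the pipeline), `truth` (list
#'   with `alleles` and `reads` tibbles; error positions are 1-based in the
#'   emitted forward-layout read).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  words <- generate_barcode_words()
  sample_ids <- sprintf("S%02d", seq_len(cfg$n_samples))
  sheet <- sample_sheet(words[seq_len(cfg$n_samples)], sample_ids)
  adapter_b <- "CTGAGCGGGCTGGCAAGGCG"

  designs <- cfg$regions
  region_rows <- list()
  ta <- list(sample = character(0), region = character(0), copy = character(0),
             sequence = character(0))
  tr <- list(read_id = character(0), sample = character(0),
             region = character(0), source = character(0), copy = character(0),
             allele_seq = character(0), parent_1 = character(0),
             parent_2 = character(0), breakpoint = integer(0),
             n_errors = integer(0), error_pos = list(),
             emitted_orientation = character(0))
  rd <- list(read_id = character(0), bases = character(0), quals = list(),
             flip = logical(0))
  read_no <- 0L

  for (r in seq_len(nrow(designs))) {
    rname <- designs$name[r]
    core_len <- designs$core_len[r]
    fwd_primer <- random_seq(20)
    rev_primer <- random_seq(20)
    core <- random_seq(core_len)
    copies <- designs$expected_copies[r]

    # disjoint substitution positions: inter-copy fixed differences first,
    # then intra-copy polymorphisms for each copy
    n_fixed <- if (copies == 2L) round(designs$divergence[r] * core_len) else 0L
    n_intra <- if (cfg$alleles_per_copy == 2L) cfg$intra_copy_diff else 0L
    pool <- sample(seq_len(core_len), n_fixed + 2L * n_intra)
    fixed_pos <- head(pool, n_fixed)
    intra_pos <- split(tail(pool, 2L * n_intra),
                       rep(1:2, each = n_intra, length.out = 2L * n_intra))

    # all substitutions placed in core coordinates, then copy B's diagnostic
    # deletions applied at sites disjoint from every substituted position,
    # so inter-copy fixed differences stay exact after alignment
    allele_pool <- list(A = core)
    if (cfg$alleles_per_copy == 2L) {
      allele_pool$A <- c(allele_pool$A, substitute_at(core, intra_pos[[1]]))
    }
    if (copies == 2L) {
      b_base <- substitute_at(core, fixed_pos)
      b_pool <- b_base
      if (cfg$alleles_per_copy == 2L) {
        b_pool <- c(b_pool, substitute_at(b_base, intra_pos[[2]]))
      }
      for (len in designs$indel_lens[[r]]) {
        repeat {
          start <- sample(seq(40L, nchar(b_pool[1]) - 40L - len), 1)
          if (!any(pool %in% seq(start - 1L, start + len))) break
        }
        b_pool <- vapply(b_pool, delete_at, character(1), start, len,
                         USE.NAMES = FALSE)
        pool <- ifelse(pool > start + len - 1L, pool - len, pool)
      }
      allele_pool$B <- b_pool
    }

    region_rows[[r]] <- gene_regions(rname, fwd_primer, rev_primer,
                                     core_len, copies)

    for (s in seq_len(cfg$n_samples)) {
      n_cell <- if (runif(1) < cfg$dropout) 0L else {
        rnbinom(1, mu = cfg$reads_mean, size = cfg$reads_dispersion)
      }
      # genotype: which alleles of each copy this sample carries
      geno <- list()
      for (cp in names(allele_pool)) {
        pool_cp <- allele_pool[[cp]]
        geno[[cp]] <- if (copies == 2L && length(pool_cp) > 1L &&
                          runif(1) < cfg$het_prob) {
          pool_cp          # heterozygous at this copy
        } else {
          # single haplotype (always the case for single-copy regions)
          pool_cp[sample(length(pool_cp), 1)]
        }
      }
      # per-read copy assignment by the B:A amplification ratio
      ratio <- designs$copy_ratio[r]
      p_b <- if (copies == 2L) ratio / (1 + ratio) else 0
      cell_alleles <- unlist(geno, use.names = FALSE)
      cell_labels <- rep(names(geno), lengths(geno))
      if (n_cell > 0L) {
        ta$sample <- c(ta$sample, rep(sample_ids[s], length(cell_alleles)))
        ta$region <- c(ta$region, rep(rname, length(cell_alleles)))
        ta$copy <- c(ta$copy, cell_labels)
        ta$sequence <- c(ta$sequence, cell_alleles)
      }
      rc_rev_primer <- revcomp(rev_primer)
      for (k in seq_len(n_cell)) {
        read_no <- read_no + 1L
        rid <- sprintf("read%06d", read_no)
        is_chimera <- cfg$chimera_rate > 0 && runif(1) < cfg$chimera_rate &&
          length(unique(cell_alleles)) >= 2L
        if (is_chimera) {
          # prefer parents from different copies (the detectable,
          # consequential kind); fall back to distinct alleles of one copy
          other <- which(cell_labels != cell_labels[1] &
                           cell_alleles != cell_alleles[1])
          if (!length(other)) other <- which(cell_alleles != cell_alleles[1])
          p2 <- other[sample(length(other), 1)]
          ch <- inject_chimera(cell_alleles[1], cell_alleles[p2],
                               cfg$min_segment)
          insert <- ch$sequence
          src <- list(source = "chimera", copy = NA_character_,
                      allele_seq = NA_character_,
                      parent_1 = cell_alleles[1], parent_2 = cell_alleles[p2],
                      breakpoint = ch$breakpoint)
        } else {
          ai <- if (copies == 2L) {
            cp <- if (runif(1) < p_b) "B" else "A"
            hits <- which(cell_labels == cp)
            hits[sample(length(hits), 1)]
          } else {
            sample(length(cell_alleles), 1)
          }
          insert <- cell_alleles[ai]
          src <- list(source = "allele", copy = cell_labels[ai],
                      allele_seq = insert, parent_1 = NA_character_,
                      parent_2 = NA_character_, breakpoint = NA_integer_)
        }
        full <- paste0(sheet$word[s], "T", fwd_primer, insert,
                       rc_rev_primer, "A", adapter_b)
        if (cfg$truncate_reads) {
          len <- round(min(max(40, stats::rnorm(1, cfg$read_len_mean,
                                                cfg$read_len_sd)),
                           nchar(full)))
          full <- substr(full, 1, len)
        }
        quals <- sample(30:40, nchar(full), replace = TRUE)
        err <- inject_errors(full, quals, cfg$error_rate,
                             cfg$error_masked_frac)
        flip <- runif(1) < 0.5
        tr$read_id <- c(tr$read_id, rid)
        tr$sample <- c(tr$sample, sample_ids[s])
        tr$region <- c(tr$region, rname)
        tr$source <- c(tr$source, src$source)
        tr$copy <- c(tr$copy, src$copy)
        tr$allele_seq <- c(tr$allele_seq, src$allele_seq)
        tr$parent_1 <- c(tr$parent_1, src$parent_1)
        tr$parent_2 <- c(tr$parent_2, src$parent_2)
        tr$breakpoint <- c(tr$breakpoint, src$breakpoint)
        tr$n_errors <- c(tr$n_errors, length(err$error_pos))
        tr$error_pos <- c(tr$error_pos, list(err$error_pos))
        tr$emitted_orientation <- c(tr$emitted_orientation,
                                    if (flip) "reverse" else "forward")
        rd$read_id <- c(rd$read_id, rid)
        rd$bases <- c(rd$bases, err$bases)
        rd$quals <- c(rd$quals, list(err$quals))
        rd$flip <- c(rd$flip, flip)
      }
    }
  }
  flip_idx <- which(rd$flip)
  if (length(flip_idx)) {
    rd$bases[flip_idx] <- revcomp(rd$bases[flip_idx])
    rd$quals[flip_idx] <- lapply(rd$quals[flip_idx], rev)
  }
  reads <- qualified_reads(rd$read_id, rd$bases, rd$quals)
  truth <- list(
    alleles = unique(tibble::as_tibble(ta)),
    reads = tibble::as_tibble(tr)
  )
  list(reads = reads, sheet = sheet, regions = do.call(rbind, region_rows),
       truth = truth)
}
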