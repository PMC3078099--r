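---
title: "Methods: barcoded polyploid amplicon sequencing with polyamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcoded polyploid amplicon sequencing with polyamp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyamp)
```

## The problem

Pooled amplicon sequencing of polyploids asks three questions at once. First,
which sample did each read come from, when dozens of samples share one
sequencing run and are told apart only by a short barcode that is itself
subject to sequencing error? Second, which of the up-to-four allele sequences
present at a nuclear locus of an allotetraploid (two homeologous gene copies,
each with up to two alleles) does each read represent, given per-base errors
and PCR artefacts? Third, how many reads per sample and locus are enough to
be confident that every allele has been seen at least once?

`polyamp` implements a complete workflow for these questions: a
checksum-protected barcode vocabulary, primer-based demultiplexing,
454-style quality control, allele calling under a minimum-difference rule,
homeologue partitioning, PCR-chimera detection, and the inverse
coupon-collector read-depth model — together with a synthetic-data generator
that produces full truth tables, so the whole pipeline is testable end to
end without access to any particular sequencing run.

## Checksum barcodes

Sample barcodes are 4-bp words: a 3-bp code plus a checksum base chosen so
that the sum of base indices (A=0, C=1, G=2, T=3) over all four positions is
0 modulo 4. This is the simplest scheme with the two properties the design
requires: exactly 4^3 = 64 of the 256 possible 4-mers are valid (one word
per code), and any single-base substitution shifts the sum modulo 4 and is
therefore always detected. Matching is exact: a read whose word fails the
checksum or is absent from the sample sheet is discarded, never rescued.
This mirrors the conservative practice of the workflow the package
automates — barcode mismatches indicate errors precisely where sample
identity is decided, so correction would risk cross-sample contamination.

```{r barcodes}
head(generate_barcode_words())
validate_word("ACGC")   # valid: 0+1+2+1 = 4 = 0 mod 4
validate_word("ACGA")   # single substitution of the checksum base
```

## Read structure, demultiplexing, trimming

Reads are expected to begin at the barcode (the library adapter serves as
the sequencing primer and is not read): `word + T + forward primer + insert
+ revcomp(reverse primer) + A + adapter remnant`. Region assignment searches
each region's forward primer and the reverse complement of its reverse
primer in the first 40 bases of the read and of its reverse complement,
tolerating one substitution (the exact-match regular expressions the
original workflow used lose reads to primer-region sequencing errors; one
mismatch recovers most of them without measurable cross-talk between
random-primer regions). Ties between regions are dropped as ambiguous
rather than arbitrated. Reads whose 5' end starts inside the primer carry
no reachable barcode and are rejected (`word_missing`), matching the fate
of fragmented molecules in real runs.

Coordinates throughout the package are 1-based closed intervals, the native
R and IRanges convention; all subsetting uses `substr`-style inclusive
ranges, and reports print the same coordinates users see in R.

## Quality control

Three steps, in order:

* **End trimming** — a window of 10 bases steps inward from each end in
  whole-window strides until its mean quality reaches Q15; the enclosed
  slice is kept. Stepping by whole windows (rather than sliding by one
  base) prevents a single good base at the edge of a bad stretch from
  rescuing it.
* **Masking** — every base with quality below Q15 becomes N. N is treated
  as missing data everywhere downstream: the aligner scores it as neutral,
  the allele caller treats it as a wildcard, and the error-rate estimator
  excludes it.
* **Length filter** — reads shorter than 100 bp are removed. The threshold
  is the package's own choice: with 400-450 bp target amplicons, shorter
  fragments rarely span enough variable positions to support an allele
  assignment.

The full pass is idempotent: applying it twice changes nothing.

## Allele calling

Each (sample, region) read group is aligned by a star alignment: the
longest read is the pivot, every other read is aligned to it with affine
gap penalties (Biostrings' pairwise aligner), and the pairwise alignments
are merged column-wise. Calling then proceeds in four steps:

1. Reads are grouped into haplotypes over the variable columns, with N
   compatible with anything.
2. Each cluster gets a consensus: majority character per column, N
   excluded; ties resolve to the character carried by the
   highest-mean-quality reads, then alphabetically. This makes output
   deterministic without inventing ambiguity codes.
3. Clusters whose consensus differs from a larger cluster's consensus at
   fewer than 2 base positions (outside mononucleotide runs longer than
   5 bp, which are unreliable in 454-style data) are merged — the
   minimum-difference rule. Single-base variants, which are mostly
   sequencing errors, therefore never found an allele.
4. A surviving cluster is a distinct allele only if, at every column that
   distinguishes it from another cluster, more than 80% of its gap-free,
   non-N member reads carry the cluster's base. The 80% consistency is
   applied per distinguishing column over the candidate allele's own
   supporting reads; the alternative reading (80% of all group reads)
   coincides with this one on clean data, and the per-allele reading is
   the one that operationalises "an allele's reads agree with it".

Clusters with fewer than 2 supporting reads, or holding less than 5% of the
group's reads (exclusive boundary), are emitted flagged `low_support` and
handed to the chimera scanner rather than silently dropped: read support
is always conserved.

For a two-copy nuclear region, alleles from all samples are pooled,
pairwise base differences (gap and N columns excluded) feed single-linkage
clustering, and the tree is cut into two groups, accepted only when the
between-group mean distance is at least twice the within-group maximum.
The group with more total supporting reads is labelled copy B, matching
the direction of amplification bias the workflow is designed around; a
reference-based override is available when diagnostic sequences are known.
The partition reports fixed differences (columns where all members of the
two copies carry different bases), shared polymorphisms (the signature of
inter-copy recombination or incomplete separation — expected to be zero),
and diagnostic indel blocks.

Indels among final allele consensi can be coded as binary characters
appended to the alignment (`a` absent / `c` present, weighting each indel
like a transversion). Two exclusions apply: length variation inside
mononucleotide runs longer than 5 bp (no reliable consensus there) and
indels carried by a single sequence (possible PCR slippage).

## Sequencing error rate

The residual (post-masking) error rate is estimated from single-copy
regions, where each sample carries one haplotype: every non-N call that
disagrees with its column's consensus at a gap-free column is counted as
an error, divided by all non-N calls surveyed. Gap columns are excluded
because length variation in these data is dominated by homopolymer
miscalls, not substitutions.

## PCR-chimera detection

An apparent allele is judged a PCR recombinant by two criteria: it holds a
minority of the group's reads (below 5%, exclusive), and some breakpoint
splits it so that the prefix matches one common allele and the suffix a
different common allele — each within 1 mismatch over at least 30 compared
bases — while no single common allele explains the whole candidate within
2 mismatches. The reported breakpoint interval is the full range of
columns over which a valid junction can lie (the true junction is only
localisable between the flanking informative sites). Only single-junction,
two-parent chimeras are modelled. Two documented limitations follow
directly from the criteria: a chimera whose junction is so close to one
end that the short flank carries fewer than two informative sites is
indistinguishable from its majority parent (and is absorbed by the
minimum-difference rule), and occasional higher-frequency recombinants
above the 5% line are not rescued.

## Read-depth model

How many reads must a (sample, region) cell yield before all alleles have
been observed? With allele proportions $p_1,\dots,p_k$ and $n$ reads drawn
independently, the probability that every allele appears is, by
inclusion–exclusion over the subsets $S$ of alleles missed,

$$P(n) = \sum_{S \subseteq \{1..k\}} (-1)^{|S|} \Big(1 - \sum_{i \in S} p_i\Big)^{n}.$$

`prob_all_observed()` evaluates this exactly; `prob_all_observed_mc()`
estimates the same quantity by multinomial simulation (10,000 draws by
default), retained both as an independent cross-check and because the
simulation route is how such curves are usually produced. The analytic
engine is primary because it is deterministic and resolves behaviour at
the threshold exactly:

```{r depth}
prob_all_observed(rep(0.25, 4), 15)
prob_all_observed(rep(0.25, 4), 16)
min_reads(rep(0.25, 4), confidence = 0.95)
```

For four equally frequent alleles, $P(15) \approx 0.9467$ sits just below
0.95, so the analytic minimum is 16 — one more than a simulation-based
reading of the same curve suggests, a distinction invisible at Monte-Carlo
resolution. With unequal copies the proportions come from the B:A
amplification ratio $r$ as $(1/(1+r),\; r/(1+r))$, each copy's mass split
equally between its alleles when four categories are wanted:

```{r depth2}
min_reads(ratio_to_proportions(1.29), confidence = 0.95)  # two copies
```

The ratio itself is estimated by regressing per-individual copy B read
counts on copy A counts with the fit forced through the origin: the slope
$\hat\beta = \sum a_ib_i / \sum a_i^2$ is the mean B:A ratio, and a t-test
with $n-1$ degrees of freedom (one parameter, no intercept) asks whether
it differs from 1.

## The synthetic-data generator

`simulate_dataset()` is first-class, tested code. Its defaults are the
study conditions the package targets, chosen once:

* 16 tetraploid samples; five regions — three single-copy plastid-like
  (410-430 bp) and two nuclear two-copy regions: one with 4% inter-copy
  divergence and a 7-bp diagnostic deletion, one with 8.5% divergence and
  four deletions of 1-4 bp.
* Up to two alleles per copy, separated by 3 substitutions (comfortably
  above the 2-bp calling threshold); heterozygosity probability 0.6 per
  copy; all substitution positions (inter-copy fixed differences,
  intra-copy polymorphisms of either copy) are mutually disjoint, and
  deletions avoid them, so truth diagnostics are exact by construction.
* Copy B:A read ratios 1.29 and 1.87 for the two nuclear regions; reads
  per cell negative-binomial with mean 50 and size 8 (cells mostly span
  roughly 20-90 reads); 2% cell dropout.
* Raw per-base substitution error 0.5%. Erroneous bases draw qualities
  below Q15 with probability 0.7 (so masking removes them) and Q15-25
  otherwise; correct bases draw Q30-40. The residual post-mask error is
  therefore about 0.15%, the magnitude this kind of workflow reports after
  quality control. The raw rate is a free calibration: instruments report
  quality, not truth, and only the residual is observable downstream.
* 3% of reads in cells carrying at least two distinct alleles are
  single-junction chimeras. Parents are drawn from different gene copies
  when the cell has both: inter-copy chimeras are the consequential kind —
  they mimic novel alleles and can corrupt copy assignment — and the kind
  the two-criterion rule can actually see. The junction is placed at a
  homologous alignment column, uniform at least 30 columns from either
  end.
* Reads are full-length by default (the protocol targets amplicons within
  read length); an optional truncation model (mean 278, sd 153) emulates
  the broad length distributions of 454-style runs.

What the generator does **not** emulate: homopolymer-length miscalls (the
dominant real 454 error mode; substitution errors only, so indel-robustness
of the caller is exercised through true indels, not error indels), PCR
stochasticity beyond the negative-binomial yields, chimeras with multiple
junctions, and contamination between samples. Passing tests on simulated
data therefore demonstrate the correctness of the algorithms under the
stated model, not performance on any particular instrument's artefacts.

## Numerical and design choices

* Consensus ties: highest-mean-quality supporting reads, then
  alphabetical; gap sorts after bases. Deterministic output was preferred
  over IUPAC ambiguity codes, which downstream distance analyses handle
  poorly.
* The star aligner scores N as 0 against everything (match 2, mismatch
  −4, gap open 6, extend 1): masked bases neither attract nor repel.
* Copies are declared non-separable when the between-group mean distance
  is under twice the within-group maximum, or zero; all alleles are then
  left unassigned with a warning rather than forced into a labelling.
* Degenerate inputs: empty alignments yield empty call tables; a group
  with fewer than two common alleles yields no chimera candidates; zero
  reads surviving QC is a valid, empty result, not an error.
* `prob_all_observed` returns exactly 0 for $n < k$ and clamps the
  alternating sum into $[0,1]$ against floating-point drift; the subset
  enumeration is capped at 20 categories.
* Monte-Carlo functions take an explicit seed and restore the caller's RNG
  state.

## Problem sizes used in the test suite

Unit tests run on groups of tens of reads. The end-to-end checks simulate
the full study design — 5 regions × 16 samples, negative-binomial read
yields with mean 50 (roughly 3,500-4,000 reads) — once without errors and
once at the default error and chimera rates; these sizes exercise every
code path at realistic coverage while keeping a full suite run in a few
minutes. On error-free data the pipeline is required to recover every
truth allele (with at least 2 supporting reads) and every read's
(sample, region) assignment exactly; with errors, allele recovery of at
least 95% and an error-rate estimate within 3 binomial standard errors of
the injected residual rate are required. Chimera sensitivity is measured
against all injected chimeras; as discussed above, junctions with an
uninformative short flank are undetectable in principle under the
two-criterion rule, which bounds attainable sensitivity below 100% and is
reported honestly by the suite.
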