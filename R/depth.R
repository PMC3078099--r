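# Inverse coupon-collector read-depth model: given the relative proportions
# of the alleles (or gene copies) at a locus, how many reads are needed to be
# confident that every allele has been sequenced at least once?

#' Validate an allele-proportion vector
#'
#' @param p Numeric vector of category probabilities, all > 0, summing to 1
#'   (within 1e-12 after normalisation check).
#' @return `p`, invisibly validated.
#' @export
allele_proportions <- function(p) {
  if (!is.numeric(p) || length(p) < 1L || anyNA(p)) {
    stop("proportions must be a non-empty numeric vector without NA")
  }
  if (any(p <= 0)) stop("all allele proportions must be > 0")
  if (abs(sum(p) - 1) > 1e-12) {
    stop("allele proportions must sum to 1 (got ", format(sum(p), digits = 15), ")")
  }
  p
}

#' Map a copy B:A read ratio to a proportion vector
#'
#' A ratio r gives two-copy proportions (1/(1+r), r/(1+r)). With
#' `alleles_per_copy = 2` each copy's mass is split equally between its two
#' alleles, giving a four-category vector.
#'
#' @param ratio B:A read ratio (> 0).
#' @param alleles_per_copy 1 (copy-level categories) or 2.
#' @return Proportion vector.
#' @export
ratio_to_proportions <- function(ratio, alleles_per_copy = 1L) {
  stopifnot(is.numeric(ratio), length(ratio) == 1L, ratio > 0,
            alleles_per_copy %in% c(1L, 2L))
  p <- c(1, ratio) / (1 + ratio)
  if (alleles_per_copy == 2L) p <- rep(p / 2, each = 2L)
  allele_proportions(p)
}

#' Probability that all alleles are observed in n reads
#'
#' Exact inclusion-exclusion over subsets S of the k categories:
#' P = sum_S (-1)^|S| (1 - sum_{i in S} p_i)^n. For n < k the probability is
#' exactly 0.
#'
#' @param p Allele-proportion vector (see [allele_proportions()]).
#' @param n Number of reads drawn (>= 0).
#' @return Probability in \[0, 1\].
#' @examples
#' prob_all_observed(c(0.5, 0.5), 2)        # 0.5
#' prob_all_observed(rep(0.25, 4), 4)       # 24/256
#' @export
prob_all_observed <- function(p, n) {
  p <- allele_proportions(p)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0, n == floor(n))
  k <- length(p)
  if (k > 20L) stop("inclusion-exclusion limited to 20 categories")
  if (n < k) return(0)
  total <- 0
  for (s in 0:(2^k - 1)) {
    members <- which(bitwAnd(s, bitwShiftL(1L, 0:(k - 1L))) != 0L)
    total <- total + (-1)^length(members) * (1 - sum(p[members]))^n
  }
  min(max(total, 0), 1)
}

#' Monte-Carlo estimate of the probability that all alleles are observed
#'
#' Simulates `reps` multinomial draws of `n` reads and reports the fraction
#' in which every category appears at least once.
#'
#' @inheritParams prob_all_observed
#' @param reps Number of simulation replicates (default 10000).
#' @param seed Optional integer seed; given the same seed the estimate is
#'   reproducible and the caller's RNG state is left untouched.
#' @return Probability estimate in \[0, 1\].
#' @export
prob_all_observed_mc <- function(p, n, reps = 10000L, seed = NULL) {
  p <- allele_proportions(p)
  stopifnot(reps >= 1L, n >= 0)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  if (n == 0L) return(if (length(p) == 0L) 1 else 0)
  counts <- rmultinom(reps, size = n, prob = p)
  mean(colSums(counts > 0L) == length(p))
}

#' Minimum read depth for a target confidence
#'
#' Smallest n such that the analytic probability of observing every allele
#' reaches `confidence`.
#'
#' @inheritParams prob_all_observed
#' @param confidence Target probability in (0, 1), default 0.95.
#' @return Integer read count.
#' @examples
#' min_reads(rep(0.25, 4))                       # 16
#' min_reads(ratio_to_proportions(1.29))         # 6
#' @export
min_reads <- function(p, confidence = 0.95) {
  p <- allele_proportions(p)
  stopifnot(confidence > 0, confidence < 1)
  n <- length(p)
  while (prob_all_observed(p, n) < confidence) n <- n + 1L
  as.integer(n)
}

#' Depth-probability curve
#'
#' Analytic probability of observing all alleles for n = 1..n_max, suitable
#' for plotting read-depth planning curves.
#'
#' @inheritParams prob_all_observed
#' @param n_max Largest read count tabulated.
#' @return Tibble with columns `n` and `probability` (monotone
#'   non-decreasing).
#' @export
depth_table <- function(p, n_max) {
  stopifnot(n_max >= 1L)
  tibble::tibble(
    n = seq_len(n_max),
    probability = vapply(seq_len(n_max), function(n) prob_all_observed(p, n),
                         numeric(1))
  )
}

#' Copy-amplification ratio by regression through the origin
#'
#' Regresses copy B read counts on copy A read counts with the intercept
#' forced through (0, 0): slope = sum(AB) / sum(A^2), i.e. the mean B:A
#' amplification ratio. A t-test asks whether the slope differs from 1
#' (equal amplification of the two copies), with n - 1 degrees of freedom.
#'
#' @param a,b Numeric vectors of copy A and copy B read counts per
#'   individual (same length, >= 2 pairs).
#' @return A list with `slope`, `standard_error`, `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, and `note` (non-empty for the
#'   degenerate perfect-fit case where the t statistic is infinite).
#' @export
copy_ratio_regression <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == length(b),
            length(a) >= 2L, !anyNA(a), !anyNA(b))
  if (sum(a^2) == 0) stop("all copy A counts are zero; slope undefined")
  n <- length(a)
  slope <- sum(a * b) / sum(a^2)
  df <- n - 1L
  rss <- sum((b - slope * a)^2)
  se <- sqrt((rss / df) / sum(a^2))
  note <- ""
  if (se == 0) {
    t_stat <- if (slope == 1) 0 else sign(slope - 1) * Inf
    p_val <- if (slope == 1) 1 else 0
    if (slope != 1) note <- "perfect fit: zero residual variance, t reported as infinite"
  } else {
    t_stat <- (slope - 1) / se
    p_val <- 2 * pt(-abs(t_stat), df = df)
  }
  list(slope = slope, standard_error = se, t_statistic = t_stat,
       degrees_of_freedom = df, p_value = p_val, note = note)
}
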