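# Oracle for the inclusion-exclusion engine: exhaustive enumeration of all
# k^n outcomes at tiny sizes.
prob_all_enum <- function(p, n) {
  k <- length(p)
  if (n < k) return(0)
  grids <- rep(list(seq_len(k)), n)
  outcomes <- as.matrix(expand.grid(grids))
  probs <- apply(outcomes, 1L, function(o) prod(p[o]))
  hit <- apply(outcomes, 1L, function(o) length(unique(o)) == k)
  sum(probs[hit])
}

test_that("analytic probability matches exhaustive enumeration at tiny n", {
  expect_equal(prob_all_observed(c(0.5, 0.5), 2), 0.5)
  # 4 equal alleles, n = 4: 4!/4^4 = 24/256, also by full enumeration
  expect_equal(prob_all_enum(rep(0.25, 4), 4), 24 / 256)
  expect_equal(prob_all_observed(rep(0.25, 4), 4), 24 / 256)
  for (p in list(c(0.3, 0.7), c(0.2, 0.3, 0.5), c(0.1, 0.2, 0.3, 0.4))) {
    for (n in length(p):6) {
      expect_equal(prob_all_observed(p, n), prob_all_enum(p, n),
                   tolerance = 1e-12)
    }
  }
})

test_that("two equal categories follow the closed form 1 - 2^(1-n)", {
  for (n in 1:50) {
    expect_equal(prob_all_observed(c(0.5, 0.5), n), 1 - 2^(1 - n),
                 tolerance = 1e-14)
  }
})

test_that("probability is 0 below k reads and monotone non-decreasing", {
  set.seed(11)
  for (rep in 1:25) {
    k <- sample(2:5, 1)
    p <- as.vector(stats::rgamma(k, 1)) + 0.05
    p <- p / sum(p)
    expect_identical(prob_all_observed(p, k - 1L), 0)
    tbl <- depth_table(p, 30L)
    expect_true(all(diff(tbl$probability) >= -1e-12))
    # permutation invariance
    expect_equal(prob_all_observed(sample(p), 12L), prob_all_observed(p, 12L))
  }
})

test_that("Monte-Carlo estimate agrees with the analytic engine", {
  p <- rep(0.25, 4)
  exact <- prob_all_observed(p, 15)
  est <- prob_all_observed_mc(p, 15, reps = 10000L, seed = 99L)
  expect_lt(abs(est - exact), 4 * sqrt(exact * (1 - exact) / 10000))
  expect_identical(est, prob_all_observed_mc(p, 15, reps = 10000L, seed = 99L))
  expect_equal(prob_all_observed_mc(c(1), 3, reps = 100L, seed = 1L), 1)
})

test_that("min_reads brackets the confidence threshold", {
  expect_identical(min_reads(c(1), 0.95), 1L)
  for (p in list(rep(0.25, 4), c(0.3, 0.7), ratio_to_proportions(1.87))) {
    n <- min_reads(p, 0.95)
    expect_gte(prob_all_observed(p, n), 0.95)
    expect_lt(prob_all_observed(p, n - 1L), 0.95)
  }
})

test_that("copy-ratio proportions and validation behave", {
  expect_equal(ratio_to_proportions(1), c(0.5, 0.5))
  expect_equal(ratio_to_proportions(1.29), c(1, 1.29) / 2.29)
  expect_equal(ratio_to_proportions(1.87, 2L),
               rep(c(1, 1.87) / 2.87 / 2, each = 2))
  expect_error(allele_proportions(c(0.5, 0.4)), "sum to 1")
  expect_error(allele_proportions(c(-0.5, 1.5)), "> 0")
})

test_that("origin-forced regression matches lm on random data", {
  r <- copy_ratio_regression(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$slope, 1)
  expect_equal(r$t_statistic, 0)
  r2 <- copy_ratio_regression(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r2$slope, 2)
  expect_identical(r2$standard_error, 0)
  expect_identical(r2$t_statistic, Inf)
  expect_match(r2$note, "perfect fit")
  set.seed(5)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    a <- stats::runif(n, 1, 50)
    b <- 1.5 * a + stats::rnorm(n, 0, 4)
    fit <- copy_ratio_regression(a, b)
    lm_fit <- summary(stats::lm(b ~ a + 0))
    expect_equal(fit$slope, unname(coef(lm_fit)[1, "Estimate"]))
    expect_equal(fit$standard_error, unname(coef(lm_fit)[1, "Std. Error"]))
    expect_identical(fit$degrees_of_freedom, n - 1L)
    # t here tests slope == 1, lm's t tests slope == 0
    expect_equal(fit$t_statistic,
                 (fit$slope - 1) / fit$standard_error)
  }
  expect_error(copy_ratio_regression(c(0, 0), c(1, 2)), "zero")
})
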