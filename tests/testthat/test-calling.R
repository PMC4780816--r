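# closed-form binomial upper tail, independent of the caller's pbinom route
binom_tail <- function(k, n, e) {
  sum(choose(n, k:n) * e^(k:n) * (1 - e)^(n - (k:n)))
}

test_that("binomial caller matches the closed-form tail and its boundary", {
  # 2 of 3 reads at 1% error: p = 3*e^2*(1-e) + e^3 = 2.98e-4 -> methylated
  r <- call_methylation(2L, 3L, 0.01)
  expect_equal(r$p_binomial, 3 * 0.01^2 * 0.99 + 0.01^3, tolerance = 1e-12)
  expect_equal(r$status, "methylated")
  # 1 of 3: p = 1 - 0.99^3 = 0.0297 -> unmethylated at alpha 0.01
  r <- call_methylation(1L, 3L, 0.01)
  expect_equal(r$p_binomial, 1 - 0.99^3, tolerance = 1e-12)
  expect_equal(r$status, "unmethylated")
  # 0 unconverted: p = 1 always
  expect_equal(call_methylation(0L, 7L, 0.01)$p_binomial, 1)
  expect_error(call_methylation(4L, 3L, 0.01), "exceeds")
  # closed-form agreement to 12 significant digits across n <= 50
  set.seed(3)
  for (i in 1:200) {
    n <- sample(1:50, 1L); k <- sample(0:n, 1L); e <- runif(1, 0.001, 0.2)
    expect_equal(call_methylation(k, n, e)$p_binomial, binom_tail(k, n, e),
                 tolerance = 1e-12)
  }
})

test_that("conversion-error estimate pools control reads", {
  expect_equal(estimate_conversion_error(
    make_counts(1L, 10L, 990L))$error_rate, 0.01)
  expect_equal(estimate_conversion_error(
    make_counts(1L, 0L, 500L))$error_rate, 0)
  expect_error(estimate_conversion_error(make_counts(1L, 0L, 0L)),
               "zero control coverage")
  # sampling oracle: estimate within 3 SE of the generating rate
  set.seed(11)
  e <- 0.012; n <- 1e5
  u <- rbinom(1L, n, e)
  est <- estimate_conversion_error(make_counts(1L, u, n - u))$error_rate
  expect_lt(abs(est - e), 3 * sqrt(e * (1 - e) / n))
})

test_that("Fisher exact p matches hand-enumerated tables and is symmetric", {
  # [[4,0],[0,4]]: only the two extreme tables are as improbable -> 2/70
  expect_equal(fisher_exact_p(4L, 0L, 0L, 4L), 2 / 70, tolerance = 1e-12)
  # [[3,0],[0,3]]: p = 0.1; at 3+3 coverage two-sided p can never reach 0.05
  expect_equal(fisher_exact_p(3L, 0L, 0L, 3L), 0.1, tolerance = 1e-12)
  expect_equal(fisher_exact_p(5L, 5L, 5L, 5L), 1)
  # invariances: swap samples; swap rows
  set.seed(5)
  a <- sample(0:12, 40, TRUE); b <- sample(0:12, 40, TRUE)
  c_ <- sample(0:12, 40, TRUE); d <- sample(0:12, 40, TRUE)
  p0 <- fisher_exact_p(a, b, c_, d)
  expect_equal(fisher_exact_p(c_, d, a, b), p0, tolerance = 1e-12)
  expect_equal(fisher_exact_p(b, a, d, c_), p0, tolerance = 1e-12)
})

test_that("vectorised FET agrees with stats::fisher.test on random tables", {
  set.seed(17)
  n <- 300
  a <- sample(0:15, n, TRUE); b <- sample(0:15, n, TRUE)
  c_ <- sample(0:15, n, TRUE); d <- sample(0:15, n, TRUE)
  keep <- (a + b) > 0 & (c_ + d) > 0
  p <- fisher_exact_p(a[keep], b[keep], c_[keep], d[keep])
  ref <- mapply(function(w, x, y, z) {
    stats::fisher.test(matrix(c(w, x, y, z), 2L, byrow = TRUE))$p.value
  }, a[keep], b[keep], c_[keep], d[keep])
  expect_equal(p, unname(ref), tolerance = 1e-9)
})

test_that("DMS calling applies coverage, significance, direction and CMS exclusion", {
  ca <- make_counts(c(10L, 20L, 30L, 40L), c(9L, 0L, 2L, 9L),
                    c(1L, 10L, 1L, 1L))
  cb <- make_counts(c(10L, 20L, 30L, 40L), c(0L, 0L, 2L, 9L),
                    c(10L, 2L, 1L, 1L))
  dms <- call_dms(ca, cb, min_cov = 3L, alpha_dms = 0.05)
  # site 10: 9/1 vs 0/10 -> significant, hyper in A
  expect_true(10L %in% dms$pos)
  expect_equal(dms[pos == 10L]$direction, "hyper_in_a")
  # site 30: identical fractions -> no DMS; site 40: identical -> p = 1
  expect_false(30L %in% dms$pos)
  expect_false(40L %in% dms$pos)
  # CMS exclusion keeps the sets disjoint
  cms_fake <- make_counts(10L, 1L, 1L)
  dms2 <- call_dms(ca, cb, exclude_cms = cms_fake)
  expect_false(10L %in% dms2$pos)
  expect_error(call_dms(ca, cb, min_cov = 0L), "min_cov")
})

test_that("CMS requires a methylated call in both tissues and excludes DMSs", {
  ca <- make_counts(c(1L, 2L, 3L), c(9L, 9L, 9L), c(1L, 1L, 1L))
  cb <- make_counts(c(1L, 2L, 3L), c(9L, 0L, 9L), c(1L, 10L, 1L))
  cms <- call_cms(ca, cb, error_rate_a = 0.01)
  expect_equal(sort(cms$pos), c(1L, 3L))
  # a methylated-in-both site with a significant FET is CMS, not DMS:
  # 9/1 vs 18/2 has equal fractions, make one lopsided instead
  ca2 <- make_counts(1L, 30L, 0L)
  cb2 <- make_counts(1L, 15L, 15L)
  cms2 <- call_cms(ca2, cb2, error_rate_a = 0.01)
  expect_equal(nrow(cms2), 1L)  # both pass the binomial test
  dms2 <- call_dms(ca2, cb2, exclude_cms = cms2)
  expect_equal(nrow(dms2), 0L)  # excluded despite FET p < 0.05
  expect_lt(fisher_exact_p(30L, 0L, 15L, 15L), 0.05)
})

test_that("FET type-I error on null counts stays at or below nominal", {
  set.seed(23)
  n <- 4000
  cov_a <- rpois(n, 15); cov_b <- rpois(n, 15)
  m <- 0.3  # same true level in both samples
  ua <- rbinom(n, cov_a, m); ub <- rbinom(n, cov_b, m)
  keep <- cov_a >= 3 & cov_b >= 3
  p <- fisher_exact_p(ua[keep], (cov_a - ua)[keep], ub[keep], (cov_b - ub)[keep])
  rate <- mean(p < 0.05)
  mc <- 3 * sqrt(0.05 * 0.95 / sum(keep))
  expect_lte(rate, 0.05 + mc)  # FET is conservative on discrete counts
})

test_that("BH adjustment reproduces the step-up by hand", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4L))
  expect_equal(fdr_adjust(0.037), 0.037)
  expect_equal(fdr_adjust(rep(1, 5L)), rep(1, 5L))
  expect_equal(fdr_adjust(numeric(0)), numeric(0))
})

test_that("direction bias test is an exact two-sided binomial", {
  expect_equal(direction_bias_test(rep(c("hyper_in_a", "hyper_in_b"), 50L))$p, 1)
  expect_equal(direction_bias_test(rep("hyper_in_b", 3L))$p, 0.25)
  # at the published scale, 57% of 500,245 is overwhelming
  dirs <- rep(c("hyper_in_b", "hyper_in_a"), c(285140L, 215105L))
  r <- direction_bias_test(dirs)
  expect_equal(r$fraction_hyper, 0.57, tolerance = 1e-3)
  expect_lt(r$p, 1e-15)
  expect_error(direction_bias_test(character(0)), "empty")
})

test_that("replicate combination is per-site count summation", {
  r1 <- make_counts(c(1L, 5L), c(2L, 0L), c(2L, 3L))
  r2 <- make_counts(c(1L, 9L), c(2L, 4L), c(2L, 1L))
  comb <- combine_replicates(list(r1, r2))
  expect_equal(comb[pos == 1L]$n_unconv, 4L)
  expect_equal(comb[pos == 1L]$n_conv, 4L)
  expect_equal(nrow(comb), 3L)
  # calling on the pre-summed table is identical
  cb <- make_counts(c(1L, 5L, 9L), c(0L, 1L, 0L), c(6L, 4L, 5L))
  d1 <- call_dms(comb, cb)
  d2 <- call_dms(combine_replicates(list(comb)), cb)
  expect_equal(d1, d2, ignore_attr = TRUE)
})
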