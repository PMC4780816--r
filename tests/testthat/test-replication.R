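test_that("truth set combines replicates by summation before calling", {
  r1 <- make_counts(c(1L, 5L), c(2L, 9L), c(2L, 1L))
  r2 <- make_counts(c(1L, 5L), c(2L, 9L), c(2L, 1L))
  f1 <- make_counts(c(1L, 5L), c(0L, 0L), c(4L, 10L))
  f2 <- make_counts(c(1L, 5L), c(0L, 0L), c(4L, 10L))
  tr <- build_truth_set(list(L = list(r1, r2), F = list(f1, f2)),
                        error_rates = 0.01)
  expect_equal(tr$combined$L[pos == 1L]$n_unconv, 4L)
  # identical to calling on the pre-summed tables
  direct <- call_dms(combine_replicates(list(r1, r2)),
                     combine_replicates(list(f1, f2)),
                     exclude_cms = tr$cms)
  expect_equal(tr$dms, direct, ignore_attr = TRUE)
  expect_error(build_truth_set(list(L = list(r1), F = list(f1, f2)), 0.01),
               "two replicates")
})

test_that("overlap and FPR obey their complement identity", {
  q <- make_counts(1:10, 5L, 5L)
  ref <- make_counts(6:20, 5L, 5L)
  ov <- overlap_with_reference(q, ref, denominator = "reference")
  expect_equal(ov$count, 5L)
  expect_equal(ov$pct, 100 * 5 / 15)
  expect_equal(overlap_with_reference(q, ref, "query")$pct, 50)
  # query subset of reference: 100% by query denominator
  expect_equal(overlap_with_reference(make_counts(6:10, 5L, 5L), ref,
                                      "query")$pct, 100)
  fpr <- false_positive_rate(q, ref)
  expect_equal(fpr$fpr_pct, 50)
  expect_equal(fpr$fpr_pct + overlap_with_reference(q, ref, "query")$pct, 100)
  # disjoint sets: FPR 100%, like an FDR-thinned set missing the truth
  expect_equal(false_positive_rate(make_counts(100:104, 5L, 5L), ref)$fpr_pct,
               100)
  expect_equal(false_positive_rate(ref, ref)$fpr_pct, 0)
  expect_error(overlap_with_reference(q, ref[0L]), "empty denominator")
})

test_that("interval overlap uses >= 1 bp intersection for DMRs", {
  q <- data.table::data.table(chrom = "chr1", start = c(100L, 900L),
                              end = c(200L, 950L))
  ref <- data.table::data.table(chrom = "chr1", start = 200L, end = 300L)
  expect_equal(overlap_with_reference(q, ref, "query")$count, 1L)
  expect_equal(overlap_with_reference(q, ref, "reference")$pct, 100)
})

test_that("permutation test matches exhaustive enumeration and is calibrated", {
  groups <- rep(c("between_tissue", "within_tissue"), c(9L, 6L))
  # all equal -> p = 1
  expect_equal(between_within_permutation_test(rep(3, 15L), groups)$p, 1)
  # maximal separation: only the true partition achieves the observed stat
  v <- c(rep(10, 9L), rep(1, 6L))
  ex <- between_within_permutation_test(v, groups, exact = TRUE)
  expect_equal(ex$n_partitions, 5005L)
  expect_equal(ex$p, 1 / 5005)
  # Monte-Carlo agrees with enumeration within 3 MC errors
  set.seed(13)
  v2 <- rnorm(15L)
  ex2 <- between_within_permutation_test(v2, groups, exact = TRUE)
  mc <- between_within_permutation_test(v2, groups, n_perm = 10000L, seed = 5L)
  tol <- 3 * sqrt(ex2$p * (1 - ex2$p) / 10000) + 2 / 10000
  expect_lt(abs(mc$p - ex2$p), tol)
  # determinism
  mc2 <- between_within_permutation_test(v2, groups, n_perm = 10000L, seed = 5L)
  expect_identical(mc$p, mc2$p)
  expect_warning(between_within_permutation_test(v2, groups, n_perm = 50L),
                 "n_perm")
})

test_that("neighbor joining recovers the 4-taxon additive tree exactly", {
  d <- matrix(0, 4L, 4L, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 3
  d["C", "D"] <- d["D", "C"] <- 7
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 6
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 7
  njt <- neighbor_joining(d)
  # the tree reproduces the distances exactly (additive matrix)
  coph <- ape::cophenetic.phylo(njt$tree)[rownames(d), colnames(d)]
  expect_equal(coph, d, tolerance = 1e-10)
  expect_true(tree_separates(njt$tree, c("A", "B")))
  # terminal branch lengths 1,2,3,4 and internal edge 1
  el <- njt$tree$edge.length
  tips <- njt$tree$edge[, 2L] <= 4L
  expect_equal(sort(el[tips]), 1:4, tolerance = 1e-10)
  expect_equal(el[!tips], 1, tolerance = 1e-10)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2L)), "symmetric")
})

test_that("NJ round-trips random additive trees (topology and lengths)", {
  set.seed(19)
  for (i in 1:20) {
    n <- sample(4:8, 1L)
    tr <- ape::rtree(n, rooted = FALSE)
    tr$edge.length <- runif(length(tr$edge.length), 0.2, 2)
    d <- ape::cophenetic.phylo(tr)
    rec <- neighbor_joining(d)$tree
    expect_equal(ape::dist.topo(ape::unroot(tr), rec), 0,
                 ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(rec)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
  }
})

test_that("block distance matrices cluster the two tissues apart", {
  nm <- c("L1", "L2", "L3", "F1", "F2", "F3")
  set.seed(29)
  d <- matrix(0, 6L, 6L, dimnames = list(nm, nm))
  for (i in 1:5) for (j in (i + 1):6) {
    within <- substr(nm[i], 1L, 1L) == substr(nm[j], 1L, 1L)
    d[i, j] <- d[j, i] <- if (within) runif(1, 1, 5) else runif(1, 15, 19)
  }
  njt <- neighbor_joining(d)
  expect_true(tree_separates(njt$tree, c("L1", "L2", "L3")))
})

test_that("distance matrix assembly from pairwise overlaps is symmetric and complete", {
  nm <- c("L1", "L2", "F1")
  pairs <- data.table::data.table(
    sample_a = c("L1", "L1", "L2"), sample_b = c("L2", "F1", "F1"),
    overlap_pct_truth = c(2, 15, 17))
  m <- distance_matrix_from_overlaps(pairs)
  expect_equal(m, t(m))
  expect_equal(m["L1", "F1"], 15)
  expect_equal(unname(diag(m)), rep(0, 3L))
  expect_error(distance_matrix_from_overlaps(pairs[1:2]), "missing")
})

test_that("pairwise comparisons separate between- from within-tissue signal on planted data", {
  cfg <- small_sim_config(seed = 4L)
  sim <- simulate_experiment(cfg)
  err <- estimate_conversion_error(
    combine_replicates(c(sim$controls$L, sim$controls$F)))$error_rate
  truth <- build_truth_set(sim$counts, error_rates = err)
  samples <- c(sim$counts$L, sim$counts$F)
  pairs <- pairwise_comparisons(samples, tissue_map6(), truth$dms)
  expect_equal(nrow(pairs), 15L)
  expect_equal(sum(pairs$group == "between_tissue"), 9L)
  expect_gt(mean(pairs[group == "between_tissue"]$n_dms),
            mean(pairs[group == "within_tissue"]$n_dms))
  expect_true(all(pairs$fpr_pct + pairs$overlap_pct_query - 100 < 1e-9,
                  na.rm = TRUE))
  perm <- between_within_permutation_test(pairs$n_dms, pairs$group,
                                          n_perm = 2000L, seed = 1L)
  expect_lt(perm$p, 0.01)
})

test_that("truth-set size grows with replication at fixed effect size", {
  cfg <- small_sim_config(seed = 8L)
  sim <- simulate_experiment(cfg)
  one <- build_truth_set(list(L = sim$counts$L[1:2], F = sim$counts$F[1:2]),
                         error_rates = 0.01)
  thr <- build_truth_set(sim$counts, error_rates = 0.01)
  expect_gt(nrow(thr$dms), nrow(one$dms))
})
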