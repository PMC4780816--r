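test_that("FPKM arithmetic and scaling laws hold", {
  expect_equal(compute_fpkm(1000, 1000, 1e6), 1000)
  expect_equal(compute_fpkm(0, 500, 1e6), 0)
  expect_equal(compute_fpkm(100, 2000, 2e6), compute_fpkm(100, 2000, 1e6) / 2)
  expect_error(compute_fpkm(10, 1000, 0), "mapped_reads")
})

test_that("expression table pools replicates and applies the FPKM filter", {
  counts <- data.table::data.table(
    gene = c("g1", "g2", "g3"), length_bp = 1000L,
    L1 = c(500L, 4L, 0L), L2 = c(500L, 4L, 0L),
    F1 = c(2000L, 4L, 50L), F2 = c(2000L, 4L, 50L))
  tof <- c(L1 = "L", L2 = "L", F1 = "F", F2 = "F")
  libs <- c(L1 = 1e6, L2 = 1e6, F1 = 1e6, F2 = 1e6)
  et <- expression_table(counts, tof, lib_sizes = libs, numerator = "F")
  # g1: FPKM 500 vs 2000 -> log2fc = 2
  expect_equal(et[gene == "g1"]$log2fc, 2)
  # g2: equal -> 0
  expect_equal(et[gene == "g2"]$log2fc, 0)
  # g3: FPKM 0 in leaf fails the both-tissues filter
  expect_false(et[gene == "g3"]$expressed)
  expect_true(is.na(et[gene == "g3"]$log2fc))
  # "either" rule admits it but log2fc stays undefined at zero denominator
  et2 <- expression_table(counts, tof, lib_sizes = libs,
                          filter_rule = "either", numerator = "F")
  expect_true(et2[gene == "g3"]$expressed)
  expect_true(is.na(et2[gene == "g3"]$log2fc))
  # sub-cutoff FPKM (0.01) is excluded by the 0.02 rule
  counts2 <- data.table::data.table(gene = "g", length_bp = 1000L,
                                    L1 = 1L, F1 = 100000L)
  et3 <- expression_table(counts2, c(L1 = "L", F1 = "F"),
                          lib_sizes = c(L1 = 1e8, F1 = 1e8), numerator = "F")
  expect_false(et3$expressed)
})

test_that("Spearman correlations match rank-then-Pearson with midranks", {
  res <- delta_prop_vs_expression(
    data.table::data.table(gene = c("a", "b", "c"), region = "gene",
                           context = "CG", delta = c(1, 2, 3)),
    data.table::data.table(gene = c("a", "b", "c"), expressed = TRUE,
                           log2fc = c(3, 1, 2), de_flag = FALSE))
  expect_equal(res$rho, -0.5)
  # perfectly decreasing -> rho = -1
  res2 <- delta_prop_vs_expression(
    data.table::data.table(gene = letters[1:5], region = "gene",
                           context = "CG", delta = 1:5),
    data.table::data.table(gene = letters[1:5], expressed = TRUE,
                           log2fc = 5:1, de_flag = FALSE))
  expect_equal(res2$rho, -1)
  # ties: agreement with independent midrank computation on random data
  set.seed(37)
  for (i in 1:10) {
    x <- sample(1:5, 30L, TRUE); y <- sample(1:5, 30L, TRUE)
    res3 <- delta_prop_vs_expression(
      data.table::data.table(gene = paste0("g", 1:30), region = "r",
                             context = "CG", delta = x),
      data.table::data.table(gene = paste0("g", 1:30), expressed = TRUE,
                             log2fc = y, de_flag = FALSE))
    expect_equal(res3$rho, stats::cor(rank(x), rank(y)), tolerance = 1e-12)
  }
})

test_that("Holm flags sit between Bonferroni and unadjusted rejection", {
  set.seed(43)
  n_tests <- 12L
  dp <- data.table::rbindlist(lapply(1:n_tests, function(k) {
    data.table::data.table(gene = paste0("g", 1:40),
                           region = paste0("r", (k - 1) %/% 4 + 1),
                           context = c("CG", "CHG", "CHH", "all")[(k - 1) %% 4 + 1],
                           delta = rnorm(40))
  }))
  expr <- data.table::data.table(gene = paste0("g", 1:40), expressed = TRUE,
                                 log2fc = rnorm(40), de_flag = FALSE)
  dp[region == "r1" & context == "CG", delta := -expr$log2fc[match(gene, expr$gene)] + rnorm(.N, 0, 0.1)]
  res <- delta_prop_vs_expression(dp, expr, alpha = 0.05)
  bonf <- res$p * n_tests < 0.05
  raw <- res$p < 0.05
  expect_true(all(res$significant[bonf]))      # Holm rejects a superset of Bonferroni
  expect_true(all(raw[res$significant]))       # and a subset of unadjusted
  expect_true(res[region == "r1" & context == "CG"]$significant)
  expect_lt(res[region == "r1" & context == "CG"]$rho, 0)
})

test_that("DMR-gene distance test is deterministic and uniform under the null", {
  set.seed(47)
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1000L, 96000L, by = 5000L), width = 2000L))
  names(genes) <- paste0("g", seq_along(genes))
  dmrs <- data.table::data.table(chrom = "chr1",
                                 start = sample(90000L, 12L),
                                 end = 0L)
  dmrs[, end := start + 50L]
  flags <- rep(FALSE, length(genes)); flags[sample(length(genes), 6L)] <- TRUE
  r1 <- dmr_gene_distance_test(dmrs, genes, flags, n_randomizations = 300L,
                               seed = 3L)
  r2 <- dmr_gene_distance_test(dmrs, genes, flags, n_randomizations = 300L,
                               seed = 3L)
  expect_identical(r1$p, r2$p)
  expect_gte(r1$p, 0); expect_lte(r1$p, 1)
  # DMRs inside DE genes -> observed mean 0
  inside <- data.table::data.table(chrom = "chr1",
                                   start = BiocGenerics::start(genes[flags]) + 10L,
                                   end = BiocGenerics::start(genes[flags]) + 40L)
  r0 <- dmr_gene_distance_test(inside, genes, flags, n_randomizations = 100L,
                               seed = 1L)
  expect_equal(r0$observed_mean_bp, 0)
  # calibration: with random DE labels the p-value is uniform (KS at desk scale)
  ps <- replicate(60, {
    fl <- rep(FALSE, length(genes)); fl[sample(length(genes), 6L)] <- TRUE
    dm <- data.table::data.table(chrom = "chr1", start = sample(90000L, 8L))
    dm[, end := start + 50L]
    dmr_gene_distance_test(dm, genes, fl, n_randomizations = 40L,
                           seed = sample.int(1e6, 1L))$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.001)
  expect_error(dmr_gene_distance_test(dmrs, genes, rep(FALSE, length(genes))),
               "no differentially expressed")
})

test_that("hyper-DMR grouping shifts expression in the planted direction", {
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1000L, 40000L, by = 2000L), width = 1000L))
  names(genes) <- paste0("g", seq_along(genes))
  set.seed(53)
  lfc <- rnorm(length(genes), 0, 0.3)
  hyper_b <- 1:5; hyper_a <- 6:10          # DMR in genes 1..10
  lfc[hyper_b] <- lfc[hyper_b] - 2         # hyper in B (flower) -> repressed in B
  lfc[hyper_a] <- lfc[hyper_a] + 2
  expr <- data.table::data.table(gene = names(genes), expressed = TRUE,
                                 log2fc = lfc, de_flag = FALSE)
  dmrs <- data.table::data.table(
    chrom = "chr1",
    start = BiocGenerics::start(genes[c(hyper_b, hyper_a)]) + 100L,
    end = BiocGenerics::start(genes[c(hyper_b, hyper_a)]) + 200L,
    direction = rep(c("hyper_in_b", "hyper_in_a"), each = 5L))
  g <- hyper_dmr_expression_contrast(dmrs, genes, expr)
  expect_equal(g[group == "hyper_in_b"]$n, 5L)
  expect_equal(g[group == "none"]$n, length(genes) - 10L)
  expect_lt(g[group == "hyper_in_b"]$median, g[group == "none"]$median)
  expect_gt(g[group == "hyper_in_a"]$median, g[group == "none"]$median)
  # no DMRs at all -> everything in "none"
  g0 <- hyper_dmr_expression_contrast(dmrs[0L], genes, expr)
  expect_equal(g0[group == "none"]$n, length(genes))
  expect_equal(g0[group == "hyper_in_a"]$n, 0L)
})

test_that("TSS profiles localise planted methylation and mirror on the minus strand", {
  # plus-strand gene at 2001..4000 (TSS 2001); minus-strand gene at
  # 6001..8000 (TSS 8000); plant a CG methylation zenith 701-750 bp upstream
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(2001L, 6001L), c(4000L, 8000L)), strand = c("+", "-"))
  names(genes) <- c("gp", "gm")
  pos_plus <- 2001L - seq(10L, 990L, by = 20L)       # upstream of gp
  pos_minus <- 8000L + seq(10L, 990L, by = 20L)      # upstream of gm
  zen_p <- 2001L - 701L:750L
  zen_m <- 8000L + 701L:750L
  tab <- make_counts(c(pos_plus, pos_minus, zen_p, zen_m),
                     n_unconv = c(rep(1L, 100L), rep(9L, 100L)),
                     n_conv = c(rep(9L, 100L), rep(1L, 100L)),
                     context = "CG")
  prof <- tss_methylation_profile(tab, genes, bin_bp = 50L)
  cg <- prof[context == "CG" & !is.na(prop)]
  expect_equal(cg[which.max(cg$prop)]$bin_start, 701L)
  # flat methylation -> flat profile
  tab2 <- make_counts(c(pos_plus, pos_minus), 5L, 5L, context = "CG")
  prof2 <- tss_methylation_profile(tab2, genes, bin_bp = 50L)
  expect_true(all(abs(prof2[context == "CG" & !is.na(prop)]$prop - 0.5) < 1e-12))
})

test_that("sliding windows conserve counts and respect chromosome ends", {
  items <- make_counts(c(100L, 200L, 40100L), 1L, 1L)
  d <- sliding_window_density(items, c(chr1 = 60000L), window_bp = 50000L,
                              step_bp = 50000L)
  expect_equal(sum(d$count[c(1L, 2L)]), 3L)
  expect_equal(d$end[nrow(d)], 60000L)
  # non-overlapping windows partition the items
  d2 <- sliding_window_density(items, c(chr1 = 60000L), window_bp = 10000L,
                               step_bp = 10000L)
  expect_equal(sum(d2$count), nrow(items))
  # Poisson sanity: uniform items give approximately flat density
  set.seed(59)
  u <- make_counts(sort(sample(1e6, 3000L)), 1L, 1L)
  d3 <- sliding_window_density(u, c(chr1 = 1000000L), window_bp = 50000L,
                               step_bp = 50000L)
  chi <- sum((d3$count - mean(d3$count))^2 / mean(d3$count))
  expect_lt(chi, qchisq(0.999, nrow(d3) - 1L))
})

test_that("nearest-TE assignment breaks ties toward the smaller start", {
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5000L, 6000L))
  names(genes) <- "g"
  tes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(4800L, 6100L, 9000L), c(4900L, 6200L, 9100L)))
  names(tes) <- c("left", "right", "far")
  nt <- nearest_te_per_gene(genes, tes)
  expect_equal(BiocGenerics::start(nt), 4800L)  # both gaps 99 bp; left wins
  expect_equal(S4Vectors::mcols(nt)$distance, 99L)
})

test_that("the TE linear model recovers exact and noisy coefficients", {
  set.seed(61)
  x1 <- rnorm(50); x2 <- rnorm(50)
  fit <- te_distance_linear_model(x1, x2, 2 * x1 + 0 * x2)
  expect_equal(unname(fit$coefficients["delta_prop", "Estimate"]), 2,
               tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["distance", "Estimate"]), 0,
               tolerance = 1e-10)
  # planted effect: methylation term recovered, distance term null
  n <- 2000L
  dp <- rnorm(n); dist <- runif(n, 0, 5e4)
  y <- -1 * dp + 0 * dist + rnorm(n)
  fit2 <- te_distance_linear_model(dp, dist, y)
  est <- fit2$coefficients["delta_prop", ]
  expect_lt(abs(est[["Estimate"]] - (-1)), 3 * est[["Std. Error"]])
  expect_false(fit2$collinear)
  expect_error(te_distance_linear_model(1:3, 1:3, 1:3), "complete cases")
})
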