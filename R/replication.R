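#' Combined-replicate "truth" DMS set
#'
#' Sums counts site-wise across the replicates of each tissue and calls DMSs
#' (and the CMS exclusion set) on the combined tables with the same caller
#' settings used for pairwise comparisons. Following the replication
#' analysis, this combined-data set serves as the best available estimate of
#' true between-tissue DMSs; false-positive rates computed against it are
#' *relative* FPRs, since the combined set itself contains false positives.
#'
#' @param counts_by_tissue Named list of two tissues, each a list of
#'   replicate count tables (>= 2 replicates each).
#' @param error_rates Named per-tissue conversion-error rates (for the CMS
#'   exclusion); a single number is recycled.
#' @param min_cov,alpha_dms,alpha_meth Caller settings (defaults 3, 0.05,
#'   0.01).
#' @return List: `dms` (the truth DMS table), `cms`, and the combined
#'   per-tissue count tables.
#' @export
build_truth_set <- function(counts_by_tissue, error_rates, min_cov = 3L,
                            alpha_dms = 0.05, alpha_meth = 0.01) {
  stopifnot(length(counts_by_tissue) == 2L)
  if (any(vapply(counts_by_tissue, length, 1L) < 2L)) {
    stop("each tissue needs at least two replicates")
  }
  if (length(error_rates) == 1L) {
    error_rates <- rep(error_rates, 2L)
    names(error_rates) <- names(counts_by_tissue)
  }
  comb <- lapply(counts_by_tissue, combine_replicates)
  tis <- names(comb)
  cms <- call_cms(comb[[1L]], comb[[2L]],
                  error_rate_a = error_rates[[tis[1L]]],
                  error_rate_b = error_rates[[tis[2L]]],
                  alpha_meth = alpha_meth)
  dms <- call_dms(comb[[1L]], comb[[2L]], min_cov = min_cov,
                  alpha_dms = alpha_dms, exclude_cms = cms)
  list(dms = dms, cms = cms, combined = comb, tissues = tis)
}

#' Overlap of a call set with a reference set
#'
#' Site sets are matched by identity on (chrom, pos, strand); DMR/interval
#' sets by >= 1 bp intersection. The percentage can be expressed against
#' either denominator, which matters: a pairwise set's overlap *of the
#' reference* and the fraction *of its own calls* that are supported differ
#' whenever the set sizes differ.
#'
#' @param query,reference Site tables (with `pos`) or interval tables (with
#'   `start`/`end`).
#' @param denominator `"reference"` (default) or `"query"`.
#' @return List `count` (matching query items, or overlapped reference items
#'   when `denominator = "reference"` for intervals) and `pct`.
#' @export
overlap_with_reference <- function(query, reference,
                                   denominator = c("reference", "query")) {
  denominator <- match.arg(denominator)
  if ("pos" %in% names(query)) {
    qk <- paste(query$chrom, query$pos, query$strand)
    rk <- paste(reference$chrom, reference$pos, reference$strand)
    count <- sum(qk %in% rk)
  } else {
    qg <- GenomicRanges::GRanges(query$chrom,
                                 IRanges::IRanges(query$start, query$end))
    rg <- GenomicRanges::GRanges(reference$chrom,
                                 IRanges::IRanges(reference$start, reference$end))
    count <- if (denominator == "reference") {
      sum(IRanges::overlapsAny(rg, qg))
    } else {
      sum(IRanges::overlapsAny(qg, rg))
    }
  }
  denom <- if (denominator == "reference") nrow(reference) else nrow(query)
  if (denom == 0L) stop("empty denominator set")
  list(count = count, pct = 100 * count / denom)
}

#' Relative false-positive rate of a pairwise call set
#'
#' The fraction of calls from a single-replicate comparison that are absent
#' from the combined-replicate truth set:
#' `fpr_pct = 100 * (1 - shared / |pair_set|)`.
#'
#' @param pair_set Call set from one pairwise comparison (nonempty).
#' @param truth_set The combined-data reference set.
#' @return List `shared`, `n_pair`, `fpr_pct`.
#' @export
false_positive_rate <- function(pair_set, truth_set) {
  if (nrow(pair_set) == 0L) stop("empty pair set: FPR undefined")
  shared <- overlap_with_reference(pair_set, truth_set,
                                   denominator = "query")$count
  list(shared = shared, n_pair = nrow(pair_set),
       fpr_pct = 100 * (1 - shared / nrow(pair_set)))
}

#' All pairwise DMS (or DMR) comparisons among replicates
#'
#' Runs the caller on every unordered pair of the six samples, records the
#' number of calls, the overlap with the truth set (both denominators) and
#' the relative FPR, and labels each pair within- or between-tissue.
#'
#' @param samples Named list of per-sample count tables (names like
#'   `L1..L3`, `F1..F3`).
#' @param tissue_of Named character vector mapping sample -> tissue.
#' @param truth_dms Truth DMS table from [build_truth_set()].
#' @param min_cov,alpha_dms Caller settings.
#' @param dmr_args Optional list to also build DMRs per pair:
#'   `list(sites=, cms=, threshold=, max_gap=, truth_dmrs=)`.
#' @return data.table, one row per pair: `sample_a`, `sample_b`, `group`,
#'   `n_dms`, `overlap_truth`, `overlap_pct_truth` (reference denominator),
#'   `overlap_pct_query`, `fpr_pct`, and DMR columns when requested.
#' @export
pairwise_comparisons <- function(samples, tissue_of, truth_dms,
                                 min_cov = 3L, alpha_dms = 0.05,
                                 dmr_args = NULL) {
  nm <- names(samples)
  pairs <- utils::combn(nm, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    dms <- call_dms(samples[[a]], samples[[b]], min_cov = min_cov,
                    alpha_dms = alpha_dms)
    grp <- if (tissue_of[[a]] == tissue_of[[b]]) "within_tissue" else "between_tissue"
    ov_t <- if (nrow(dms)) overlap_with_reference(dms, truth_dms, "reference") else list(count = 0L, pct = 0)
    ov_q <- if (nrow(dms)) overlap_with_reference(dms, truth_dms, "query") else list(count = 0L, pct = NA_real_)
    fpr <- if (nrow(dms)) false_positive_rate(dms, truth_dms)$fpr_pct else NA_real_
    row <- data.table::data.table(
      sample_a = a, sample_b = b, group = grp, n_dms = nrow(dms),
      overlap_truth = ov_t$count, overlap_pct_truth = ov_t$pct,
      overlap_pct_query = ov_q$pct, fpr_pct = fpr)
    if (!is.null(dmr_args)) {
      cms <- call_cms(samples[[a]], samples[[b]], dmr_args$error_rate,
                      alpha_meth = dmr_args$alpha_meth %||% 0.01)
      dms2 <- call_dms(samples[[a]], samples[[b]], min_cov = min_cov,
                       alpha_dms = alpha_dms, exclude_cms = cms)
      cls <- classify_sites(dmr_args$sites, cms, dms2)
      dmrs <- call_dmrs(build_runs(cls, dmr_args$max_gap %||% 500L),
                        threshold = dmr_args$threshold %||% 5L)
      row[, n_dmr := nrow(dmrs)]
      if (!is.null(dmr_args$truth_dmrs) && nrow(dmrs)) {
        row[, dmr_overlap_pct := overlap_with_reference(
          dmrs, dmr_args$truth_dmrs, "reference")$pct]
        row[, dmr_fpr_pct := false_positive_rate(dmrs, dmr_args$truth_dmrs)$fpr_pct]
      }
    }
    row
  })
  data.table::rbindlist(rows, fill = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Permutation test: between-tissue vs within-tissue differentiation
#'
#' Tests whether the mean pairwise statistic (e.g. DMS count) is higher for
#' between-tissue pairs than within-tissue pairs. The unit of permutation is
#' the pairwise value: the observed statistic `mean(between) - mean(within)`
#' is compared to the null obtained by re-partitioning the values into
#' random groups of the same sizes. With 6 samples there are 15 pairwise
#' values (9 between, 6 within) and C(15,6) = 5005 distinct partitions, so
#' the exact enumeration is also available.
#'
#' @param values Numeric vector of pairwise statistics.
#' @param groups Character vector, `"between_tissue"`/`"within_tissue"`.
#' @param n_perm Monte-Carlo permutations (default 10000; a warning below
#'   100).
#' @param seed Integer seed.
#' @param exact If `TRUE`, enumerate all partitions (feasible for 15
#'   values) instead of sampling.
#' @return List: `statistic`, `p`, `n_perm` (or `n_partitions`), `method`.
#' @export
between_within_permutation_test <- function(values, groups, n_perm = 10000L,
                                            seed = 1L, exact = FALSE) {
  stopifnot(length(values) == length(groups))
  is_b <- groups == "between_tissue"
  stat <- function(b) mean(values[b]) - mean(values[!b])
  obs <- stat(is_b)
  n <- length(values)
  k <- sum(!is_b)
  if (exact) {
    combs <- utils::combn(n, k)
    null <- apply(combs, 2L, function(w) {
      b <- rep(TRUE, n); b[w] <- FALSE; stat(b)
    })
    p <- mean(null >= obs)
    return(list(statistic = obs, p = p, n_partitions = ncol(combs),
                method = "exact"))
  }
  if (n_perm < 100L) warning("n_perm < 100: p-value resolution is poor")
  set.seed(seed)
  null <- replicate(n_perm, {
    b <- rep(TRUE, n); b[sample.int(n, k)] <- FALSE; stat(b)
  })
  p <- (1 + sum(null >= obs)) / (n_perm + 1)
  list(statistic = obs, p = p, n_perm = n_perm, method = "monte-carlo")
}

#' Distance matrix for clustering from pairwise overlap percentages
#'
#' Uses the pairwise overlap-with-truth percentages directly as the distance
#' between two samples, mirroring the lower-matrix-as-distance construction
#' used for the methylome clustering figures.
#'
#' @param pairs Output of [pairwise_comparisons()].
#' @param value Column to use (default `"overlap_pct_truth"`).
#' @return Symmetric numeric matrix with zero diagonal, labelled by sample.
#' @export
distance_matrix_from_overlaps <- function(pairs, value = "overlap_pct_truth") {
  nm <- sort(unique(c(pairs$sample_a, pairs$sample_b)))
  n <- length(nm)
  if (nrow(pairs) != n * (n - 1) / 2) stop("missing pairwise comparisons")
  m <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$sample_a[i]; b <- pairs$sample_b[i]
    m[a, b] <- m[b, a] <- pairs[[value]][i]
  }
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via [ape::nj()]) on a symmetric,
#' zero-diagonal, non-negative distance matrix; returns the unrooted tree
#' and its Newick string.
#'
#' @param d Distance matrix (labelled).
#' @param labels Optional tip labels overriding the matrix dimnames.
#' @return List: `tree` ([ape::phylo]) and `newick` (character).
#' @export
neighbor_joining <- function(d, labels = NULL) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric")
  }
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  if (any(d < 0)) stop("distances must be non-negative")
  if (!is.null(labels)) dimnames(d) <- list(labels, labels)
  tree <- ape::nj(stats::as.dist(d))
  list(tree = tree, newick = ape::write.tree(tree))
}

#' Does a tree split two tissues onto the two sides of one edge?
#'
#' Utility for clustering checks: `TRUE` when the tip set of some internal
#' edge is exactly the given group (a monophyletic bipartition of the
#' unrooted tree).
#'
#' @param tree An [ape::phylo] tree.
#' @param tips Character vector naming one side of the expected split.
#' @return Logical.
#' @export
tree_separates <- function(tree, tips) {
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  target <- sort(match(tips, labs))
  comp <- sort(setdiff(seq_along(labs), target))
  any(vapply(parts, function(p) identical(sort(p), target) ||
               identical(sort(p), comp), logical(1)))
}
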