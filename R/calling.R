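#' Fisher's exact test p-values for 2x2 methylation tables, vectorised
#'
#' Computes the exact hypergeometric p-value for each site's 2x2 table of
#' (unconverted, converted) reads across two samples. The two-sided p sums
#' the probabilities of all tables with the observed margins whose point
#' probability does not exceed the observed one (the classic Fisher
#' definition, identical to [stats::fisher.test()]); one-sided alternatives
#' are tail sums over the unconverted count of sample A. Identical tables
#' are memoised, which makes genome-scale calling fast because coverage is
#' low and tables repeat heavily.
#'
#' @param a_unconv,a_conv,b_unconv,b_conv Integer vectors: the per-site 2x2
#'   entries for samples A and B.
#' @param alternative `"two.sided"` (default), `"greater"` (A more
#'   methylated) or `"less"`.
#' @return Numeric vector of p-values.
#' @export
fisher_exact_p <- function(a_unconv, a_conv, b_unconv, b_conv,
                           alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  n <- length(a_unconv)
  stopifnot(length(a_conv) == n, length(b_unconv) == n, length(b_conv) == n)
  if (n == 0L) return(numeric(0))
  if (any(c(a_unconv, a_conv, b_unconv, b_conv) < 0)) {
    stop("counts must be non-negative")
  }
  key <- paste(a_unconv, a_conv, b_unconv, b_conv, sep = ",")
  first <- !duplicated(key)
  idx <- which(first)
  pu <- vapply(idx, function(i) {
    .fet_one(a_unconv[i], a_conv[i], b_unconv[i], b_conv[i], alternative)
  }, numeric(1))
  pu[match(key, key[first])]
}

.fet_one <- function(a, b, c, d, alternative) {
  m <- a + c          # unconverted margin
  nn <- b + d         # converted margin
  k <- a + b          # sample A total
  if (k == 0L || c + d == 0L || (m == 0L && nn == 0L)) return(1)
  lo <- max(0L, k - nn)
  hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, nn, k)
  pobs <- probs[a - lo + 1L]
  p <- switch(alternative,
    two.sided = sum(probs[probs <= pobs * (1 + 1e-7)]),
    greater   = sum(probs[support >= a]),
    less      = sum(probs[support <= a])
  )
  min(p, 1)
}

#' Pooled bisulfite conversion-error estimate from an unmethylated control
#'
#' On a control region assumed fully unmethylated (in the source organism,
#' contaminating chloroplast reads), every unconverted read is a conversion
#' failure, so the pooled unconverted fraction estimates the conversion error
#' directly.
#'
#' @param control_counts Count table (as from [read_count_table()]) for the
#'   control region, or anything with `n_unconv`/`n_conv` columns.
#' @return List with `error_rate`, `n_control_reads` and `n_unconverted`.
#' @export
estimate_conversion_error <- function(control_counts) {
  u <- sum(control_counts$n_unconv)
  tot <- u + sum(control_counts$n_conv)
  if (tot == 0) {
    stop("zero control coverage: supply an error rate explicitly")
  }
  list(error_rate = u / tot, n_control_reads = tot, n_unconverted = u)
}

#' Per-site binomial methylation call
#'
#' A site is called methylated when its unconverted read count is improbably
#' large under the conversion-error null: the upper-tail binomial probability
#' `P(X >= n_unconv | n_total, error_rate)` is at most `alpha_meth`. The test
#' is upper-tail only because methylation can only inflate unconverted counts
#' above the error rate. Sites below `min_cov` are `no_call`.
#'
#' @param n_unconv,n_total Integer vectors of unconverted and total reads.
#' @param error_rate Conversion-error rate in (0, 1).
#' @param alpha_meth Significance level (default 0.01).
#' @param min_cov Minimum coverage for a call (default 1).
#' @return data.table with `p_binomial` and `status`
#'   (`methylated`/`unmethylated`/`no_call`).
#' @export
call_methylation <- function(n_unconv, n_total, error_rate,
                             alpha_meth = 0.01, min_cov = 1L) {
  if (any(n_unconv > n_total)) stop("n_unconv exceeds n_total")
  if (any(n_unconv < 0 | n_total < 0)) stop("negative counts")
  stopifnot(error_rate > 0, error_rate < 1)
  p <- stats::pbinom(n_unconv - 1L, n_total, error_rate, lower.tail = FALSE)
  status <- ifelse(n_total < min_cov, "no_call",
                   ifelse(p <= alpha_meth & n_total > 0, "methylated",
                          "unmethylated"))
  data.table::data.table(p_binomial = p, status = status)
}

#' Conserved methylated sites (CMS) between two tissues
#'
#' A CMS is a cytosine called methylated by the binomial test in *both*
#' tissues, each tissue using its replicate-combined counts and its own
#' conversion-error rate.
#'
#' @param counts_a,counts_b Combined count tables for the two tissues.
#' @param error_rate_a,error_rate_b Per-tissue conversion-error rates.
#' @param alpha_meth Binomial significance level (default 0.01).
#' @param min_cov Minimum per-tissue coverage for a call (default 1).
#' @return data.table of CMS sites with per-tissue binomial p-values.
#' @export
call_cms <- function(counts_a, counts_b, error_rate_a, error_rate_b = error_rate_a,
                     alpha_meth = 0.01, min_cov = 1L) {
  j <- .join_sites(counts_a, counts_b)
  ca <- call_methylation(j$n_unconv_a, j$n_unconv_a + j$n_conv_a,
                         error_rate_a, alpha_meth, min_cov)
  cb <- call_methylation(j$n_unconv_b, j$n_unconv_b + j$n_conv_b,
                         error_rate_b, alpha_meth, min_cov)
  keep <- ca$status == "methylated" & cb$status == "methylated"
  out <- j[keep]
  out[, p_binomial_a := ca$p_binomial[keep]]
  out[, p_binomial_b := cb$p_binomial[keep]]
  out[]
}

.join_sites <- function(counts_a, counts_b) {
  a <- data.table::as.data.table(counts_a)
  b <- data.table::as.data.table(counts_b)
  keys <- c("chrom", "pos", "strand", "context")
  j <- merge(a, b, by = keys, suffixes = c("_a", "_b"))
  data.table::setkeyv(j, c("chrom", "pos", "strand"))
  j
}

#' Differentially methylated sites (DMS) between two samples
#'
#' Sites covered by at least `min_cov` reads in *each* sample are tested with
#' Fisher's exact test on the 2x2 table of unconverted vs converted reads;
#' a site is a DMS when p < `alpha_dms`. The direction records which sample
#' has the larger methylated (unconverted) fraction. Sites present in an
#' optional CMS set are excluded, keeping the CMS and DMS sets mutually
#' exclusive; ties in direction are dropped.
#'
#' @param counts_a,counts_b Count tables for the two samples.
#' @param min_cov Minimum per-sample coverage (default 3).
#' @param alpha_dms FET significance level (default 0.05).
#' @param alternative Sidedness of the FET (default two-sided).
#' @param exclude_cms Optional CMS table; overlapping sites are removed.
#' @return data.table of DMS records: site key, 2x2 counts, `p`, `direction`
#'   (`hyper_in_a`/`hyper_in_b`).
#' @export
call_dms <- function(counts_a, counts_b, min_cov = 3L, alpha_dms = 0.05,
                     alternative = "two.sided", exclude_cms = NULL) {
  if (min_cov < 1L) stop("min_cov must be >= 1")
  j <- .join_sites(counts_a, counts_b)
  tot_a <- j$n_unconv_a + j$n_conv_a
  tot_b <- j$n_unconv_b + j$n_conv_b
  j <- j[tot_a >= min_cov & tot_b >= min_cov]
  if (nrow(j) == 0L) return(.empty_dms())
  p <- fisher_exact_p(j$n_unconv_a, j$n_conv_a, j$n_unconv_b, j$n_conv_b,
                      alternative = alternative)
  j[, p := p]
  j <- j[p < alpha_dms]
  if (nrow(j) == 0L) return(.empty_dms())
  frac_a <- j$n_unconv_a / (j$n_unconv_a + j$n_conv_a)
  frac_b <- j$n_unconv_b / (j$n_unconv_b + j$n_conv_b)
  j[, direction := ifelse(frac_a > frac_b, "hyper_in_a", "hyper_in_b")]
  j <- j[frac_a != frac_b]   # guard: equal fractions carry no direction
  if (!is.null(exclude_cms) && nrow(j) > 0L) {
    cmskey <- paste(exclude_cms$chrom, exclude_cms$pos, exclude_cms$strand)
    j <- j[!paste(chrom, pos, strand) %in% cmskey]
  }
  data.table::setkeyv(j, c("chrom", "pos", "strand"))
  j[]
}

.empty_dms <- function() {
  data.table::data.table(chrom = character(), pos = integer(),
                         strand = character(), context = character(),
                         n_unconv_a = integer(), n_conv_a = integer(),
                         n_unconv_b = integer(), n_conv_b = integer(),
                         p = numeric(), direction = character())
}

#' Benjamini-Hochberg q-values
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Step-up q-values (monotone in rank), via [stats::p.adjust()].
#' @export
fdr_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  stats::p.adjust(p_values, method = "BH")
}

#' Test the tissue bias in DMS/DMR direction
#'
#' Under no tissue preference, hyper-in-A and hyper-in-B calls are equally
#' likely; the deviation is assessed with a two-sided exact binomial test
#' against 0.5.
#'
#' @param directions Character vector of direction labels, or a DMS/DMR
#'   table with a `direction` column.
#' @param hyper_level The level counted as "successes" (default
#'   `"hyper_in_b"`).
#' @return List: `n`, `n_hyper`, `fraction_hyper`, `p`.
#' @export
direction_bias_test <- function(directions, hyper_level = "hyper_in_b") {
  if (is.data.frame(directions)) directions <- directions$direction
  n <- length(directions)
  if (n == 0L) stop("empty direction set")
  k <- sum(directions == hyper_level)
  p <- stats::binom.test(k, n, p = 0.5, alternative = "two.sided")$p.value
  list(n = n, n_hyper = k, fraction_hyper = k / n, p = p)
}

#' Combine replicate count tables by per-site summation
#'
#' @param tables List of count tables for the replicates of one tissue.
#' @return One count table with counts summed site-wise; a site appears if it
#'   appears in any replicate.
#' @export
combine_replicates <- function(tables) {
  stopifnot(length(tables) >= 1L)
  all <- data.table::rbindlist(lapply(tables, data.table::as.data.table))
  out <- all[, .(n_unconv = sum(n_unconv), n_conv = sum(n_conv)),
             by = c("chrom", "pos", "strand", "context")]
  data.table::setkeyv(out, c("chrom", "pos", "strand"))
  out[]
}
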