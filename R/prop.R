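#' Regional methylation proportion (prop values)
#'
#' The prop statistic for a region and context is the pooled, read-weighted
#' proportion of methylation-supporting (unconverted) reads over all reads at
#' cytosines of that context in the region: `prop = sum(n_unconv) /
#' sum(n_unconv + n_conv)`. It is a significance-free regional methylation
#' level; `prop_C` pools all three contexts, `prop_CG`/`prop_CHG`/`prop_CHH`
#' restrict to one. Because it is read-weighted it is additive: the prop of a
#' region equals the coverage-weighted combination of the props of any
#' disjoint partition of it.
#'
#' @param counts A count table ([read_count_table()]).
#' @param region Optional [GenomicRanges::GRanges]; `NULL` means the whole
#'   table (whole genome).
#' @param context `"CG"`, `"CHG"`, `"CHH"` or `"all"`.
#' @return List with `value`, `sum_unconv`, `sum_total`, `context` and a
#'   `defined` flag (`FALSE`, with `value = NA`, when no read covers the
#'   region in that context).
#' @export
compute_prop <- function(counts, region = NULL, context = "all") {
  counts <- data.table::as.data.table(counts)
  if (context != "all") counts <- counts[counts$context == context]
  if (!is.null(region)) counts <- counts[.sites_in(counts, region)]
  u <- sum(as.numeric(counts$n_unconv))
  tot <- u + sum(as.numeric(counts$n_conv))
  list(value = if (tot > 0) u / tot else NA_real_,
       sum_unconv = u, sum_total = tot,
       context = context, defined = tot > 0)
}

#' Per-feature prop values for a set of features
#'
#' Computes `prop` per feature x context in one pass (sites assigned to
#' features by position overlap; a site overlapping several features counts
#' in each).
#'
#' @param counts Count table.
#' @param features Named [GenomicRanges::GRanges].
#' @param contexts Contexts to tabulate (default CG/CHG/CHH plus pooled
#'   `"all"`).
#' @return data.table with `feature`, `context`, `sum_unconv`, `sum_total`,
#'   `prop` (NA where uncovered). Features with no covered site in a context
#'   still appear.
#' @export
prop_by_feature <- function(counts, features,
                            contexts = c("CG", "CHG", "CHH", "all")) {
  counts <- data.table::as.data.table(counts)
  stopifnot(!is.null(names(features)))
  pts <- GenomicRanges::GRanges(counts$chrom,
                                IRanges::IRanges(counts$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(pts, features, ignore.strand = TRUE)
  dt <- data.table::data.table(
    feature = names(features)[S4Vectors::subjectHits(hits)],
    context = counts$context[S4Vectors::queryHits(hits)],
    n_unconv = counts$n_unconv[S4Vectors::queryHits(hits)],
    n_conv = counts$n_conv[S4Vectors::queryHits(hits)]
  )
  per_ctx <- dt[, .(sum_unconv = sum(as.numeric(n_unconv)),
                    sum_total = sum(as.numeric(n_unconv + n_conv))),
                by = c("feature", "context")]
  if ("all" %in% contexts) {
    pooled <- per_ctx[, .(context = "all", sum_unconv = sum(sum_unconv),
                          sum_total = sum(sum_total)), by = "feature"]
    per_ctx <- data.table::rbindlist(list(per_ctx, pooled), use.names = TRUE)
  }
  per_ctx <- per_ctx[context %in% contexts]
  grid <- data.table::CJ(feature = names(features), context = contexts,
                         unique = TRUE)
  out <- merge(grid, per_ctx, by = c("feature", "context"), all.x = TRUE)
  out[is.na(sum_total), `:=`(sum_unconv = 0, sum_total = 0)]
  out[, prop := ifelse(sum_total > 0, sum_unconv / sum_total, NA_real_)]
  data.table::setkeyv(out, c("feature", "context"))
  out[]
}

#' Methylation rate table (counts and percentages)
#'
#' Builds the feature x context table of available cytosines, CMS and DMS
#' counts, and the corresponding rates `100 * count / available`, in the
#' layout: rows Genic / TE / Promoter / Whole Genome, contexts CG / CHG /
#' CHH / Total.
#'
#' `methylation_rate_table()` is pure arithmetic on count matrices (so the
#' same code serves published count tables); [tabulate_rate_table()] derives
#' the matrices from site-level data and an annotation.
#'
#' @param available Matrix or data.frame of available-site counts,
#'   rows = feature classes, columns = contexts (a `Total` column is added
#'   if absent).
#' @param cms,dms Matching matrices of CMS / DMS counts (optional).
#' @return Long-format data.table: `feature`, `context`, `available`,
#'   `n_cms`, `cms_rate_pct`, `n_dms`, `dms_rate_pct`.
#' @export
methylation_rate_table <- function(available, cms = NULL, dms = NULL) {
  fix <- function(m) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(as.data.frame(m))
    if (!"Total" %in% colnames(m)) m <- cbind(m, Total = rowSums(m))
    m
  }
  available <- fix(available); cms <- fix(cms); dms <- fix(dms)
  out <- data.table::data.table(
    feature = rep(rownames(available), ncol(available)),
    context = rep(colnames(available), each = nrow(available)),
    available = as.vector(available)
  )
  rate <- function(m) if (is.null(m)) rep(NA_real_, nrow(out)) else as.vector(m)
  out[, n_cms := rate(cms)]
  out[, n_dms := rate(dms)]
  out[, cms_rate_pct := 100 * n_cms / available]
  out[, dms_rate_pct := 100 * n_dms / available]
  out[]
}

#' @rdname methylation_rate_table
#' @param sites All assayed cytosines (context map from [assign_contexts()]).
#' @param cms_sites,dms_sites CMS and DMS site tables.
#' @param annotation A [load_annotation()] object.
#' @export
tabulate_rate_table <- function(sites, cms_sites, dms_sites, annotation) {
  classes <- list(Genic = annotation$genes, TE = annotation$tes,
                  Promoter = annotation$promoters)
  ctxs <- c("CG", "CHG", "CHH")
  count_mat <- function(tab) {
    m <- matrix(0, nrow = 4L, ncol = 3L,
                dimnames = list(c("Genic", "TE", "Promoter", "Whole Genome"), ctxs))
    if (is.null(tab) || nrow(tab) == 0L) return(m)
    for (f in names(classes)) {
      inside <- tab[.sites_in(tab, classes[[f]])]
      tb <- table(factor(inside$context, levels = ctxs))
      m[f, ] <- as.integer(tb)
    }
    m["Whole Genome", ] <- as.integer(table(factor(tab$context, levels = ctxs)))
    m
  }
  methylation_rate_table(count_mat(sites), count_mat(cms_sites),
                         count_mat(dms_sites))
}
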