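#' Label every assayed site as DMS (with direction), CMS or other
#'
#' Precomputation for run building: projects the CMS and DMS calls onto the
#' full list of assayed cytosines. The CMS and DMS sets must be disjoint.
#'
#' @param sites All assayed sites (context map, or any site table).
#' @param cms,dms CMS and DMS site tables ([call_cms()], [call_dms()]).
#' @return data.table `chrom`, `pos`, `strand`, `context`, `label`
#'   (`"dms"`/`"cms"`/`"other"`), `direction` (NA unless DMS), sorted by
#'   chromosome and position.
#' @export
classify_sites <- function(sites, cms, dms) {
  out <- data.table::as.data.table(sites)[, c("chrom", "pos", "strand", "context"),
                                          with = FALSE]
  key <- function(x) paste(x$chrom, x$pos, x$strand)
  cmsk <- if (nrow(cms)) key(cms) else character(0)
  dmsk <- if (nrow(dms)) key(dms) else character(0)
  if (length(intersect(cmsk, dmsk))) {
    stop("CMS and DMS sets overlap; apply the exclusion rule first")
  }
  k <- key(out)
  out[, label := "other"]
  out[k %in% cmsk, label := "cms"]
  mi <- match(k, dmsk)
  out[!is.na(mi), `:=`(label = "dms", direction = dms$direction[mi[!is.na(mi)]])]
  if (!"direction" %in% names(out)) out[, direction := NA_character_]
  data.table::setorderv(out, c("chrom", "pos"))
  out[]
}

#' Build maximal same-direction DMS runs
#'
#' Walks each chromosome's classified sites in positional order and collects
#' maximal stretches of DMSs that share one direction. A stretch is broken by
#' an opposite-direction DMS, by a CMS lying between two members, by a gap of
#' more than `max_gap` bases between consecutive members, or by a chromosome
#' end. Sites labelled `other` are transparent: they never terminate a run.
#' DMSs of all contexts participate.
#'
#' @param classified Output of [classify_sites()] (must be position-sorted).
#' @param max_gap Maximum distance in bp between consecutive member DMSs
#'   (default 500).
#' @return List: `runs` (one row per run: `chrom`, `start`, `end`, `n_dms`,
#'   `direction`, `run_id`) and `members` (the member DMS rows with their
#'   `run_id`).
#' @export
build_runs <- function(classified, max_gap = 500L) {
  cl <- data.table::as.data.table(classified)
  if (nrow(cl) > 1L &&
      any(cl[, if (.N > 1L) any(diff(pos) < 0) else FALSE, by = "chrom"]$V1)) {
    stop("classified sites must be sorted by position within chromosome")
  }
  dms <- cl[label == "dms"]
  if (nrow(dms) == 0L) {
    return(list(runs = .empty_runs(), members = dms))
  }
  cmspos <- split(cl[label == "cms"]$pos, cl[label == "cms"]$chrom)
  pieces <- lapply(split(dms, by = "chrom", sorted = TRUE), function(d) {
    cp <- sort(cmspos[[d$chrom[1]]])
    n <- nrow(d)
    if (n == 1L) {
      d[, run_id := 1L]
      return(d)
    }
    gap_break <- diff(d$pos) > max_gap
    dir_break <- d$direction[-1L] != d$direction[-n]
    if (length(cp)) {
      below <- findInterval(d$pos, cp)          # CMSs at position <= pos
      below_open <- findInterval(d$pos - 1L, cp) # CMSs at position < pos
      cms_break <- below_open[-1L] - below[-n] > 0L
    } else {
      cms_break <- rep(FALSE, n - 1L)
    }
    d[, run_id := cumsum(c(1L, as.integer(gap_break | dir_break | cms_break)))]
    d
  })
  members <- data.table::rbindlist(pieces)
  members[, run_id := cumsum(c(1L, as.integer(diff(run_id) != 0L |
                                                chrom[-1L] != chrom[-.N])))]
  runs <- members[, .(chrom = chrom[1L], start = min(pos), end = max(pos),
                      n_dms = .N, direction = direction[1L]), by = "run_id"]
  list(runs = runs[], members = members[])
}

.empty_runs <- function() {
  data.table::data.table(run_id = integer(), chrom = character(),
                         start = integer(), end = integer(),
                         n_dms = integer(), direction = character())
}

#' Calibrate the minimum DMR run length by genome-wide permutation
#'
#' Shuffles the site labels (DMS with its direction, CMS, other) uniformly
#' among the assayed positions *within each sequence context*, keeping the
#' physical site lattice fixed (the gap structure that the `max_gap` rule
#' depends on is preserved and label counts per context are conserved).
#' Runs are rebuilt in each permuted genome; the pooled run-length histogram
#' is the null. The calibrated threshold `L*` is the smallest run length
#' whose tail fraction among all permuted runs is at most `tail_quantile`.
#'
#' Because the unit of the tail can be argued two ways, both normalisations
#' are returned: the fraction of permuted *runs* of length >= L, and the
#' fraction of permuted DMS *sites* lying in such runs.
#'
#' @param classified Output of [classify_sites()].
#' @param n_perm Number of permutations (default 20).
#' @param tail_quantile Tail mass defining significance (default 0.01).
#' @param max_gap Run gap rule, as in [build_runs()].
#' @param seed Integer seed; fixed seed gives identical histograms.
#' @return Object of class `RunLengthNull`: `histogram` (run length ->
#'   count), `tail_by_run`, `tail_by_site`, `threshold`, `tail_at_threshold`,
#'   `n_perm`, `tail_quantile`.
#' @export
calibrate_run_threshold <- function(classified, n_perm = 20L,
                                    tail_quantile = 0.01, max_gap = 500L,
                                    seed = 1L) {
  stopifnot(n_perm >= 1L)
  cl <- data.table::as.data.table(classified)
  if (!any(cl$label == "dms")) {
    stop("no DMS labels: run-length threshold is undefined")
  }
  set.seed(seed)
  lens <- vector("list", n_perm)
  for (b in seq_len(n_perm)) {
    perm <- data.table::copy(cl)
    for (ctx in unique(perm$context)) {
      idx <- which(perm$context == ctx)
      sh <- sample(idx)
      perm[idx, `:=`(label = cl$label[sh], direction = cl$direction[sh])]
    }
    lens[[b]] <- build_runs(perm, max_gap = max_gap)$runs$n_dms
  }
  all_len <- unlist(lens)
  hist <- table(factor(all_len, levels = seq_len(max(all_len))))
  counts <- as.numeric(hist)
  L <- seq_along(counts)
  tail_by_run <- rev(cumsum(rev(counts))) / sum(counts)
  tail_by_site <- rev(cumsum(rev(counts * L))) / sum(counts * L)
  ok <- which(tail_by_run <= tail_quantile)
  threshold <- if (length(ok)) min(ok) else max(L) + 1L
  out <- list(histogram = hist, tail_by_run = tail_by_run,
              tail_by_site = tail_by_site, threshold = threshold,
              tail_at_threshold = if (threshold <= max(L)) tail_by_run[threshold] else 0,
              n_perm = n_perm, tail_quantile = tail_quantile)
  class(out) <- "RunLengthNull"
  out
}

#' @export
print.RunLengthNull <- function(x, ...) {
  cat(sprintf("RunLengthNull: %d permutations; L* = %d (tail %.4f <= %.4f)\n",
              x$n_perm, x$threshold, x$tail_at_threshold, x$tail_quantile))
  invisible(x)
}

#' Call DMRs from runs
#'
#' Runs with at least `threshold` member DMSs become differentially
#' methylated regions. The DMR span goes from the first to the last member
#' DMS inclusive, so `length_bp = end - start + 1` and a run of five
#' adjacent cytosines gives the minimum possible 5 bp DMR.
#'
#' @param runs Output of [build_runs()].
#' @param threshold Minimum member count (>= 2; the calibrated `L*`, 5 under
#'   the default calibration).
#' @return data.table of DMRs with `length_bp` and the per-context member
#'   histogram columns `n_CG`, `n_CHG`, `n_CHH`.
#' @export
call_dmrs <- function(runs, threshold = 5L) {
  stopifnot(threshold >= 2L)
  dmrs <- runs$runs[n_dms >= threshold]
  if (nrow(dmrs) == 0L) {
    out <- .empty_runs()
    out[, `:=`(length_bp = integer(), n_CG = integer(), n_CHG = integer(),
               n_CHH = integer())]
    return(out[])
  }
  dmrs[, length_bp := end - start + 1L]
  ctx <- runs$members[run_id %in% dmrs$run_id,
                      .(n_CG = sum(context == "CG"),
                        n_CHG = sum(context == "CHG"),
                        n_CHH = sum(context == "CHH")), by = "run_id"]
  out <- merge(dmrs, ctx, by = "run_id")
  data.table::setorderv(out, c("chrom", "start"))
  out[]
}

#' Summarise a DMR set
#'
#' Counts, length statistics, the direction split with its exact binomial
#' p-value, the context composition of member DMSs, and the genomic location
#' fractions. Location is assigned by DMR midpoint with precedence
#' TE > gene > promoter > unannotated, so the fractions are exclusive and
#' sum to one.
#'
#' @param dmrs A [call_dmrs()] table.
#' @param annotation A [load_annotation()] object.
#' @return List of summary components.
#' @export
summarize_dmrs <- function(dmrs, annotation) {
  if (nrow(dmrs) == 0L) return(list(n = 0L))
  mid <- floor((dmrs$start + dmrs$end) / 2)
  pts <- GenomicRanges::GRanges(dmrs$chrom, IRanges::IRanges(mid, width = 1L))
  loc <- rep("unannotated", nrow(dmrs))
  loc[IRanges::overlapsAny(pts, annotation$promoters, ignore.strand = TRUE)] <- "promoter"
  loc[IRanges::overlapsAny(pts, annotation$genes, ignore.strand = TRUE)] <- "gene"
  loc[IRanges::overlapsAny(pts, annotation$tes, ignore.strand = TRUE)] <- "te"
  bias <- direction_bias_test(dmrs$direction)
  nctx <- c(CG = sum(dmrs$n_CG), CHG = sum(dmrs$n_CHG), CHH = sum(dmrs$n_CHH))
  list(
    n = nrow(dmrs),
    length_bp = c(mean = mean(dmrs$length_bp), min = min(dmrs$length_bp),
                  max = max(dmrs$length_bp)),
    n_dms_total = sum(dmrs$n_dms),
    direction = bias,
    context_fraction = nctx / sum(nctx),
    location_fraction = {
      lf <- prop.table(table(factor(loc,
        levels = c("te", "gene", "promoter", "unannotated"))))
      stats::setNames(as.numeric(lf), names(lf))
    }
  )
}

#' Independently validate emitted DMRs
#'
#' Re-checks every DMR against the raw classified site list with a separate
#' code path from the run builder: at least `threshold` member DMSs, all one
#' direction, consecutive members no more than `max_gap` apart, and no CMS
#' or opposite-direction DMS anywhere inside the span.
#'
#' @param dmrs A [call_dmrs()] table.
#' @param classified The [classify_sites()] table the DMRs came from.
#' @param threshold,max_gap The caller's settings.
#' @return Logical vector, one entry per DMR (`TRUE` = all constraints met).
#' @export
validate_dmrs <- function(dmrs, classified, threshold = 5L, max_gap = 500L) {
  cl <- data.table::as.data.table(classified)
  vapply(seq_len(nrow(dmrs)), function(i) {
    span <- cl[chrom == dmrs$chrom[i] & pos >= dmrs$start[i] & pos <= dmrs$end[i]]
    d <- span[label == "dms"]
    if (nrow(d) < threshold) return(FALSE)
    if (any(span$label == "cms")) return(FALSE)
    if (length(unique(d$direction)) != 1L) return(FALSE)
    if (d$direction[1L] != dmrs$direction[i]) return(FALSE)
    if (any(diff(sort(d$pos)) > max_gap)) return(FALSE)
    TRUE
  }, logical(1))
}
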