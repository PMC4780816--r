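#' Fragments per kilobase of transcript per million mapped reads
#'
#' `FPKM = count / ((length_bp / 1e3) * (mapped_reads / 1e6))`.
#'
#' @param counts Read counts (vector).
#' @param gene_length_bp Transcript length in bases (>= 1).
#' @param mapped_reads Library size (>= 1).
#' @return FPKM values.
#' @export
compute_fpkm <- function(counts, gene_length_bp, mapped_reads) {
  stopifnot(all(gene_length_bp >= 1), all(mapped_reads >= 1))
  counts / ((gene_length_bp / 1e3) * (mapped_reads / 1e6))
}

#' Per-gene expression table with tissue FPKM and log2 fold change
#'
#' Pools replicates within each tissue (summed counts over summed library
#' sizes), computes per-tissue FPKM, flags expressed genes by the FPKM
#' cutoff, and computes `log2fc = log2(FPKM_B / FPKM_A)` for genes passing
#' the filter (B is conventionally the flower tissue so positive values mean
#' higher floral expression). Genes failing the filter get `NA` rather than
#' a pseudo-count.
#'
#' @param counts data.table with `gene`, `length_bp` and one column per
#'   replicate ([read_expression_counts()]).
#' @param tissue_of Named vector mapping replicate column -> tissue (exactly
#'   two tissues; the *second* sorted tissue name is the log2fc numerator
#'   unless `numerator` says otherwise).
#' @param lib_sizes Named vector of mapped reads per replicate; defaults to
#'   column sums.
#' @param de_flags Optional data.table `gene`, `de_flag` (external caller or
#'   planted truth).
#' @param fpkm_min Expression cutoff (default 0.02).
#' @param filter_rule `"both"` (default: FPKM > cutoff in both tissues) or
#'   `"either"`.
#' @param numerator Tissue placed in the log2fc numerator.
#' @return data.table: `gene`, `length_bp`, `fpkm_<tissue>` columns,
#'   `expressed`, `log2fc`, `de_flag`.
#' @export
expression_table <- function(counts, tissue_of, lib_sizes = NULL,
                             de_flags = NULL, fpkm_min = 0.02,
                             filter_rule = c("both", "either"),
                             numerator = NULL) {
  filter_rule <- match.arg(filter_rule)
  counts <- data.table::as.data.table(counts)
  reps <- names(tissue_of)
  stopifnot(all(reps %in% names(counts)))
  tissues <- sort(unique(unname(tissue_of)))
  stopifnot(length(tissues) == 2L)
  if (is.null(numerator)) numerator <- tissues[2L]
  denom <- setdiff(tissues, numerator)
  if (is.null(lib_sizes)) {
    lib_sizes <- vapply(reps, function(r) sum(counts[[r]]), numeric(1))
  }
  out <- counts[, c("gene", "length_bp"), with = FALSE]
  fpkm <- list()
  for (tis in tissues) {
    rr <- reps[tissue_of[reps] == tis]
    tot <- Reduce(`+`, lapply(rr, function(r) counts[[r]]))
    fpkm[[tis]] <- compute_fpkm(tot, counts$length_bp, sum(lib_sizes[rr]))
    data.table::set(out, j = paste0("fpkm_", tis), value = fpkm[[tis]])
  }
  pass <- if (filter_rule == "both") {
    fpkm[[1L]] > fpkm_min & fpkm[[2L]] > fpkm_min
  } else {
    fpkm[[1L]] > fpkm_min | fpkm[[2L]] > fpkm_min
  }
  out[, expressed := pass]
  out[, log2fc := ifelse(pass & fpkm[[numerator]] > 0 & fpkm[[denom]] > 0,
                         log2(fpkm[[numerator]] / fpkm[[denom]]), NA_real_)]
  if (!is.null(de_flags)) {
    out[, de_flag := de_flags$de_flag[match(out$gene, de_flags$gene)]]
    out[is.na(de_flag), de_flag := FALSE]
  } else {
    out[, de_flag := NA]
  }
  data.table::setkeyv(out, "gene")
  out[]
}

#' Are DMRs closer to differentially expressed genes than expected?
#'
#' The statistic is the mean, over DMRs, of the bp gap from the DMR to its
#' nearest differentially expressed (DE) gene (0 if overlapping). The null
#' randomises the DE labels among genes and recomputes the mean; the
#' one-sided p is the (add-one corrected) fraction of randomisations whose
#' null mean is at most the observed one ("closer than expected").
#'
#' @param dmrs DMR table (`chrom`, `start`, `end`).
#' @param genes Named [GenomicRanges::GRanges] of genes.
#' @param de_flags Logical vector along `genes` (or gene names).
#' @param n_randomizations Default 1000.
#' @param seed Integer seed.
#' @return List: `observed_mean_bp`, `null_mean_bp`, `null_distribution`,
#'   `p`.
#' @export
dmr_gene_distance_test <- function(dmrs, genes, de_flags,
                                   n_randomizations = 1000L, seed = 1L) {
  if (nrow(dmrs) == 0L) stop("no DMRs")
  if (is.character(de_flags)) de_flags <- names(genes) %in% de_flags
  n_de <- sum(de_flags)
  if (n_de == 0L) stop("no differentially expressed genes")
  dg <- GenomicRanges::GRanges(dmrs$chrom,
                               IRanges::IRanges(dmrs$start, dmrs$end))
  mean_dist <- function(flags) {
    h <- GenomicRanges::distanceToNearest(dg, genes[flags],
                                          ignore.strand = TRUE)
    d <- rep(NA_real_, length(dg))
    d[S4Vectors::queryHits(h)] <- S4Vectors::mcols(h)$distance
    mean(d, na.rm = TRUE)
  }
  obs <- mean_dist(de_flags)
  set.seed(seed)
  null <- replicate(n_randomizations, {
    mean_dist(sample(de_flags))
  })
  p <- (1 + sum(null <= obs)) / (n_randomizations + 1)
  list(observed_mean_bp = obs, null_mean_bp = mean(null),
       null_distribution = null, p = p)
}

#' Differential expression grouped by hyper-methylated DMR location
#'
#' For a feature class (gene body, promoter, or the TE nearest to each
#' gene), genes are grouped by whether the feature linked to them overlaps
#' (>= 1 bp) a DMR hyper-methylated in tissue A, in tissue B, or no DMR at
#' all, and the log2 fold-change distribution of each group is summarised
#' with boxplot statistics. Under methylation-driven repression, the group
#' hyper-methylated in the numerator tissue should shift negative.
#'
#' @param dmrs DMR table with `direction`.
#' @param feature_of_gene Named [GenomicRanges::GRanges], one interval per
#'   gene (names = gene ids): the gene body, its promoter, or its nearest
#'   TE ([nearest_te_per_gene()]).
#' @param expr [expression_table()] output.
#' @return data.table per group (`hyper_in_a`, `hyper_in_b`, `none`): `n`,
#'   `median`, `q1`, `q3`, `min`, `max` of log2fc.
#' @export
hyper_dmr_expression_contrast <- function(dmrs, feature_of_gene, expr) {
  grp <- rep("none", length(feature_of_gene))
  names(grp) <- names(feature_of_gene)
  if (nrow(dmrs) > 0L) {
    dg <- GenomicRanges::GRanges(dmrs$chrom,
                                 IRanges::IRanges(dmrs$start, dmrs$end))
    for (dir in c("hyper_in_a", "hyper_in_b")) {
      hit <- IRanges::overlapsAny(feature_of_gene, dg[dmrs$direction == dir],
                                  ignore.strand = TRUE)
      grp[hit] <- dir   # later direction wins only on double overlap
    }
  }
  lfc <- expr$log2fc[match(names(feature_of_gene), expr$gene)]
  keep <- !is.na(lfc)
  dt <- data.table::data.table(group = grp[keep], log2fc = lfc[keep])
  out <- dt[, .(n = .N, median = stats::median(log2fc),
                q1 = unname(stats::quantile(log2fc, 0.25)),
                q3 = unname(stats::quantile(log2fc, 0.75)),
                min = min(log2fc), max = max(log2fc)), by = "group"]
  for (g in c("hyper_in_a", "hyper_in_b", "none")) {
    if (!g %in% out$group) {
      out <- rbind(out, data.table::data.table(group = g, n = 0L,
        median = NA_real_, q1 = NA_real_, q3 = NA_real_,
        min = NA_real_, max = NA_real_))
    }
  }
  out[order(group)]
}

#' Spearman correlation of differential methylation with differential
#' expression
#'
#' For each (region class x context) pair, correlates the per-gene
#' difference in prop values between tissues with the log2 fold change in
#' expression (Spearman, midranks for ties). The whole family of tests in
#' one call is corrected with sequential Bonferroni (Holm) at
#' `alpha = 0.01`.
#'
#' @param delta_props data.table: `gene`, `region`, `context`, `delta`
#'   (prop difference, numerator tissue minus denominator tissue).
#' @param expr [expression_table()] output.
#' @param gene_subset `"all_expressed"` (default) or `"de_only"`.
#' @param alpha Family-wise level for the Holm flags (default 0.01).
#' @return data.table: `region`, `context`, `n`, `rho`, `p`, `p_holm`,
#'   `significant`.
#' @export
delta_prop_vs_expression <- function(delta_props, expr,
                                     gene_subset = c("all_expressed", "de_only"),
                                     alpha = 0.01) {
  gene_subset <- match.arg(gene_subset)
  keep <- expr[expr$expressed & !is.na(expr$log2fc)]
  if (gene_subset == "de_only") keep <- keep[keep$de_flag %in% TRUE]
  dp <- data.table::as.data.table(delta_props)[gene %in% keep$gene]
  dp[, log2fc := keep$log2fc[match(gene, keep$gene)]]
  res <- dp[!is.na(delta) & !is.na(log2fc),
            .(n = .N, rho = .spearman_safe(delta, log2fc)$rho,
              p = .spearman_safe(delta, log2fc)$p),
            by = c("region", "context")]
  res[, p_holm := stats::p.adjust(p, method = "holm")]
  res[, significant := !is.na(p_holm) & p_holm < alpha]
  res[]
}

.spearman_safe <- function(x, y) {
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Mean methylation by distance from the TSS
#'
#' Pools prop values in bins of distance 5'-upstream from the transcription
#' start site, measured along the gene's own strand (so minus-strand genes
#' look rightward in genome coordinates), per context.
#'
#' @param counts Count table.
#' @param genes Named, stranded [GenomicRanges::GRanges] of genes.
#' @param promoter_bp Profile depth upstream (default 1000).
#' @param bin_bp Bin width; must divide `promoter_bp` (default 50).
#' @return data.table: `context`, `bin_start` (distance from TSS, bp),
#'   `bin_end`, `prop` (NA where no read falls in the bin).
#' @export
tss_methylation_profile <- function(counts, genes, promoter_bp = 1000L,
                                    bin_bp = 50L) {
  stopifnot(promoter_bp %% bin_bp == 0L)
  counts <- data.table::as.data.table(counts)
  prom <- IRanges::trim(suppressWarnings(
    GenomicRanges::promoters(genes, upstream = promoter_bp, downstream = 0L)))
  pts <- GenomicRanges::GRanges(counts$chrom,
                                IRanges::IRanges(counts$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(pts, prom, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  g <- genes[si]
  tss <- ifelse(as.character(BiocGenerics::strand(g)) == "-",
                BiocGenerics::end(g), BiocGenerics::start(g))
  pos <- counts$pos[qi]
  dist <- ifelse(as.character(BiocGenerics::strand(g)) == "-",
                 pos - tss, tss - pos)   # 1..promoter_bp upstream
  ok <- dist >= 1 & dist <= promoter_bp
  dt <- data.table::data.table(
    context = counts$context[qi][ok],
    bin = ceiling(dist[ok] / bin_bp),
    n_unconv = counts$n_unconv[qi][ok],
    total = counts$n_unconv[qi][ok] + counts$n_conv[qi][ok]
  )
  agg <- dt[, .(prop = if (sum(total) > 0) sum(n_unconv) / sum(total) else NA_real_),
            by = c("context", "bin")]
  grid <- data.table::CJ(context = c("CG", "CHG", "CHH"),
                         bin = seq_len(promoter_bp %/% bin_bp))
  out <- merge(grid, agg, by = c("context", "bin"), all.x = TRUE)
  out[, bin_start := (bin - 1L) * bin_bp + 1L]
  out[, bin_end := bin * bin_bp]
  out[, bin := NULL]
  out[]
}

#' Feature density in sliding windows along chromosomes
#'
#' Counts items (sites, DMSs, genes, TEs, DE genes, ...) overlapping each
#' window of `window_bp`, advanced by `step_bp`, clipped at chromosome ends.
#'
#' @param items [GenomicRanges::GRanges] or a table with `chrom` and `pos`
#'   (points) or `start`/`end` (intervals).
#' @param seqlengths Named chromosome lengths.
#' @param window_bp Window size (default 50000).
#' @param step_bp Step (default `window_bp / 5`).
#' @return data.table: `chrom`, `start`, `end`, `count`.
#' @export
sliding_window_density <- function(items, seqlengths, window_bp = 50000L,
                                   step_bp = window_bp %/% 5L) {
  if (!methods::is(items, "GRanges")) {
    items <- data.table::as.data.table(items)
    items <- if ("pos" %in% names(items)) {
      GenomicRanges::GRanges(items$chrom, IRanges::IRanges(items$pos, width = 1L))
    } else {
      GenomicRanges::GRanges(items$chrom, IRanges::IRanges(items$start, items$end))
    }
  }
  wins <- lapply(names(seqlengths), function(chr) {
    len <- seqlengths[[chr]]
    if (len < 1L) return(NULL)
    starts <- seq.int(1L, max(1L, len), by = step_bp)
    data.table::data.table(chrom = chr, start = starts,
                           end = pmin(starts + window_bp - 1L, len))
  })
  wins <- data.table::rbindlist(wins)
  wg <- GenomicRanges::GRanges(wins$chrom, IRanges::IRanges(wins$start, wins$end))
  wins[, count := GenomicRanges::countOverlaps(wg, items, ignore.strand = TRUE)]
  wins[]
}

#' Nearest TE for each gene
#'
#' Minimal boundary-to-boundary gap; ties broken toward the TE with the
#' smaller start coordinate.
#'
#' @param genes,tes [GenomicRanges::GRanges] (genes named).
#' @return Named GRanges of TEs, one per gene that has any TE on its
#'   chromosome, plus a `distance` metadata column.
#' @export
nearest_te_per_gene <- function(genes, tes) {
  h <- GenomicRanges::distanceToNearest(genes, tes, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(h)
  dmin <- S4Vectors::mcols(h)$distance
  # distanceToNearest picks one arbitrary TE on ties; re-enumerate every TE
  # at the minimal distance and break ties by start coordinate
  ext <- GenomicRanges::GRanges(
    as.character(GenomeInfoDb::seqnames(genes[qi])),
    IRanges::IRanges(pmax(1L, BiocGenerics::start(genes[qi]) - dmin - 1L),
                     BiocGenerics::end(genes[qi]) + dmin + 1L))
  tes0 <- GenomicRanges::GRanges(
    as.character(GenomeInfoDb::seqnames(tes)),
    IRanges::IRanges(BiocGenerics::start(tes), BiocGenerics::end(tes)))
  genes0 <- GenomicRanges::GRanges(
    as.character(GenomeInfoDb::seqnames(genes)),
    IRanges::IRanges(BiocGenerics::start(genes), BiocGenerics::end(genes)))
  cand <- GenomicRanges::findOverlaps(ext, tes0, ignore.strand = TRUE)
  gi <- qi[S4Vectors::queryHits(cand)]
  ti <- S4Vectors::subjectHits(cand)
  dt <- data.table::data.table(
    gene = gi, te = ti,
    distance = GenomicRanges::distance(genes0[gi], tes0[ti],
                                       ignore.strand = TRUE),
    te_start = BiocGenerics::start(tes)[ti]
  )
  data.table::setorderv(dt, c("gene", "distance", "te_start"))
  dt <- dt[!duplicated(gene)]
  out <- tes[dt$te]
  names(out) <- names(genes)[dt$gene]
  S4Vectors::mcols(out)$distance <- dt$distance
  out
}

#' Linear model separating TE methylation from TE distance
#'
#' Ordinary least squares `log2fc ~ delta_prop + distance` on complete
#' cases: does the methylation difference of the nearest TE explain
#' differential expression once the TE's distance to the gene is accounted
#' for?
#'
#' @param delta_prop Per-gene prop difference of the nearest TE.
#' @param te_distance_bp Per-gene distance to that TE.
#' @param log2fc Differential expression.
#' @return List: `fit` (the [stats::lm] object), `coefficients` (estimate,
#'   SE, t, p per term), `collinear` flag, `n`.
#' @export
te_distance_linear_model <- function(delta_prop, te_distance_bp, log2fc) {
  df <- data.frame(log2fc = log2fc, delta_prop = delta_prop,
                   distance = te_distance_bp)
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) <= 3L) stop("need more than 3 complete cases")
  fit <- stats::lm(log2fc ~ delta_prop + distance, data = df)
  collinear <- qr(stats::model.matrix(fit))$rank < 3L ||
    any(is.na(stats::coef(fit)))
  list(fit = fit, coefficients = suppressWarnings(summary(fit))$coefficients,
       collinear = collinear, n = nrow(df))
}
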