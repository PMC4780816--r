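#' Build the gene/promoter/TE annotation with overlap filtering
#'
#' Applies the feature filters used throughout the package: transposable
#' elements (TEs) that overlap any gene are removed, and genes that are fully
#' contained in a TE are removed. Promoters are the 1.0 kb regions 5' upstream
#' of each retained gene's TSS, strand-aware, truncated (not discarded) at
#' chromosome ends. Promoters may overlap neighbouring features; no filter
#' beyond the stated gene/TE exclusion is applied.
#'
#' @param genes,tes [GenomicRanges::GRanges] of gene and TE intervals
#'   (1-based, closed, as returned by [read_features()]), or data.frames with
#'   columns `chrom`, `start`, `end`, `strand`.
#' @param seqlengths Named integer vector of chromosome lengths.
#' @param promoter_bp Promoter length in bases upstream of the TSS
#'   (default 1000).
#' @return An object of class `FeatureAnnotation`: a list with GRanges
#'   elements `genes`, `promoters`, `tes`, the chromosome lengths, and
#'   `removed` counts for the two filters.
#' @export
load_annotation <- function(genes, tes, seqlengths, promoter_bp = 1000L) {
  genes <- .as_granges(genes, seqlengths)
  tes <- .as_granges(tes, seqlengths)
  # filters are evaluated against the *original* sets
  te_drop <- IRanges::overlapsAny(tes, genes, ignore.strand = TRUE)
  gene_drop <- IRanges::overlapsAny(genes, tes, type = "within",
                                    ignore.strand = TRUE)
  genes_kept <- genes[!gene_drop]
  tes_kept <- tes[!te_drop]
  # promoters() flags upstream windows that run past the chromosome start;
  # those are truncated (not discarded) right away
  promoters <- IRanges::trim(suppressWarnings(
    GenomicRanges::promoters(genes_kept, upstream = promoter_bp,
                             downstream = 0L)
  ))
  names(promoters) <- names(genes_kept)
  ann <- list(
    genes = genes_kept,
    promoters = promoters,
    tes = tes_kept,
    seqlengths = seqlengths,
    promoter_bp = as.integer(promoter_bp),
    removed = c(genes = sum(gene_drop), tes = sum(te_drop))
  )
  class(ann) <- "FeatureAnnotation"
  ann
}

#' @export
print.FeatureAnnotation <- function(x, ...) {
  cat(sprintf(
    "FeatureAnnotation: %d genes, %d promoters (<=%d bp), %d TEs (removed: %d genes in TEs, %d TEs overlapping genes)\n",
    length(x$genes), length(x$promoters), x$promoter_bp, length(x$tes),
    x$removed[["genes"]], x$removed[["tes"]]))
  invisible(x)
}

.as_granges <- function(x, seqlengths) {
  if (methods::is(x, "GRanges")) {
    gr <- x
  } else {
    x <- as.data.frame(x)
    need <- c("chrom", "start", "end", "strand")
    if (!all(need %in% names(x))) {
      stop("feature table needs columns chrom, start, end, strand")
    }
    if (any(x$end < x$start)) stop("feature interval with end < start")
    gr <- GenomicRanges::GRanges(
      seqnames = x$chrom,
      ranges = IRanges::IRanges(start = x$start, end = x$end),
      strand = x$strand
    )
    if (!is.null(x$name)) names(gr) <- x$name
  }
  if (any(BiocGenerics::end(gr) < BiocGenerics::start(gr))) {
    stop("feature interval with end < start")
  }
  if (!all(as.character(GenomeInfoDb::seqnames(gr)) %in% names(seqlengths))) {
    bad <- setdiff(as.character(GenomeInfoDb::seqnames(gr)), names(seqlengths))
    stop(sprintf("unknown chromosome(s): %s", paste(bad, collapse = ", ")))
  }
  GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
  suppressWarnings(GenomeInfoDb::seqlengths(gr) <- seqlengths)  # checked next
  if (any(BiocGenerics::end(gr) > GenomeInfoDb::seqlengths(gr)[as.character(GenomeInfoDb::seqnames(gr))])) {
    stop("feature interval beyond chromosome end")
  }
  if (is.null(names(gr))) names(gr) <- paste0("feat", seq_along(gr))
  gr
}

#' Read gene or TE features from GFF3 or BED
#'
#' Thin wrapper over [rtracklayer::import()]. For GFF3, rows are filtered to
#' the requested feature `type` (e.g. `"gene"`, `"transposable_element"`);
#' BED files are taken as-is. Coordinates come back 1-based closed in the
#' usual GRanges convention.
#'
#' @param path File path (`.gff3`/`.gff` or `.bed`, optionally gzipped).
#' @param type GFF3 feature type to keep; ignored for BED.
#' @return A [GenomicRanges::GRanges].
#' @export
read_features <- function(path, type = NULL) {
  gr <- rtracklayer::import(path)
  if (!is.null(type) && "type" %in% names(S4Vectors::mcols(gr))) {
    gr <- gr[as.character(gr$type) %in% type]
  }
  nm <- S4Vectors::mcols(gr)$ID
  if (is.null(nm)) nm <- S4Vectors::mcols(gr)$name
  if (!is.null(nm)) names(gr) <- nm
  gr
}

# site membership in a feature set: logical vector over site rows
.sites_in <- function(sites, gr) {
  if (length(gr) == 0L || nrow(sites) == 0L) return(rep(FALSE, nrow(sites)))
  pts <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$pos, width = 1L))
  IRanges::overlapsAny(pts, gr, ignore.strand = TRUE)
}
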