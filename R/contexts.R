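#' Assign cytosine sequence contexts on both strands
#'
#' Scans a genome and classifies every cytosine into one of the three plant
#' methylation contexts -- CG, CHG or CHH, where H is A, C or T -- determined
#' by the two bases immediately 3' of the cytosine *on its own strand*.
#' Forward-strand contexts are read directly from the sequence; reverse-strand
#' contexts are read from the complement of the two bases 5' of a G on the
#' forward strand. Cytosines whose context window runs off the chromosome end
#' or contains an N are excluded: their context is undefined and they never
#' enter the denominator of any rate.
#'
#' CG dyads are *not* merged across strands: the two cytosines of a symmetric
#' CG are distinct sites (see [merge_cg_strands()] for the optional collapse).
#'
#' @param genome A named character vector of chromosome sequences, or a
#'   [Biostrings::DNAStringSet]. Only A, C, G, T and N are accepted.
#' @return A [data.table::data.table] with columns `chrom`, `pos` (1-based
#'   position of the cytosine in forward-strand coordinates), `strand`
#'   (`"+"`/`"-"`) and `context` (`"CG"`, `"CHG"`, `"CHH"`), sorted by
#'   chromosome and position.
#' @examples
#' assign_contexts(c(chr = "ACGT"))
#' @export
assign_contexts <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- as.character(genome)
  }
  if (length(genome) == 0L) {
    return(.empty_site_table())
  }
  if (is.null(names(genome)) || anyNA(names(genome)) || any(names(genome) == "")) {
    stop("genome sequences must be named by chromosome")
  }
  out <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    out[[i]] <- .contexts_one(names(genome)[i], genome[[i]])
  }
  sites <- data.table::rbindlist(out)
  if (nrow(sites) == 0L) return(.empty_site_table())
  data.table::setkeyv(sites, c("chrom", "pos", "strand"))
  sites[]
}

.empty_site_table <- function() {
  data.table::data.table(chrom = character(), pos = integer(),
                         strand = character(), context = character())
}

.contexts_one <- function(chrom, seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n == 0L) return(NULL)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- !ch %in% c("A", "C", "G", "T", "N")
  if (any(bad)) {
    stop(sprintf("non-IUPAC character '%s' in sequence '%s'",
                 ch[which(bad)[1]], chrom))
  }
  # forward strand: context is the 2 bases to the right of a C
  fwd <- which(ch == "C")
  fwd <- fwd[fwd + 2L <= n]
  f1 <- ch[fwd + 1L]
  f2 <- ch[fwd + 2L]
  keep <- f1 != "N" & f2 != "N"
  fwd <- fwd[keep]; f1 <- f1[keep]; f2 <- f2[keep]
  fctx <- ifelse(f1 == "G", "CG", ifelse(f2 == "G", "CHG", "CHH"))
  # reverse strand: a C on "-" is a G on "+"; its 3' bases are the
  # complements of the two bases to the *left* on the forward strand
  rev <- which(ch == "G")
  rev <- rev[rev - 2L >= 1L]
  r1 <- ch[rev - 1L]   # complement of first 3' base
  r2 <- ch[rev - 2L]
  keep <- r1 != "N" & r2 != "N"
  rev <- rev[keep]; r1 <- r1[keep]; r2 <- r2[keep]
  # complement(r1) == "G" <=> r1 == "C"
  rctx <- ifelse(r1 == "C", "CG", ifelse(r2 == "C", "CHG", "CHH"))
  data.table::data.table(
    chrom = chrom,
    pos = c(fwd, rev),
    strand = rep(c("+", "-"), c(length(fwd), length(rev))),
    context = c(fctx, rctx)
  )
}

#' Collapse symmetric CG sites onto the forward-strand cytosine
#'
#' Optional helper for analyses that treat the two strands of a CG dyad as a
#' single site. Reverse-strand CG sites are re-keyed to the forward-strand
#' position one base to their left; counts (if present) are summed.
#'
#' @param sites A site (or site-count) table from [assign_contexts()] or
#'   [read_count_table()].
#' @return A table with one row per CG dyad (reverse-strand CG rows merged
#'   into their forward partner); non-CG rows are untouched.
#' @export
merge_cg_strands <- function(sites) {
  sites <- data.table::copy(data.table::as.data.table(sites))
  is_rev_cg <- sites$context == "CG" & sites$strand == "-"
  sites[is_rev_cg, `:=`(pos = pos - 1L, strand = "+")]
  has_counts <- all(c("n_unconv", "n_conv") %in% names(sites))
  if (has_counts) {
    sites <- sites[, .(n_unconv = sum(n_unconv), n_conv = sum(n_conv)),
                   by = c("chrom", "pos", "strand", "context")]
  } else {
    sites <- unique(sites, by = c("chrom", "pos", "strand", "context"))
  }
  data.table::setkeyv(sites, c("chrom", "pos", "strand"))
  sites[]
}
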