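#' Read a per-cytosine bisulfite count table
#'
#' The table is the tab-delimited cytosine-report dialect: one row per site
#' with columns `chrom`, `pos` (1-based), `strand` (+/-), `context`
#' (CG/CHG/CHH), `n_unconv` (reads supporting methylation) and `n_conv`
#' (converted reads). One file per sample; gzip is transparent.
#'
#' @param path Path to the file (optionally `.gz`).
#' @return A keyed [data.table::data.table] sorted by `chrom`, `pos`,
#'   `strand`, with integer counts and a `coverage`-free layout (coverage is
#'   always `n_unconv + n_conv`).
#' @seealso [write_count_table()] for the exact inverse; the pair round-trips
#'   bit-exactly.
#' @export
read_count_table <- function(path) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    dt <- data.table::fread(text = readLines(con), sep = "\t", header = TRUE,
                            colClasses = list(character = c("chrom", "strand", "context")))
  } else {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = list(character = c("chrom", "strand", "context")))
  }
  need <- c("chrom", "pos", "strand", "context", "n_unconv", "n_conv")
  if (!all(need %in% names(dt))) {
    stop(sprintf("count table %s lacks columns: %s", path,
                 paste(setdiff(need, names(dt)), collapse = ", ")))
  }
  dt <- dt[, need, with = FALSE]
  .validate_count_table(dt, path)
  dt[, pos := as.integer(pos)]
  dt[, n_unconv := as.integer(n_unconv)]
  dt[, n_conv := as.integer(n_conv)]
  data.table::setkeyv(dt, c("chrom", "pos", "strand"))
  dt[]
}

.validate_count_table <- function(dt, path = "<table>") {
  line <- function(i) i + 1L  # header line is 1
  bad <- which(!dt$context %in% c("CG", "CHG", "CHH"))
  if (length(bad)) {
    stop(sprintf("%s line %d: malformed context token '%s'",
                 path, line(bad[1]), dt$context[bad[1]]))
  }
  bad <- which(!dt$strand %in% c("+", "-"))
  if (length(bad)) {
    stop(sprintf("%s line %d: strand must be + or -", path, line(bad[1])))
  }
  bad <- which(dt$n_unconv < 0 | dt$n_conv < 0 | !is.finite(dt$n_unconv) |
                 !is.finite(dt$n_conv))
  if (length(bad)) {
    stop(sprintf("%s line %d: negative or non-numeric count", path, line(bad[1])))
  }
  bad <- which(duplicated(dt[, c("chrom", "pos", "strand")]))
  if (length(bad)) {
    stop(sprintf("%s line %d: duplicate site %s:%d(%s)", path, line(bad[1]),
                 dt$chrom[bad[1]], dt$pos[bad[1]], dt$strand[bad[1]]))
  }
  invisible(dt)
}

#' Write a per-cytosine count table
#'
#' @param table A count table as returned by [read_count_table()].
#' @param path Output path; a `.gz` suffix compresses.
#' @export
write_count_table <- function(table, path) {
  need <- c("chrom", "pos", "strand", "context", "n_unconv", "n_conv")
  stopifnot(all(need %in% names(table)))
  data.table::fwrite(data.table::as.data.table(table)[, need, with = FALSE],
                     path, sep = "\t")
  invisible(path)
}

#' Read / write a genome FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' @rdname read_genome
#' @param genome Named character vector (or DNAStringSet).
#' @export
write_genome <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(unlist(genome))
  }
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a gene expression count table
#'
#' Tab-delimited, one row per gene: `gene`, `length_bp`, then one integer
#' column per replicate (e.g. `L1 L2 L3 F1 F2 F3`).
#'
#' @param path File path.
#' @return data.table keyed by `gene`.
#' @export
read_expression_counts <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  stopifnot(all(c("gene", "length_bp") %in% names(dt)))
  data.table::setkeyv(dt, "gene")
  dt[]
}

#' Read differential-expression flags produced by an external caller
#'
#' @param path Tab-delimited file with columns `gene` and `q`.
#' @param de_q Significance cutoff on `q` (default 0.01).
#' @return data.table `gene`, `q`, logical `de_flag`.
#' @export
read_de_flags <- function(path, de_q = 0.01) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  stopifnot(all(c("gene", "q") %in% names(dt)))
  dt[, de_flag := q < de_q]
  data.table::setkeyv(dt, "gene")
  dt[]
}

#' Export site or region calls as BED
#'
#' Six-column BED (chrom, start, end, name, score, strand); scores are
#' `-log10(p)` for site tables with a `p` column, or the member-DMS count for
#' DMR tables.
#'
#' @param x A DMS/CMS site table or DMR table.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  x <- data.table::as.data.table(x)
  if ("pos" %in% names(x)) {
    bed <- data.table::data.table(
      chrom = x$chrom, start = x$pos - 1L, end = x$pos,
      name = if ("context" %in% names(x)) x$context else ".",
      score = if ("p" %in% names(x)) round(-log10(pmax(x$p, 1e-300)), 4) else 0,
      strand = if ("strand" %in% names(x)) x$strand else "."
    )
  } else {
    bed <- data.table::data.table(
      chrom = x$chrom, start = x$start - 1L, end = x$end,
      name = if ("direction" %in% names(x)) x$direction else ".",
      score = if ("n_dms" %in% names(x)) x$n_dms else 0,
      strand = "."
    )
  }
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
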