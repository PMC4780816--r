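# shared fixture builders (everything generated in code; no stored data)

library(data.table)

# a count table from parallel vectors, defaulting to one chromosome
make_counts <- function(pos, n_unconv, n_conv, context = "CG",
                        chrom = "chr1", strand = "+") {
  dt <- data.table::data.table(chrom = chrom, pos = as.integer(pos),
                               strand = strand, context = context,
                               n_unconv = as.integer(n_unconv),
                               n_conv = as.integer(n_conv))
  data.table::setkeyv(dt, c("chrom", "pos", "strand"))
  dt
}

# classified-site table for run building: label/direction vectors over
# evenly spaced positions
make_classified <- function(labels, directions = NA_character_,
                            pos = NULL, chrom = "chr1", context = "CHH") {
  n <- length(labels)
  if (is.null(pos)) pos <- seq_len(n) * 10L
  data.table::data.table(chrom = chrom, pos = as.integer(pos), strand = "+",
                         context = context, label = labels,
                         direction = rep(directions, length.out = n))
}

# a small but fully featured simulation config (fast: ~1 s end to end)
small_sim_config <- function(seed = 1L, ...) {
  sim_config(n_chrom = 1L, chrom_length = 30000L, n_genes = 4L, n_tes = 6L,
             control_sites = 500L, seed = seed, ...)
}

tissue_map6 <- function() {
  stats::setNames(rep(c("L", "F"), each = 3L),
                  c("L1", "L2", "L3", "F1", "F2", "F3"))
}
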