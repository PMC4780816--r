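#' Simulation configuration
#'
#' Defaults emulate the statistical regime of a two-tissue (leaf vs floral
#' bud) plant methylome experiment: three biological replicates per tissue at
#' ~15X coverage each (~45X per tissue combined), ~1% bisulfite conversion
#' error, feature-dependent methylation by context (TEs heavily methylated
#' at CG/CHG, genes CG-dominant, CHH low everywhere), a minority of planted
#' differentially methylated sites biased 57% toward hyper-methylation in
#' the flower, clustered same-direction blocks (>= 6 sites, CHH-enriched)
#' that form recoverable DMRs, and gene expression coupled negatively to the
#' promoter-CG methylation difference.
#'
#' The genome scale is deliberately small (desk scale); every statistical
#' parameter of the study design is kept at its realistic value.
#'
#' @param ... Overrides of the default keys (unknown keys are an error).
#' @return A `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_chrom = 2L, chrom_length = 200000L, gc = 0.46,
    n_genes = 40L, n_tes = 60L,
    gene_length = c(1000L, 3000L), te_length = c(300L, 1500L),
    promoter_bp = 1000L,
    # P(site methylated) by feature x context
    meth_prob = rbind(
      te          = c(CG = 0.95, CHG = 0.64, CHH = 0.04),
      gene        = c(CG = 0.26, CHG = 0.03, CHH = 0.005),
      promoter    = c(CG = 0.26, CHG = 0.14, CHH = 0.04),
      unannotated = c(CG = 0.50, CHG = 0.28, CHH = 0.02)
    ),
    level_methylated = 0.9,      # true methylated fraction at a methylated site
    dms_fraction = 0.005,        # planted isolated DMSs among assayed sites
    direction_bias = 0.57,       # P(hyper in flower) for a planted DMS
    dmr_blocks = 8L, dmr_block_size = 6L, dmr_chh_frac = 0.67,
    promoter_dm_fraction = 0.5,  # genes with a coherent promoter-CG difference
    promoter_dm_max_delta = 0.3, # max |delta prop_CG| planted in a promoter
    coverage = 15, replicates = 3L, conversion_error = 0.01,
    control_sites = 2000L,
    tissues = c("L", "F"),
    # expression
    expr_log2_baseline_mean = 3, expr_log2_baseline_sd = 2,
    expr_dispersion = 10,        # NB size
    de_fraction = 0.30, de_log2fc_sd = 2,
    beta_promoter_cg = -4,       # log2-expression shift per unit delta prop_CG
    lib_size = 2e6,
    max_gap = 500L,
    seed = 1L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) {
    stop(sprintf("unknown config key(s): %s (valid: %s)",
                 paste(bad, collapse = ", "),
                 paste(names(cfg), collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  stopifnot(cfg$coverage >= 1, cfg$replicates >= 1,
            cfg$gc > 0, cfg$gc < 1,
            cfg$conversion_error > 0, cfg$conversion_error < 1,
            cfg$dms_fraction >= 0, cfg$dms_fraction <= 1,
            cfg$direction_bias >= 0, cfg$direction_bias <= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a genome and its gene/TE annotation
#'
#' Sequence is i.i.d. at the configured GC content; genes and TEs are placed
#' by a hard-core process (uniform candidate starts, greedy rejection of any
#' overlap with an already placed feature), so the gene/TE exclusion filter
#' removes nothing by construction. Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return List: `genome` (named character), `genes`, `tes` (GRanges),
#'   `seqlengths`, `annotation` ([load_annotation()] result).
#' @export
simulate_genome_and_annotation <- function(config) {
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chrom))
  seqlengths <- stats::setNames(rep(config$chrom_length, config$n_chrom), chroms)
  p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
         G = config$gc / 2, T = (1 - config$gc) / 2)
  genome <- stats::setNames(vapply(chroms, function(ch) {
    paste(sample(names(p), config$chrom_length, replace = TRUE, prob = p),
          collapse = "")
  }, character(1)), chroms)
  mean_flen <- mean(c(config$gene_length, config$te_length))
  if ((config$n_genes + config$n_tes) * mean_flen >
        0.7 * sum(seqlengths)) {
    stop("feature densities imply impossible packing")
  }
  # hard-core placement on plain vectors (GRanges built once at the end)
  occ <- stats::setNames(lapply(chroms, function(x)
    list(start = integer(0), end = integer(0))), chroms)
  place <- function(n, len_range) {
    out <- data.table::data.table(chrom = character(n), start = integer(n),
                                  end = integer(n), strand = character(n))
    k <- 0L; tries <- 0L
    while (k < n && tries < 200L * n) {
      tries <- tries + 1L
      chr <- sample(chroms, 1L)
      len <- sample(seq(len_range[1L], len_range[2L]), 1L)
      start <- sample.int(seqlengths[[chr]] - len, 1L)
      end <- start + len - 1L
      o <- occ[[chr]]
      if (!any(o$start <= end & o$end >= start)) {
        occ[[chr]]$start <<- c(o$start, start)
        occ[[chr]]$end <<- c(o$end, end)
        k <- k + 1L
        data.table::set(out, k, names(out),
                        list(chr, start, end, sample(c("+", "-"), 1L)))
      }
    }
    if (k < n) stop("feature densities imply impossible packing")
    gr <- GenomicRanges::GRanges(out$chrom,
                                 IRanges::IRanges(out$start, out$end),
                                 strand = out$strand)
    GenomeInfoDb::seqlevels(gr) <- chroms
    GenomeInfoDb::seqlengths(gr) <- seqlengths
    gr
  }
  genes <- place(config$n_genes, config$gene_length)
  names(genes) <- sprintf("gene%03d", seq_along(genes))
  tes <- place(config$n_tes, config$te_length)
  names(tes) <- sprintf("te%03d", seq_along(tes))
  ann <- load_annotation(genes, tes, seqlengths,
                         promoter_bp = config$promoter_bp)
  list(genome = genome, genes = genes, tes = tes, seqlengths = seqlengths,
       annotation = ann)
}

#' Simulate true per-site methylation levels for two tissues
#'
#' Baseline methylation is drawn per site from the feature x context
#' probabilities (site feature assigned by position with precedence
#' TE > gene > promoter > unannotated); methylated sites carry the
#' configured true level, unmethylated sites level 0, identically in both
#' tissues. A configured fraction of sites is then perturbed into planted
#' DMSs (the level flipped in one tissue, direction biased toward the
#' flower), and contiguous blocks of same-direction differences are planted
#' as recoverable DMRs, preferring CHH-rich stretches.
#'
#' @param sites Context map from [assign_contexts()].
#' @param annotation [load_annotation()] object.
#' @param config [sim_config()].
#' @return List: `levels` (data.table site key + `level_L`, `level_F`),
#'   `truth_dms` (planted isolated DMSs with direction), `truth_dmrs`
#'   (planted blocks: chrom, start, end, n, direction), and
#'   `truth_promoter_dm` (per-gene planted promoter prop_CG difference,
#'   flower minus leaf).
#' @export
simulate_methylomes <- function(sites, annotation, config) {
  set.seed(config$seed + 1L)
  lv <- data.table::as.data.table(sites)[, c("chrom", "pos", "strand", "context"),
                                         with = FALSE]
  n <- nrow(lv)
  if (ceiling(config$dms_fraction * n) + config$dmr_blocks * config$dmr_block_size > n) {
    stop("perturbation fraction exceeds available sites")
  }
  feat <- rep("unannotated", n)
  feat[.sites_in(lv, annotation$promoters)] <- "promoter"
  feat[.sites_in(lv, annotation$genes)] <- "gene"
  feat[.sites_in(lv, annotation$tes)] <- "te"
  pm <- config$meth_prob[cbind(feat, lv$context)]
  m <- stats::rbinom(n, 1L, pm) * config$level_methylated
  lv[, level_L := m]
  lv[, level_F := m]
  hi <- config$level_methylated
  # planted isolated DMSs
  n_dms <- round(config$dms_fraction * n)
  dms_idx <- sort(sample.int(n, n_dms))
  hyper_f <- stats::rbinom(n_dms, 1L, config$direction_bias) == 1L
  lv$level_L[dms_idx] <- ifelse(hyper_f, 0, hi)
  lv$level_F[dms_idx] <- ifelse(hyper_f, hi, 0)
  truth_dms <- lv[dms_idx, c("chrom", "pos", "strand", "context"), with = FALSE]
  truth_dms[, direction := ifelse(hyper_f, "hyper_in_b", "hyper_in_a")]
  data.table::setorderv(lv, c("chrom", "pos"))
  used <- rep(FALSE, n); used[dms_idx] <- TRUE
  # coherent per-promoter CG differences (the substrate of the expression
  # coupling): a fraction of genes gets a tissue shift of its promoter
  # prop_CG, realised by flipping a matching share of promoter CG sites
  prom_dm <- data.table::data.table(gene = character(), delta_planted = numeric())
  if (config$promoter_dm_fraction > 0 && length(annotation$promoters)) {
    cg_pts <- GenomicRanges::GRanges(lv$chrom, IRanges::IRanges(lv$pos, width = 1L))
    sel_g <- which(stats::runif(length(annotation$promoters)) <
                     config$promoter_dm_fraction)
    for (gi in sel_g) {
      idx <- which(IRanges::overlapsAny(cg_pts, annotation$promoters[gi],
                                        ignore.strand = TRUE) &
                     lv$context == "CG" & !used)
      if (length(idx) == 0L) next
      delta <- stats::runif(1L, -config$promoter_dm_max_delta,
                            config$promoter_dm_max_delta)
      k <- round(abs(delta) / hi * length(idx))
      if (k == 0L) next
      pick <- sample(idx, k)
      if (delta > 0) {
        lv$level_F[pick] <- hi; lv$level_L[pick] <- 0
      } else {
        lv$level_F[pick] <- 0; lv$level_L[pick] <- hi
      }
      used[pick] <- TRUE
      prom_dm <- rbind(prom_dm, data.table::data.table(
        gene = names(annotation$promoters)[gi],
        delta_planted = sign(delta) * k * hi / length(idx)))
    }
  }
  # planted DMR blocks: runs of consecutive assayed sites, same direction
  bs <- config$dmr_block_size
  ok_start <- function(i) {
    j <- i + bs - 1L
    j <= n && lv$chrom[i] == lv$chrom[j] && !any(used[i:j]) &&
      all(diff(lv$pos[i:j]) <= config$max_gap)
  }
  blocks <- list()
  cand <- sample.int(n - bs, min(n - bs, 4000L))
  chh_frac <- vapply(cand, function(i) {
    mean(lv$context[i:(i + bs - 1L)] == "CHH")
  }, numeric(1))
  cand <- cand[order(-(chh_frac >= config$dmr_chh_frac))]
  for (i in cand) {
    if (length(blocks) >= config$dmr_blocks) break
    if (!ok_start(i)) next
    j <- i:(i + bs - 1L)
    used[j] <- TRUE
    dirF <- stats::rbinom(1L, 1L, config$direction_bias) == 1L
    lv$level_L[j] <- if (dirF) 0 else hi
    lv$level_F[j] <- if (dirF) hi else 0
    blocks[[length(blocks) + 1L]] <- data.table::data.table(
      chrom = lv$chrom[i], start = lv$pos[i], end = lv$pos[i + bs - 1L],
      n = bs, direction = if (dirF) "hyper_in_b" else "hyper_in_a")
  }
  truth_dmrs <- if (length(blocks)) data.table::rbindlist(blocks) else
    data.table::data.table(chrom = character(), start = integer(),
                           end = integer(), n = integer(),
                           direction = character())
  list(levels = lv[], truth_dms = truth_dms[], truth_dmrs = truth_dmrs,
       truth_promoter_dm = prom_dm[])
}

#' Simulate bisulfite count tables from true methylation levels
#'
#' Coverage is Poisson(`coverage`) per site per replicate; the unconverted
#' read count is Binomial(coverage, `m + (1 - m) * error`): each read of an
#' unmethylated molecule fails to convert independently with the conversion
#' error rate, matching the binomial caller's error model exactly. A fully
#' unmethylated control contig (`chrC`) is also emitted per sample for
#' conversion-error estimation.
#'
#' @param levels The `levels` table from [simulate_methylomes()].
#' @param config [sim_config()].
#' @return List: `counts` -- nested list `[[tissue]][[replicate]]` of count
#'   tables; `controls` -- matching control-contig tables.
#' @export
simulate_bsseq_counts <- function(levels, config) {
  stopifnot(all(levels$level_L >= 0 & levels$level_L <= 1),
            all(levels$level_F >= 0 & levels$level_F <= 1))
  set.seed(config$seed + 2L)
  e <- config$conversion_error
  n <- nrow(levels)
  tissues <- config$tissues
  counts <- controls <- stats::setNames(vector("list", 2L), tissues)
  for (tis in tissues) {
    m <- if (tis == tissues[1L]) levels$level_L else levels$level_F
    p_unconv <- m + (1 - m) * e
    counts[[tis]] <- controls[[tis]] <- vector("list", config$replicates)
    for (r in seq_len(config$replicates)) {
      cov <- stats::rpois(n, config$coverage)
      u <- stats::rbinom(n, cov, p_unconv)
      tab <- data.table::data.table(
        chrom = levels$chrom, pos = levels$pos, strand = levels$strand,
        context = levels$context, n_unconv = u, n_conv = cov - u)
      data.table::setkeyv(tab, c("chrom", "pos", "strand"))
      counts[[tis]][[r]] <- tab
      ccov <- stats::rpois(config$control_sites, config$coverage)
      cu <- stats::rbinom(config$control_sites, ccov, e)
      controls[[tis]][[r]] <- data.table::data.table(
        chrom = "chrC", pos = seq_len(config$control_sites) * 3L,
        strand = "+", context = "CHH", n_unconv = cu, n_conv = ccov - cu)
      names(counts[[tis]]) <- names(controls[[tis]]) <-
        paste0(tis, seq_len(config$replicates))
    }
  }
  list(counts = counts, controls = controls)
}

#' Simulate replicate gene-expression counts coupled to promoter methylation
#'
#' Per-gene log2 expression baseline is Gaussian; a configured subset of
#' genes gets a true tissue effect (differential expression), and every gene
#' additionally receives `beta * (promoter prop_CG difference)` on its
#' flower expression, so a negative `beta` represses flower expression of
#' genes whose promoters are more CG-methylated in flower. Counts are
#' negative binomial with FPKM-recoverable library sizes.
#'
#' @param annotation [load_annotation()] object.
#' @param levels True methylation levels ([simulate_methylomes()]).
#' @param sites Context map (for promoter CG sites).
#' @param config [sim_config()].
#' @return List: `counts` (data.table gene x replicate with `length_bp`),
#'   `lib_sizes`, `tissue_of`, `truth` (per-gene true log2fc, DE flag,
#'   promoter delta prop_CG).
#' @export
simulate_expression <- function(annotation, levels, sites, config) {
  set.seed(config$seed + 3L)
  genes <- annotation$genes
  ng <- length(genes)
  # true promoter prop_CG per tissue = mean true level over promoter CG sites
  cg <- levels[levels$context == "CG"]
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(cg$chrom, IRanges::IRanges(cg$pos, width = 1L)),
    annotation$promoters, ignore.strand = TRUE)
  by_gene <- split(S4Vectors::queryHits(hits),
                   names(annotation$promoters)[S4Vectors::subjectHits(hits)])
  dprop <- stats::setNames(rep(0, ng), names(genes))
  for (g in names(by_gene)) {
    i <- by_gene[[g]]
    dprop[g] <- mean(cg$level_F[i]) - mean(cg$level_L[i])
  }
  beta_shift <- config$beta_promoter_cg * dprop
  base <- stats::rnorm(ng, config$expr_log2_baseline_mean,
                       config$expr_log2_baseline_sd)
  de <- stats::rbinom(ng, 1L, config$de_fraction) == 1L
  t_eff <- ifelse(de, stats::rnorm(ng, 0, config$de_log2fc_sd), 0)
  log2_L <- base
  log2_F <- base + t_eff + beta_shift
  if (any(!is.finite(2^log2_F))) stop("beta too large: expression mean overflow")
  len <- BiocGenerics::width(genes)
  tissues <- config$tissues
  reps <- as.vector(outer(seq_len(config$replicates), tissues,
                          function(r, t) paste0(t, r)))
  tissue_of <- stats::setNames(rep(tissues, each = config$replicates), reps)
  lib_sizes <- stats::setNames(rep(config$lib_size, length(reps)), reps)
  out <- data.table::data.table(gene = names(genes), length_bp = len)
  for (rp in reps) {
    fpkm_true <- 2^(if (tissue_of[[rp]] == tissues[1L]) log2_L else log2_F)
    mu <- fpkm_true * (len / 1e3) * (lib_sizes[[rp]] / 1e6)
    out[[rp]] <- stats::rnbinom(ng, mu = mu, size = config$expr_dispersion)
  }
  truth <- data.table::data.table(
    gene = names(genes), true_log2fc = t_eff + beta_shift, de_flag = de,
    delta_prop_cg_promoter = unname(dprop))
  list(counts = out[], lib_sizes = lib_sizes, tissue_of = tissue_of,
       truth = truth)
}

#' Run the full generator
#'
#' Convenience wrapper chaining genome, methylome, BSseq-count and
#' expression simulation under one config; byte-identical under a fixed
#' seed.
#'
#' @param config A [sim_config()].
#' @return List with all generator outputs plus the context map (`sites`).
#' @export
simulate_experiment <- function(config = sim_config()) {
  gen <- simulate_genome_and_annotation(config)
  sites <- assign_contexts(gen$genome)
  meth <- simulate_methylomes(sites, gen$annotation, config)
  bs <- simulate_bsseq_counts(meth$levels, config)
  expr <- simulate_expression(gen$annotation, meth$levels, sites, config)
  c(gen, list(sites = sites), meth, bs, expr = list(expr),
    list(config = config))
}
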