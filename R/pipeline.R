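#' Default pipeline configuration
#'
#' One flat key namespace holding every analysis threshold (none are
#' hard-coded elsewhere): the binomial methylation call level, the FET DMS
#' level and minimum coverage, the DMR run threshold and gap, promoter
#' length, expression cutoffs and window sizes, plus the simulation block
#' (see [sim_config()]).
#'
#' @param ... Key overrides.
#' @return Named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    alpha_meth = 0.01, alpha_dms = 0.05, min_cov = 3L,
    dmr_threshold = 5L, max_gap = 500L, tail_quantile = 0.01,
    n_perm_runs = 20L, n_perm_pairs = 10000L, n_randomizations = 1000L,
    promoter_bp = 1000L, fpkm_min = 0.02, de_q = 0.01,
    window_bp = 50000L, bin_bp = 50L,
    seed = 1L,
    sim = list()
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) {
    stop(sprintf("unknown config key(s): %s (valid: %s)",
                 paste(bad, collapse = ", "), paste(names(cfg), collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with top-level pipeline keys and an optional `sim`
#'   block.
#' @return Config list as from [default_config()].
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline on simulated data
#'
#' Orchestrates the stages end to end: simulate (genome, methylomes, BSseq
#' counts, expression), call (conversion error, combined-tissue CMS/DMS,
#' the replicate truth set), dmr (classification, permutation calibration,
#' DMR calls and summary), replicate-qc (15 pairwise comparisons,
#' between/within permutation test, neighbor-joining tree) and integrate
#' (expression table, delta-prop correlations, DMR-gene distance test, TSS
#' profile, window densities, TE linear model). Artifacts are written as
#' TSV/Newick/JSON under `outdir` together with a run manifest (config,
#' seed, checksums, package version); rerunning with the same config and
#' seed reproduces them byte-identically.
#'
#' @param config [default_config()] list.
#' @param outdir Output directory (created); `NULL` skips writing.
#' @param stages Character subset of
#'   `c("simulate","call","dmr","replicate-qc","integrate")`.
#' @return Invisible list with all stage results.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL,
                         stages = c("simulate", "call", "dmr",
                                    "replicate-qc", "integrate")) {
  t0 <- Sys.time()
  log_line <- function(stage, msg) {
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
  }
  scfg <- do.call(sim_config, c(config$sim,
                                if (is.null(config$sim$seed)) list(seed = config$seed)))
  res <- list(config = config)

  ## simulate
  sim <- simulate_experiment(scfg)
  res$sim <- sim
  log_line("simulate", sprintf("%d sites, %d genes, %d TEs, %d planted DMSs, %d blocks",
                               nrow(sim$sites), length(sim$genes), length(sim$tes),
                               nrow(sim$truth_dms), nrow(sim$truth_dmrs)))
  if (!"call" %in% stages && !"dmr" %in% stages &&
        !"replicate-qc" %in% stages && !"integrate" %in% stages) {
    return(.finish_pipeline(res, outdir, t0))
  }

  ## call
  tissues <- scfg$tissues
  err <- lapply(tissues, function(tis) {
    estimate_conversion_error(combine_replicates(sim$controls[[tis]]))$error_rate
  })
  names(err) <- tissues
  truth <- build_truth_set(sim$counts, error_rates = unlist(err),
                           min_cov = config$min_cov,
                           alpha_dms = config$alpha_dms,
                           alpha_meth = config$alpha_meth)
  rate_tab <- tabulate_rate_table(sim$sites, truth$cms, truth$dms,
                                  sim$annotation)
  res$call <- list(error_rates = err, truth = truth, rate_table = rate_tab,
                   direction_bias = if (nrow(truth$dms))
                     direction_bias_test(truth$dms) else NULL)
  log_line("call", sprintf("error %s; %d CMS, %d DMS",
                           paste(sprintf("%s=%.4f", tissues, unlist(err)),
                                 collapse = " "),
                           nrow(truth$cms), nrow(truth$dms)))

  ## dmr
  if (any(c("dmr", "replicate-qc", "integrate") %in% stages)) {
    cls <- classify_sites(sim$sites, truth$cms, truth$dms)
    runs <- build_runs(cls, max_gap = config$max_gap)
    null <- if (nrow(truth$dms)) {
      calibrate_run_threshold(cls, n_perm = config$n_perm_runs,
                              tail_quantile = config$tail_quantile,
                              max_gap = config$max_gap,
                              seed = config$seed)
    } else NULL
    thr <- config$dmr_threshold
    dmrs <- call_dmrs(runs, threshold = thr)
    res$dmr <- list(classified = cls, runs = runs, null = null,
                    threshold_used = thr, dmrs = dmrs,
                    summary = summarize_dmrs(dmrs, sim$annotation),
                    valid = validate_dmrs(dmrs, cls, threshold = thr,
                                          max_gap = config$max_gap))
    log_line("dmr", sprintf("%d runs, %d DMRs at threshold %d (calibrated L* = %s)",
                            nrow(runs$runs), nrow(dmrs), thr,
                            if (is.null(null)) "NA" else null$threshold))
  }

  ## replicate-qc
  if ("replicate-qc" %in% stages) {
    samples <- c(sim$counts[[tissues[1L]]], sim$counts[[tissues[2L]]])
    tissue_of <- stats::setNames(rep(tissues, each = scfg$replicates),
                                 names(samples))
    pairs <- pairwise_comparisons(samples, tissue_of, truth$dms,
                                  min_cov = config$min_cov,
                                  alpha_dms = config$alpha_dms)
    perm <- between_within_permutation_test(pairs$n_dms, pairs$group,
                                            n_perm = config$n_perm_pairs,
                                            seed = config$seed)
    dmat <- distance_matrix_from_overlaps(pairs)
    njt <- neighbor_joining(dmat)
    res$replicate_qc <- list(pairs = pairs, permutation = perm,
                             distance_matrix = dmat, tree = njt)
    log_line("replicate-qc",
             sprintf("between-within mean diff %.1f DMSs (p = %.4g); tissues %s separated",
                     perm$statistic, perm$p,
                     if (tree_separates(njt$tree,
                                        names(tissue_of)[tissue_of == tissues[1L]]))
                       "are" else "are NOT"))
  }

  ## integrate
  if ("integrate" %in% stages) {
    expr <- expression_table(sim$expr$counts, sim$expr$tissue_of,
                             lib_sizes = sim$expr$lib_sizes,
                             de_flags = sim$expr$truth[, .(gene, de_flag)],
                             fpkm_min = config$fpkm_min,
                             numerator = tissues[2L])
    ann <- sim$annotation
    comb <- truth$combined
    regions <- list(gene = ann$genes, promoter = ann$promoters,
                    nearest_te = nearest_te_per_gene(ann$genes, ann$tes))
    dps <- list()
    for (rg in names(regions)) {
      pa <- prop_by_feature(comb[[1L]], regions[[rg]])
      pb <- prop_by_feature(comb[[2L]], regions[[rg]])
      dp <- merge(pa, pb, by = c("feature", "context"),
                  suffixes = c("_a", "_b"))
      dps[[rg]] <- data.table::data.table(
        gene = dp$feature, region = rg, context = dp$context,
        delta = dp$prop_b - dp$prop_a)
    }
    delta_props <- data.table::rbindlist(dps)
    cors <- list(
      all_expressed = delta_prop_vs_expression(delta_props, expr,
                                               "all_expressed"),
      de_only = delta_prop_vs_expression(delta_props, expr, "de_only"))
    dmrs <- res$dmr$dmrs
    dist_test <- if (nrow(dmrs) && any(expr$de_flag %in% TRUE)) {
      dmr_gene_distance_test(dmrs, ann$genes,
                             expr$de_flag[match(names(ann$genes), expr$gene)],
                             n_randomizations = config$n_randomizations,
                             seed = config$seed)
    } else NULL
    contrast <- hyper_dmr_expression_contrast(dmrs, ann$genes, expr)
    profile <- tss_methylation_profile(comb[[1L]], ann$genes,
                                       promoter_bp = config$promoter_bp,
                                       bin_bp = config$bin_bp)
    dens <- list(
      dms = sliding_window_density(truth$dms, sim$seqlengths,
                                   config$window_bp),
      cms = sliding_window_density(truth$cms, sim$seqlengths,
                                   config$window_bp))
    te_dp <- dps$nearest_te[context == "CG"]
    te_lm <- {
      d <- S4Vectors::mcols(regions$nearest_te)$distance
      lfc <- expr$log2fc[match(te_dp$gene, expr$gene)]
      dd <- d[match(te_dp$gene, names(regions$nearest_te))]
      if (sum(stats::complete.cases(data.frame(te_dp$delta, dd, lfc))) > 3L)
        te_distance_linear_model(te_dp$delta, dd, lfc) else NULL
    }
    res$integrate <- list(expr = expr, delta_props = delta_props,
                          correlations = cors, dmr_gene_distance = dist_test,
                          hyper_dmr_contrast = contrast,
                          tss_profile = profile, densities = dens,
                          te_lm = te_lm)
    pcg <- cors$all_expressed[region == "promoter" & context == "CG"]
    log_line("integrate",
             sprintf("%d expressed genes; promoter-CG rho = %.3f (p = %.3g)",
                     sum(expr$expressed), pcg$rho, pcg$p))
  }
  .finish_pipeline(res, outdir, t0)
}

.finish_pipeline <- function(res, outdir, t0) {
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_report(res, outdir)
  }
  res$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  invisible(res)
}

#' Write pipeline artifacts and the run manifest
#'
#' Every numeric table of the run is regenerated from the in-memory results
#' and written as TSV (plus the NJ tree as Newick); a `manifest.json`
#' records the config, seed, per-file MD5 checksums and the package
#' version.
#'
#' @param res A [run_pipeline()] result.
#' @param outdir Output directory.
#' @return Invisible vector of written paths.
#' @export
write_report <- function(res, outdir) {
  paths <- character(0)
  put <- function(x, name) {
    p <- file.path(outdir, name)
    data.table::fwrite(data.table::as.data.table(x), p, sep = "\t")
    paths <<- c(paths, p)
  }
  if (!is.null(res$call)) {
    put(res$call$rate_table, "rate_table.tsv")
    put(res$call$truth$dms, "truth_dms.tsv")
    write_bed(res$call$truth$dms, file.path(outdir, "truth_dms.bed"))
    paths <- c(paths, file.path(outdir, "truth_dms.bed"))
  }
  if (!is.null(res$dmr)) {
    put(res$dmr$dmrs, "dmrs.tsv")
    if (!is.null(res$dmr$null)) {
      put(data.table::data.table(
        run_length = seq_along(res$dmr$null$tail_by_run),
        count = as.integer(res$dmr$null$histogram),
        tail_by_run = res$dmr$null$tail_by_run,
        tail_by_site = res$dmr$null$tail_by_site), "run_length_null.tsv")
    }
  }
  if (!is.null(res$replicate_qc)) {
    put(res$replicate_qc$pairs, "pairwise_comparisons.tsv")
    p <- file.path(outdir, "nj_tree.nwk")
    writeLines(res$replicate_qc$tree$newick, p)
    paths <- c(paths, p)
  }
  if (!is.null(res$integrate)) {
    put(res$integrate$expr, "expression_table.tsv")
    put(res$integrate$correlations$all_expressed, "correlations_all.tsv")
    put(res$integrate$correlations$de_only, "correlations_de.tsv")
    put(res$integrate$tss_profile, "tss_profile.tsv")
  }
  manifest <- list(
    package = "methdiff",
    version = as.character(utils::packageVersion("methdiff")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = res$config$seed,
    config = res$config[setdiff(names(res$config), "sim")],
    sim = res$sim$config[!vapply(res$sim$config, is.matrix, logical(1))],
    files = as.list(tools::md5sum(paths))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}

#' Command-line entry point
#'
#' Thin argument parser used by the `inst/exec/methdiff` Rscript wrapper:
#' `methdiff <simulate|call|dmr|replicate-qc|integrate|all> [--config f.yaml]
#' [--out dir] [--key value ...]`.
#'
#' @param args Character vector (default `commandArgs(trailingOnly=TRUE)`).
#' @return Exit status (0 on success), invisibly.
#' @export
cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  sub_all <- c("simulate", "call", "dmr", "replicate-qc", "integrate", "all")
  if (length(args) == 0L || !args[1L] %in% sub_all) {
    message("usage: methdiff <", paste(sub_all, collapse = "|"),
            "> [--config file.yaml] [--out dir] [--key value ...]")
    return(invisible(1L))
  }
  sub <- args[1L]; args <- args[-1L]
  cfg <- default_config(); outdir <- "methdiff_run"
  i <- 1L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (i + 1L > length(args)) stop("missing value for --", key)
    val <- args[i + 1L]
    if (key == "config") {
      cfg <- read_config(val)
    } else if (key == "out") {
      outdir <- val
    } else {
      if (!key %in% names(cfg)) {
        stop(sprintf("invalid config key '%s'; valid keys: %s", key,
                     paste(names(cfg), collapse = ", ")))
      }
      mode <- class(cfg[[key]])[1L]
      cfg[[key]] <- if (mode %in% c("integer", "numeric"))
        as.numeric(val) else val
    }
    i <- i + 2L
  }
  stages <- if (sub == "all")
    c("simulate", "call", "dmr", "replicate-qc", "integrate") else sub
  if (sub != "simulate" && !"simulate" %in% stages) {
    stages <- c("simulate", stages)  # upstream stages are recomputed in-memory
  }
  run_pipeline(cfg, outdir = outdir, stages = stages)
  invisible(0L)
}
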