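.datatable.aware <- TRUE

# data.table non-standard evaluation symbols
utils::globalVariables(c(
  ".", ".N", "chrom", "pos", "strand", "context", "n_unconv", "n_conv",
  "label", "direction", "run_id", "n_dms", "start", "end", "length_bp",
  "n_CG", "n_CHG", "n_CHH", "p", "p_binomial_a", "p_binomial_b",
  "sum_unconv", "sum_total", "prop", "n_cms", "cms_rate_pct", "dms_rate_pct",
  "feature", "gene", "log2fc", "expressed", "de_flag", "delta",
  "p_holm", "significant", "bin", "bin_start", "bin_end", "total",
  "count", "q", "level_L", "level_F", "n_dmr", "dmr_overlap_pct",
  "dmr_fpr_pct", "region", "available"
))
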