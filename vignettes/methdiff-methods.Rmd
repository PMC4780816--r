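---
title: "Methods: tissue-differential methylation with replication"
author: "methdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue-differential methylation with replication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdiff)
```

# Scope

`methdiff` analyses whole-genome bisulfite sequencing (BSseq) of two plant
tissues with biological replication. It answers three questions in order:
(1) which cytosines are methylated, conserved between tissues (CMS) or
differentially methylated (DMS/DMR); (2) how reproducible those calls are
across biological replicates; and (3) whether differential methylation
covaries with differential gene expression. The package starts from
per-cytosine count tables; read trimming, mapping and differential-expression
calling are out of scope (DE flags are consumed as input or planted by the
simulator).

# The statistical model

## Methylation calls

Bisulfite conversion reads an unmethylated cytosine as T ("converted") and a
methylated one as C ("unconverted"), but conversion fails at a small rate
$e$, estimated by pooling reads on a known-unmethylated control (chloroplast
DNA in the motivating system; an unmethylated control contig in the
simulator). At a site with $n$ reads of which $k$ are unconverted, the
methylation call tests

$$P(X \ge k \mid n, e), \quad X \sim \mathrm{Binomial}(n, e),$$

an upper tail because methylation can only inflate unconverted counts. A
site is *methylated* at level $\alpha_{meth}$ (default 0.01; 0.05 available
by configuration, since both conventions are in circulation) and a *CMS*
when methylated in both tissues, each tissue using counts summed over its
replicates and its own error rate.

## Differential sites

A *DMS* between two samples requires coverage of at least `min_cov` (default
3) reads in each sample and a Fisher exact test on the 2×2 table of
(unconverted, converted) × (sample A, sample B) with $p < \alpha_{dms}$
(default 0.05). The test is two-sided by default; note that at the minimal
3+3 coverage the two-sided p cannot fall below $0.1$, so the effective
minimum informative coverage is higher — a one-sided option exists. The
direction records which sample has the larger unconverted fraction; ties
carry no direction and are dropped. Because "methylated in both tissues"
and "significantly different" are not mutually exclusive by construction,
sites called CMS are removed from the DMS set explicitly, keeping the two
sets disjoint.

The FET p-value is computed in-package as the standard hypergeometric sum
(all tables with the observed margins whose point probability does not
exceed the observed one, with the usual $1+10^{-7}$ tolerance). Identical
tables are memoised; at genome scale with ~15–45X coverage the number of
distinct tables is tiny compared to the number of sites, which makes calling
fast. `stats::fisher.test` is used only as an independent oracle in the test
suite.

## Regional methylation: prop values

For a region and context, $prop = \sum_i k_i / \sum_i n_i$ over cytosines of
that context in the region — a read-weighted pooled proportion, not a mean
of per-site fractions, hence exactly additive over disjoint partitions. It
carries no significance and is the basis of all methylation–expression
correlations.

## DMRs as non-random runs

A candidate run is a maximal stretch of same-direction DMSs in which
consecutive members are at most `max_gap` = 500 bp apart and no CMS or
opposite-direction DMS intervenes; sites that are neither CMS nor DMS are
transparent. DMSs of all three contexts participate. The minimum run length
`L*` that qualifies as a DMR is calibrated by permutation: DMS (with its
direction) and CMS labels are shuffled uniformly among the assayed positions
*within each context*, keeping the physical site lattice fixed — this
preserves both the per-context label counts and the inter-site gap structure
that the 500 bp rule depends on. `L*` is the smallest length whose tail
fraction among permuted runs is at most `tail_quantile`. Because the unit of
that tail can be read per-run or per-site, both normalisations are reported;
the conventional threshold of 5, obtained at roughly the 1% tail in the
motivating data, is the default and is directly settable. Runs never span
chromosomes. An independent validator re-checks every emitted DMR against
the raw classified site list.

## Replication and the relative FPR

The combined-replicate comparison (L1+L2+L3 vs F1+F2+F3, counts summed
site-wise) defines the best available "truth" set of DMSs/DMRs. Every
unordered pair of the six samples is then compared with identical caller
settings. For a pairwise set $S$ and truth $T$:

* overlap percentage, reference denominator: $100\,|S \cap T| / |T|$;
* overlap percentage, query denominator: $100\,|S \cap T| / |S|$;
* relative FPR: $100\,(1 - |S \cap T| / |S|)$.

Both denominators are computed and labelled because they answer different
questions and differ materially when $|S| \ne |T|$. The FPR is *relative*:
the truth set itself contains false positives, so these rates are
conservative statements about single-replicate reliability, not absolute
error rates. DMR overlap uses ≥ 1 bp interval intersection.

Whether tissues differ beyond replicate noise is tested by permutation on
the 15 pairwise values (9 between-tissue, 6 within-tissue): statistic
$\bar{x}_{between} - \bar{x}_{within}$, null by re-partitioning the 15
values into random groups of 9 and 6. The values, not the sample labels,
are the permutation unit: relabelling only the six samples admits just 10
distinct partitions, which cannot resolve $p < 0.01$, while value
re-partitioning gives $\binom{15}{6} = 5005$ (exhaustive enumeration is
available and is cross-checked against Monte-Carlo sampling). Pairwise
overlap percentages also serve directly as distances for neighbor-joining
(Saitou–Nei, via `ape::nj`) clustering of the six methylomes.

## Methylation and expression

Expression uses FPKM with replicates pooled within tissue (summed counts
over summed library sizes); genes pass the expression filter at FPKM > 0.02
in both tissues (default; "either" by configuration) and
$\log_2\!\mathrm{FC} = \log_2(\mathrm{FPKM}_{flower}/\mathrm{FPKM}_{leaf})$.
Genes failing the filter are excluded, not pseudo-counted. The integration
analyses are:

* **DMR–gene distance**: mean bp gap from each DMR to its nearest
  differentially expressed gene, against a null that permutes DE labels
  among genes (default 1000 randomisations; one-sided, "closer than
  expected", add-one corrected).
* **Hyper-DMR contrasts**: genes grouped by whether the gene body, promoter
  or nearest TE overlaps (≥ 1 bp) a DMR hyper-methylated in one tissue, the
  other, or none; boxplot statistics of log2FC per group.
* **Δprop–expression correlations**: per gene and region class
  (gene/promoter/nearest TE) and context, Spearman correlation (midranks)
  between $prop_{flower} - prop_{leaf}$ and log2FC; the family of 12 tests
  per gene universe is corrected by sequential Bonferroni (Holm) at
  $p < 0.01$. Both the all-expressed and DE-only gene universes are
  supported (the two appear in published tables; which universe regional
  within-tissue correlations used is ambiguous, so it is a configuration
  choice).
* **TSS profiles**: pooled prop per distance-from-TSS bin (default 50 bp
  over 1 kb), measured 5′-upstream along the gene's own strand.
* **TE linear model**: OLS $\log_2 FC \sim \Delta prop + d_{TE}$ separating
  the nearest TE's methylation difference from its distance; ties in
  nearest-TE assignment break toward the smaller start coordinate.
* **Window densities**: counts of CMSs/DMSs/genes/TEs/DE genes in 50 kb
  windows (step defaults to window/5; the step is not specified in the
  source conventions).

# Coordinates and conventions

Internally everything lives in the 1-based, closed-interval convention of
`GenomicRanges`; GFF3 imports natively, BED converts on read. Cytosine
context (CG/CHG/CHH, H ∈ {A,C,T}) is determined solely by the two bases 3′
of the cytosine on its own strand; sites whose context window leaves the
chromosome or touches an N are excluded from all denominators. The two
cytosines of a symmetric CG dyad are distinct sites by default — published
totals cannot disambiguate whether strands were merged, so merging is an
explicit opt-in (`merge_cg_strands()`). Promoters are 1 kb upstream of the
TSS, truncated at chromosome ends rather than discarded, and may overlap
neighbouring features; the only annotation filter is the stated one (TEs
overlapping genes removed; genes contained in TEs removed). DMR genomic
location is assigned by midpoint with precedence TE > gene > promoter >
unannotated so the reported fractions are exclusive and sum to one.

# The synthetic study design

The generator reproduces the statistical regime of the motivating
experiment so that every stage is testable without external data:

* two tissues × three replicates, Poisson coverage 15X per replicate (≈ 45X
  per combined tissue), conversion error 1% applied per read as
  $k \sim \mathrm{Binomial}(n,\; m + (1-m)e)$ — exactly the caller's error
  model, so power is closed-form;
* i.i.d. genome at GC 0.46 with genes and TEs placed by a hard-core process
  (the gene/TE filter removes nothing by construction);
* per-site methylation states drawn from feature × context probabilities
  echoing the published conserved-methylation rates (TE CG 0.95, TE CHG
  0.64, gene CG 0.26, CHH low everywhere); methylated sites carry true
  level 0.9;
* a planted 0.5% of sites differ between tissues, 57% hyper-methylated in
  flower; planted same-direction blocks of 6 consecutive assayed sites
  (CHH-preferring, within 500 bp spans) provide recoverable DMRs with one
  miss tolerated at threshold 5;
* a coherent promoter-CG difference (|Δprop| ≤ 0.3) is planted for half the
  genes, and flower expression receives $\beta \cdot \Delta prop_{CG}$ with
  $\beta = -4$ on the log2 scale, on top of Gaussian baselines, a 30% DE
  subset and negative-binomial counting noise with FPKM-recoverable library
  sizes.

What the simulator does *not* emulate — and hence what passing tests do not
certify about real data: biological variance between replicates (replicate
differences are purely binomial/Poisson, so simulated within-tissue DMS
counts reflect only test noise, and single-replicate FPRs are far smaller
than the >50% seen in real tissue comparisons where cell-type mixtures vary
between replicates), genome sequence structure (no repeats or TE families,
no methylation autocorrelation beyond the planted blocks), context-dependent
DMS rates (planted isolated DMSs are uniform across contexts), and isoform-
or read-level effects. The direction of every qualitative finding is still
reproduced: between-tissue pairs show more DMSs than within-tissue pairs,
clustering splits the tissues, single-replicate calls have a strictly higher
relative FPR than the combined set's internal error, and the promoter-CG
coupling is recovered with its planted negative sign.

# Numerical choices

* FET two-sided definition with the $(1+10^{-7})$ relative tolerance,
  matching the reference implementation exactly (verified by enumeration on
  all tables with total ≤ 40).
* Binomial tails via `pbinom(k - 1, n, e, lower.tail = FALSE)`; no
  continuity or normal approximation anywhere — the direction-bias test
  uses the exact binomial even at $n = 5 \times 10^5$.
* Permutation p-values use the add-one correction $(1 + \#\{null \ge
  obs\})/(B + 1)$ for Monte-Carlo and the plain fraction for exhaustive
  enumeration.
* Degenerate inputs are explicit: zero-coverage prop is flagged undefined
  rather than 0; an empty DMS set makes run calibration an error, not a
  silent zero; empty groups in the DMR–expression contrast report n = 0.
* The NJ tie behaviour is delegated to `ape::nj` (deterministic for a fixed
  input ordering); trees are emitted as Newick.

# Problem sizes

The shipped tests and the acceptance script run the full design at reduced
genome scale — 30 kb genomes for repeated calibration/validation loops and
a 250 kb chromosome (~10⁵ assayed cytosines, 40 genes, 60 TEs) for
end-to-end recovery over 20 seeds — chosen so a complete run takes minutes
on one core while every rate (coverage, error, bias, effect sizes) stays at
its realistic value. The default `sim_config()` is 2 × 200 kb.

# Known limitations

The caller is the plain binomial/FET pair: no beta-binomial dispersion, no
smoothing, no sliding-window or HMM DMR definitions (deliberately — the DMR
here is the original "non-random run" definition). FPRs are relative to a
combined-replicate reference that itself contains errors. The permutation
null for runs conditions on the observed site lattice and label counts; it
does not model regional methylation autocorrelation, so its thresholds are
anti-conservative if true methylation is spatially clustered under the
null.
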