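# pairsig

Reverse gene-pair signatures for prognostic risk stratification in glioma
and other cancers with binary genomic-status markers.

## The problem and the method

IDH mutation and 1p/19q co-deletion are the standard prognostic genomic
markers of diffuse glioma, but assaying them directly is slow. Their effect
is visible in the transcriptome: for certain gene pairs (G_i, G_j), the
within-sample expression ordering is predominantly G_i > G_j in one genomic
state and G_i < G_j in the other. Because only within-sample orderings are
used, such *reverse gene pairs* are invariant to any strictly monotone
per-sample transform of the raw quantifications — so raw data from mixed
microarray and RNA-seq cohorts can be used directly, with no normalization.

`pairsig` implements the full pipeline:

1. **Detection** — expression is rank-transformed within each sample; the
   top 10% of genes by mean rank deviation between the status groups (up-
   and down-regulated separately) are crossed into candidate pairs; each
   pair's ordering table

   |            | G_i > G_j | G_i < G_j |
   |------------|-----------|-----------|
   | status 0   | a         | b         |
   | status 1   | c         | d         |

   is scored with a two-sided Fisher's exact test computed in log space
   (p-values of strong pairs reach ~1e-95, far below naive double-precision
   underflow), Bonferroni-screened over all choose(G, 2) pairs, and the top
   50 pairs kept.
2. **Single-status signature (GPS)** — stability selection over the binary
   pair-ordering profile (50 stratified-bootstrap L1-penalized logistic
   fits, cross-validated penalty; pairs kept when selected in ≥ 80% of
   fits), an unpenalized logistic refit for the final weights, a risk score
   = linear predictor, and a survival-optimal (log-rank-maximizing) or mean
   score cutoff.
3. **Ensemble** — the pair pools of the two single-status signatures are
   combined on a common risk polarity and refined by greedy forward
   selection on the training concordance index of the majority-vote label;
   a sample is high risk when more than half of the panel pairs show their
   risk ordering.
4. **Evaluation** — Kaplan–Meier curves, log-rank test, Harrell's C-index,
   ROC AUC at fixed horizons and the univariate Cox hazard ratio.

A synthetic-cohort generator with planted reversal pairs, correlated binary
statuses, status-dependent exponential survival and per-sample monotone
platform distortions makes the whole pipeline testable without any external
download.

## Worked example

```r
library(pairsig)

cfg <- sim_config(n_samples = 200, n_genes = 500, seed = 42)
sim <- generate_cohort(cfg)
head(detect_reverse_pairs(sim$cohort, "status1"), 3)
#> # A tibble: 3 × 9
#>   gene_i gene_j     a     b     c     d  ties  p_value orientation
#>   <chr>  <chr>  <int> <int> <int> <int> <int>    <dbl> <chr>
#> 1 G00228 G00165     2    75   114     9     0 5.50e-42 i<j
#> 2 G00128 G00370     2    75   113    10     0 4.60e-41 i<j
#> 3 G00049 G00303     8    69   118     5     0 4.55e-38 i<j
```

Each row is one oriented reverse pair: among the 77 status-0 samples the
first pair shows `G00228 < G00165` in 75, while among the 123 status-1
samples the ordering flips in 114 — Fisher p ≈ 5.5e-42. The `orientation`
column records the risk ordering (the one typical of status-0 samples). The
log-space Fisher test handles far smaller values; on an ordering table of
the strength seen for the best IDH reversal pairs in real ~650-patient
discovery cohorts, (193, 22, 39, 403):

```r
fisher_reversal_test(193, 22, 39, 403)
#> [1] 1.264279e-98
```

The whole study flow runs from one config:

```r
res <- run_pipeline(pipeline_config(
  out_dir = "demo-run", simulation = cfg, seed = 42
))
res$signatures$status1
#> <gene_pair_signature> status 'status1': 11 pairs, intercept -6.892, cutoff 3.779 (logrank-max)
res$panel
#> <ensemble_panel> 4 pairs (vote threshold 0.50, criterion cindex)
res$reports$ensemble
#> <survival_eval> n = 200 (76 high / 124 low risk), 62 events
#>   C-index 0.618; log-rank p 1.14e-05
#>   HR (high vs low) 2.983 [1.787, 4.979]
#>   AUC at t=1: 0.654
#>   AUC at t=3: 0.589
#>   AUC at t=5: 0.624
```

The majority-vote panel splits the cohort into 76 high-risk and 124
low-risk samples; high-risk samples die about three times faster
(HR ≈ 3.0) and the split is strongly supported by the log-rank test. All
fitted objects have `tidy()`, `glance()` and `autoplot()` methods, and
`write_signature()` / `read_signature()` serialize signatures and panels to
a versioned JSON schema so a frozen panel can be applied to external
cohorts with `run_external()` (classification reads expression only — no
survival leakage).

A thin command-line wrapper with `simulate`, `detect`, `build-gps`,
`ensemble`, `classify`, `evaluate` and `run-all` subcommands is installed
at `inst/cli/pairsig.R`.

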