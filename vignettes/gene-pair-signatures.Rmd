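---
title: "Gene-pair signatures: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-pair signatures: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pairsig)
```

## The statistical idea

Absolute expression values are hostage to platform, library size and
normalization. The quantity this package works with instead is the
*within-sample ordering* of a pair of genes: the indicator
`1[expr(G_i) > expr(G_j)]` evaluated sample by sample. Any normalization
that is strictly increasing in the raw values — which covers essentially
all practical pipelines — leaves every such indicator unchanged. A *reverse
gene pair* for a binary genomic status (say IDH mutation) is a pair whose
ordering is predominantly one way in status-negative samples and the other
way in status-positive samples. A small panel of such pairs is a
transcriptome-level readout of the genomic status, and, because the status
is prognostic, a prognostic classifier.

The package builds three nested objects:

* a ranked table of **reversal records** per status
  (`detect_reverse_pairs()`),
* a weighted **gene-pair signature** per status (`build_signature()`),
* an unweighted majority-vote **ensemble panel** combining two signatures
  (`build_ensemble()`).

## Detection

For one binary status with `n0` negative and `n1` positive annotated
samples (samples with unknown status are dropped from that screen, genes
with any missing value are excluded):

1. `rank_transform()` replaces each sample's values by within-sample ranks
   (ascending, average ranks on exact ties).
2. `mean_rank_deviation()` computes, per gene, mean rank in status-positive
   minus mean rank in status-negative samples.
3. `select_candidate_genes()` keeps the `floor(0.10 * G)` most up- and
   most down-deviating genes (deterministic gene-id tie-break), and
   `enumerate_pairs()` forms their full cross product. The 10% fraction
   balances covering the true signal against the cost of the quadratic
   pair enumeration; it is exposed as `fraction`.
4. `pair_order_counts()` tabulates the four ordering counts `a, b, c, d`
   per pair. Exact expression ties are counted separately and excluded:
   a tie is evidence of neither ordering. This is the conservative reading;
   it also keeps every count monotone-invariant.
5. `fisher_reversal_test()` computes the two-sided Fisher exact p of
   `[[a, b], [c, d]]` as the sum of hypergeometric point masses not
   exceeding the observed mass. All arithmetic is in log space via
   `dhyper(log = TRUE)` and a log-sum-exp: informative pairs in cohorts of
   a few hundred samples reach p around 1e-40 to 1e-100, far below what a
   naive product of probabilities can represent. Equality with direct
   enumeration is verified to 1e-12 relative error over every table with
   total at most 30. The knife-edge rule for "not exceeding" uses the
   customary 1e-7 relative tolerance so results agree with the standard
   two-sided convention.
6. Pairs are screened at `alpha = 0.05` Bonferroni-corrected over **all**
   `choose(G, 2)` orderable pairs — not merely the enumerated up-by-down
   products. The candidate sets are chosen using the same labels the test
   then uses, so the enumerated pairs are the most extreme corner of the
   full search space; correcting only over them is anti-conservative.
   With the full-space correction, label permutations on a 500-gene,
   200-sample cohort produce no significant pair in 20/20 permutations,
   i.e. the screen is calibrated. Survivors are ranked by ascending p with
   a deterministic tie-break (larger normalized odds `|ad − bc|/((a+b)(c+d))`,
   then lexicographic pair id) and the top `top_k = 50` kept.

Each record's `orientation` names the *risk ordering* — the one commoner in
status-negative samples (the unfavorable state, e.g. IDH wild-type).

## Signature fitting

`pair_profile()` turns records into binary features per sample. Two
polarities are kept: `reversed` (1 = the status-positive-typical ordering)
and `risk` (1 = the risk ordering); ties are 0 in both.

`stability_lasso_select()` repeats an L1-penalized logistic regression of
the status on the profile `n_repeats = 50` times. Each repeat resamples the
samples by stratified bootstrap and picks its penalty by internal 5-fold
cross-validation (`lambda.min`); a pair is kept when its coefficient is
nonzero in at least `freq_threshold = 0.8` of the repeats. The resampling
scheme is the package's interpretation of "repeated LASSO": something must
vary across repeats for the frequency to be informative, and the stratified
bootstrap is the standard stability-selection choice. Both knobs are
exposed; `n_repeats = 1` degenerates to a single cross-validated fit.

`fit_signature()` refits the selected pairs without penalty (relaxed-lasso
practice) as a logistic regression of the *unfavorable* status on the
risk-ordering bits. The linear predictor is the risk score: positive
coefficients mean "this risk ordering raises the risk", samples showing many
risk orderings score high, and `classify_risk()` calls a sample high-risk
iff its score strictly exceeds the cutoff (a score exactly at the cutoff is
low risk — ties resolve to the favorable class). Under complete separation
(common on strong signatures) the fit falls back to a lightly
ridge-penalized one (`lambda = 0.01`) and flags `separation_fallback` in
the provenance; the ranking of scores, which is all the cutoff and
classification use, is insensitive to this fallback.

`optimal_cutoff()` offers two rules: `logrank-max` (default) scans the
score quantiles 0.1–0.9 in steps of 0.05, keeps splits leaving at least 10
samples per stratum, and returns the cutoff maximizing the two-group
log-rank statistic; `mean` returns the mean score. Both appear in the
literature on such signatures; when no survival signal exists the
log-rank-maximizing cutoff is unstable across resamples, which is inherent
to maximally selected statistics and one reason the mean rule is offered.

## Ensembling

`pool_pairs()` merges the two signatures' pairs on a common risk polarity
(every pair's risk ordering votes *for* high risk), erroring on
contradictory orientations, and ranks candidates by detection p-value.
`forward_select()` then grows the panel greedily: starting from the most
significant pair, each next candidate is kept only if adding it *strictly*
improves the training criterion — Harrell's C-index of the majority-vote
label against overall survival (default), or the log-rank statistic. Equal
scores skip the candidate, which keeps panels small and the procedure
deterministic. Voting is unweighted: the logistic coefficients are
deliberately discarded at the ensemble stage, and a sample is high risk iff
strictly more than half (`vote_threshold = 0.5`) of the panel pairs show
their risk ordering.

By construction the greedy panel's training criterion is monotone over the
selection path, so it dominates its own singleton start. Dominance over the
two *base signatures'* risk groupings (whose classifier — logistic score
plus fitted cutoff — is different from a majority vote) is an empirical
regularity on cohorts where both statuses carry hazard information, not a
theorem; the bundled end-to-end check demonstrates it on the demo
configuration.

## Survival evaluation

`evaluate_model()` wraps the standard machinery: Kaplan–Meier per risk
group and the two-group log-rank test (survival package), Harrell's
C-index via `survival::concordance()` with the risk convention (higher
score, earlier death; tied scores count one half), and a univariate Cox
model with Efron tie handling for the hazard ratio of high versus low risk.
The fixed-horizon AUC uses the plain binary definition: cases are observed
deaths by the horizon, controls are samples still under observation beyond
it, and samples censored before the horizon are excluded. This is a
deliberate simplification relative to IPCW or cumulative-dynamic
time-dependent ROC estimators: it is exactly reproducible by a hand count
of case–control pairs, at the price of a mild bias when censoring before
the horizon is heavy and score-dependent. Horizon units are whatever the
clinical table's time column uses; the package never converts units.

## The synthetic cohort generator

`generate_cohort()` emulates the data structure the pipeline assumes, on a
glioma-like template:

* two binary statuses, the second nested in the first
  (`prevalence_s1 = 0.67`, `P(s2 | s1) = 0.40`, `P(s2 | !s1) = 0` by
  default, matching the prevalence pattern of IDH mutation and 1p/19q
  co-deletion in large mixed-grade cohorts, where co-deletion essentially
  implies IDH mutation);
* log-normal expression, `exp(mean + N(0, noise_sd))`, gene baselines
  `N(7, 2)` on the log scale;
* planted reversal pairs: both genes of a pair share a baseline and a
  per-sample pair-level random effect `N(0, pair_effect_sd)`; their means
  sit at `±reversal_strength/2` around the shared level, the signs swapping
  with the status. The separation `δ = reversal_strength` gives a
  closed-form per-sample probability `pnorm(δ / (noise_sd * sqrt(2)))` of
  the status-typical ordering (the shared terms cancel within the pair);
  the defaults `δ = 2, noise_sd = 1` give ≈ 0.92. The shared pair effect
  is essential, not decorative: without it, two genes taken from two
  *different* planted pairs with nearby baselines would form just as strong
  a reversal pair as a planted one, and "the detector's top pairs are the
  planted pairs" would be unachievable in principle under the cross-product
  pairing rule. The shared effect leaves within-pair orderings untouched
  while overdispersing cross-pair orderings;
* exponential survival with hazard
  `baseline_hazard * exp(log_hr_s1 * s1 + log_hr_s2 * s2)` (defaults 0.1
  events per time unit; log hazard ratios −1.0 and −0.7, both protective),
  and censoring `min(Uniform(0, 2 * censor_time_max), censor_time_max)`,
  which mixes early drop-out with an administrative mass at the horizon
  (default 10 time units) — exercising both censoring regimes the C-index
  comparability rules must handle;
* `apply_monotone_distortion()` re-maps every sample through an independent
  strictly increasing transform (power, positive-affine, shifted-log or
  identity), emulating arbitrary per-sample platform differences.

Structural randomness (which genes are planted, baseline levels) is driven
by the config seed; sampling randomness (statuses, noise, survival) by an
overridable `sample_seed`. Calling the generator with the same config and a
new `sample_seed` therefore draws an independent cohort from the same
population — the natural stand-in for an external validation cohort.

What the generator does **not** emulate: probe-level artifacts, batch
structure beyond monotone distortion, copy-number dosage gradients along
chromosomes, non-proportional hazards, or informative censoring. Passing
tests on synthetic cohorts therefore demonstrates correctness of the
algorithms and their invariances, not clinical performance on real data.

## Numerical and reproducibility choices

* Fisher p-values are computed and can be returned in log space
  (`log.p = TRUE`); they are exact to at least 10 significant digits for
  table totals up to 1000.
* Every stochastic step takes an explicit integer seed; the pipeline fans a
  single master seed out to its stages by fixed offsets, so a config
  reproduces every artifact byte for byte.
* All selection steps (candidate genes, pair ranking, forward selection)
  have deterministic tie-breaks, so results are platform-independent.
* Degenerate inputs fail loudly: single-class labels, constant scores,
  missing signature genes, empty sample intersections, truncated or
  version-mismatched signature files.

## Problem sizes used in the bundled checks

The test suite and the acceptance script exercise the pipeline at sizes
chosen to make the statistical properties measurable while staying
desk-scale: detection and invariance checks on 200 samples × 500–1000
genes, planted-recovery and null-calibration sweeps over 20 simulated
cohorts, Cox recovery at n = 2000, and a full end-to-end run on 300
samples × 1000 genes. These sizes are an order of magnitude below real
discovery cohorts in gene count but preserve every structural feature the
algorithms depend on.

## Known limitations

* The horizon AUC ignores censoring between 0 and the horizon beyond
  excluding those samples (see above).
* Pair enumeration is the full up×down cross product; with very large
  `fraction` the quadratic cost dominates detection.
* The ensemble interface is written for exactly two base signatures, as in
  the underlying design; `pool_pairs()` generalizes trivially but is not
  tested beyond two.
* Gene identifiers are matched as exact strings; harmonizing probe-level
  identifiers to gene symbols across platforms is the user's
  responsibility, upstream of this package.
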