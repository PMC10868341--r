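---
title: "Deep centroid cascades: model, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep centroid cascades: model, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Omics classification tasks — calling cancer from cfDNA fragment counts,
prognosis from expression arrays, drug sensitivity from expression plus
methylation — typically offer a few hundred samples against thousands of
features, imbalanced classes, and external validation cohorts that differ
systematically from the training source. Flexible models overfit both the
noise and the batch; the nearest-centroid classifier (NCC), which only
estimates two class mean vectors, is famously stable here but has little
fitting capacity. `deepcentroid` combines the two: a stack of pruned NCC
ensembles whose depth adapts to the data.

## The model

### Feature scanning

A base classifier never sees the whole matrix; it sees one *feature set*
produced by a scanning strategy:

* **Random scanning (default).** `n_feature_sets = 500` subsets, each of a
  size drawn uniformly from `[set_size_min, set_size_max] = [10, 200]`,
  members sampled without replacement within a set. Sets overlap freely
  across the ensemble. The uniform size law is our choice; only the range
  is fixed by the method's configuration.
* **Sliding windows** (ablation comparator): `n_feature_sets` contiguous
  windows of width `window_size = 100` (the median random-set size), with
  step `floor(p / n_feature_sets)`. Window starts are clamped at
  `p − window`, and the final window is always anchored there, so every
  set has exactly `window` members and both matrix ends are covered.
  Because feature order in omics matrices is usually alphabetical or
  positional rather than biological, windows are expected to underperform
  random sets — which is precisely what the ablation probes.
* **Gene-set scanning**: curated sets (GO/KEGG GMT files via
  `read_gmt()`) intersected with the matrix's feature names; sets with
  fewer than `min_overlap = 10` surviving members are dropped. This trades
  coverage for prior biological coherence.

### One cascade layer

For each feature set, on the layer's input matrix:

1. **Balanced resampling.** Draw `n` samples with replacement;
   `round(0.65 · n)` draws come from the minority class
   (`sampling_coefficient`, anchorable to the positive class instead via
   `coefficient_class`). The never-drawn samples form the classifier's
   out-of-bag (oob) validation set. Degenerate draws — a class missing
   from the training multiset or an empty oob set — are re-drawn, with a
   hard error after 100 attempts. The published description fixes the
   coefficient's value but not its precise semantics; "fraction of draws
   given to the minority class" is our reading, chosen because it pushes
   the training multiset toward the stated goal of balanced classes.
2. **Centroid fitting.** Class centroids are unshrunk per-feature means.
   The sample score is `d(x, centroid_neg) − d(x, centroid_pos)` with
   Euclidean distance on the z-scored data (a correlation distance is
   available but non-default); positive score ⇒ positive class; an exact
   tie predicts negative — deterministic and conservative for
   case/control screening.
3. **Pruning.** A classifier's oob MCC must exceed `prune_threshold = 0`
   or it is removed. A layer that prunes everything is a hard error (the
   data carry no detectable signal at that threshold).
4. **Layer validation.** The layer's own quality is the MCC of the
   surviving classifiers' majority vote over the union of oob samples,
   each sample voted on only by classifiers for which it is oob — an
   out-of-bag ensemble estimate that reuses no training information.

### Depth, augmentation and stopping

The next layer's input is `[one signed score column per survivor |
re-injected scanned features]`. Design choices worth spelling out:

* **One signed score per classifier** is the minimal faithful encoding of
  "the centroid distances become new features"; `augment_mode =
  "distances"` switches to two raw distance columns per classifier for
  sensitivity analysis.
* **Re-injection uses the union** of all columns touched by the scan plan,
  de-duplicated, rather than per-set copies — identical information at
  linear memory. Re-injection exists to keep feeding fresh information to
  deep layers so the cascade does not converge prematurely; it can be
  disabled (`reinject = FALSE`).
* **Deep-layer feature sets are re-drawn randomly** over the augmented
  width with the same size law (bounds clamped to the available width).
  How deep layers form their sets is not pinned down by the published
  description; re-drawing mirrors standard cascade-forest practice.

Training stops at the first layer whose validation MCC fails to improve
on the best so far (`patience = 0`; an exactly equal MCC counts as
non-improvement), or at `max_layers = 20`. The retained model is the best
prefix of layers; under patience 0 its layer MCCs are strictly
increasing. Prediction propagates new samples through the retained
layers — standardized with the *training* normalization statistics — and
majority-votes the final layer; the vote fraction is the reported
probability, with 0.5 labelled negative.

### Multi-omics fusion

Two modes for a paired secondary matrix: `fusion = "concatenate"` joins
both matrices as first-layer input (and in the re-injection block);
`fusion = "reinject"` keeps the first layer on the primary matrix and
adds the secondary matrix's scanned-column union to the re-injection
block only, so the second data type enriches deep layers without widening
the first — useful when the secondary type is weaker or noisier.

### Feature importance

`rank_important_features()` scores a feature as the mean oob MCC of the
surviving *first-layer* classifiers whose set contains it (deeper layers
operate on derived score columns, not original features), and reports the
top `k` with the number of containing classifiers. This is a documented
stand-in for a procedure whose exact published form is unavailable. Its
resolution is intrinsically limited: with 500 sets of median size ~100
over thousands of features, each feature is seen by a couple of dozen
classifiers whose oob MCC also varies with their resamples and the other
set members, so single-feature attribution is noisy; the
`feature_recovery_precision_at_50` quantity in `scripts/acceptance.R`
measures exactly this on planted ground truth. Treat the table as an
enrichment-ready candidate list, not a calibrated ranking.

## Evaluation harness

`repeated_cv()` runs repeated stratified k-fold CV (default 10×5),
refitting from scratch per fold; `independent_validation()` refits
several times on one cohort and averages metrics on a disjoint cohort;
`run_ablation()` evaluates variants on identical folds for paired
comparison. Metric conventions: MCC returns 0 when any denominator factor
is zero; AUC is the Mann–Whitney statistic with ties counted ½; F1 is the
positive class's and returns 0 in the 0/0 case; aggregates are means (with
sds) over all repeat×fold cells.

## Numerical conventions

* z-scoring uses the population denominator *n*; constant training
  columns map to 0, also for new data. Held-out data are always
  transformed with training statistics.
* All randomness flows from one root seed through a fixed derivation
  scheme (a multiplicative mix per layer/classifier/purpose, kept inside
  32-bit range), so fits are bit-reproducible and every random draw is
  insulated from the caller's RNG state.
* Ties: sample score 0 → negative; vote fraction 0.5 → negative; equal
  layer MCC → non-improvement. All deterministic.
* Missing values in input files are rejected by default
  (`impute = "mean"` opts into per-feature mean imputation); matrix
  orientation must be declared, never guessed.
* Models persist as versioned JSON of plain arrays at full IEEE precision
  (`save_model()`/`load_model()`), so a round trip reproduces predictions
  bit-identically and artifacts stay auditable.

## The synthetic-data generator

`simulate_omics()` is the package's test bed: Gaussian features
(`noise_sd = 1`), a planted set of informative features mean-shifted by
`effect_size` (in sd units) in the positive class, optional
equicorrelation among them (`block_correlation = 0.2` by default —
informative genes in real data are co-expressed, not independent),
configurable imbalance, and an independent cohort from the same law with
a location shift (`batch_shift = 0.5` sd) on a random half of the
features, emulating cross-source inconsistency without erasing the
signal. Feature order is randomized so the informative set is scattered —
the property that makes the scanning ablation meaningful. The default
scenario is 200 samples × 2000 features, 50 informative, effect 1.0,
classes 1:3. `simulate_multiomics()` adds a paired secondary matrix whose
informative features share the class signal in a configurable fraction.
A `heavy_tails` flag swaps the noise for scaled t(5) draws.

What the generator does *not* emulate: count-like or beta-like marginal
distributions, realistic correlation structure beyond one equicorrelated
block, feature-specific variances, or nonlinear class boundaries. Passing
tests on this generator therefore demonstrate the mechanics of scanning,
pruning, cascading, voting and cross-cohort transfer — not performance on
any particular real assay.

## Problem sizes used in the test suite

The shipped tests run the default scenario (200×2000, 500 feature sets)
for the seeded end-to-end checks — cascade vs single-NCC cross-validation,
the scanning ablation, the permuted-label null and determinism, each over
ten seeds with 5-fold CV — and smaller matrices (tens to hundreds of
samples/features, 20–120 sets) for module-level unit and property tests.
These sizes were chosen so the whole suite exercises full-scale behaviour
while remaining quick to run routinely.

## Known limitations

* Binary classification only; the voting and MCC machinery is two-class.
* Only the built-in nearest-centroid base classifier is serializable;
  custom `base_classifier()` plug-ins fit and predict in-session.
* Feature importance is first-layer, mean-MCC based and low-resolution
  (see above).
* The cascade's advantage over a single all-feature NCC is real but
  modest when the signal is dense and linear — exactly the regime a plain
  NCC already handles; its value grows with pruning opportunities
  (scattered, partially informative feature space).
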