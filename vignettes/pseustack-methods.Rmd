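---
title: "Methods: stacked ensembles with swarm-weighted RNA profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stacked ensembles with swarm-weighted RNA profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pseudouridine (Ψ) is the most abundant internal RNA modification; a *PseU
site* is a uridine carrying it. Experimental mapping is expensive, so
sequence-based predictors are used to call candidate sites from short,
fixed-length RNA windows centered on a uridine (21 nt in the human/mouse
benchmark generation, 31 nt in the yeast one). pseustack implements a
retrainable predictor of this kind: a two-level stacked ensemble whose
intermediate representation — the *RNA profile* — is re-weighted by particle
swarm optimization (PSO) before the final logistic call.

## Architecture

The pipeline has five stages, each exposed as its own function so every
intermediate can be inspected and tested:

1. **Encodings** (`encode_windows()`). Two families, each at k = 1, 2, 3,
   giving six representations. One-hot of k-nucleotides expands each of the
   `lambda - k + 1` overlapping k-mers into a `4^k` indicator block
   (dimension `4^k * (lambda - k + 1)`, position-major layout); k-mer
   frequency counts the overlapping k-mers and divides by `lambda - k + 1`,
   so each row is a probability vector. Columns follow lexicographic
   `A < C < G < U` order. The layout and the frequency normalizer are
   implementation choices (any fixed layout is information-equivalent;
   normalizing makes 21-nt and 31-nt windows commensurable).

2. **Base classifiers** (`base_registry()`, `fit_base()`). Five
   tree-ensemble families in fixed order: AdaBoost (ADA), gradient-boosted
   trees (GBDT), extreme gradient boosting (XGB), random forest (RF) and
   extra trees (ET). Hyperparameters are each family's widely used
   defaults — 100 estimators throughout, shallow trees with learning rate
   0.1 for GBDT, regularized depth-6 boosting for XGB, impurity-scored
   forests for RF/ET — surfaced in the registry and overridable; nothing is
   tuned. GBDT and XGB are both gradient boosting with deliberately
   different configurations; ADA is discrete AdaBoost over exact
   best-weighted-error decision stumps. All families expose nonnegative
   per-feature importances and positive-class probabilities.

3. **Two-step feature selection** (`threshold_sweep()`). For each of the
   6 × 5 = 30 (encoding, family) pairs: fit the family once on the full
   matrix, take its importance vector, and try every distinct importance
   value (ascending) as an inclusion threshold `importance >= t`. Each
   candidate mask is scored by stratified 5-fold CV accuracy of a freshly
   fitted model of the same family on the masked matrix; the best mask
   wins, ties going to the larger threshold (fewer features). Because the
   comparison is inclusive the argmax feature is always kept, so masks are
   never empty; because thresholds are nested the candidates form a
   monotone family, which is what makes exhaustive verification cheap in
   tests. When more than `max_thresholds` (default 200) distinct values
   exist, thresholds are subsampled at quantiles. Scoring by CV rather than
   training fit avoids the trivial all-features optimum; this is an
   interpretation, the alternative being underdetermined.

4. **Stacking** (`oof_profile()`, `test_profile()`). Training rows are
   split into `stacking_folds` (default 10) stratified folds; each of the
   30 masked (encoding, family) models is fitted per fold on the other
   folds and predicts the held-out fold. Row *i*'s profile entry in column
   *c* therefore comes from a model that never saw row *i* — the honesty
   that lets the meta-classifier train on the profile without leakage.
   Held-out or deployment sequences get the average of the k fold models'
   probabilities per column. Profile values are probabilities, not hard
   labels, preserving information for the meta-classifier and making the
   per-column MCC and correlation diagnostics meaningful. Masks are chosen
   once on the full training set before stacking (matching the stated
   ordering of the architecture); the evaluation harness below never lets
   this touch held-out data.

5. **PSO weight search + logistic meta-classifier**
   (`optimize_weights()`, `fit_meta()`). Particles live in the `[0,1]^30`
   box; a particle *is* a candidate per-column weight vector. Fitness of
   `w` is the stratified 10-fold CV accuracy of the logistic
   meta-classifier trained on the column-weighted profile. The swarm uses
   the standard inertia-weight update with 60 particles, 100 iterations,
   inertia 0.8 and learning factors c1 = c2 = 0.6; the final weights are
   the global best, and the global-best history (the fitness curve) is
   non-decreasing by construction.

## Numerical and design choices

* **Meta-classifier.** Ridge-penalized logistic regression
  (`glmnet`, `alpha = 0`, penalty `1/n`, i.e. unit-strength L2), fitted
  *without* standardization — standardizing would silently undo the very
  column weights the swarm searches. The ridge penalty keeps the fit
  defined under the quasi-separation that near-perfect profile columns
  routinely produce. PSO fitness and the final model share identical
  settings, since the searched weights are only optimal for the surface
  they were scored on.
* **Weight identifiability.** The meta-classifier can rescale
  coefficients, so a column's raw PSO weight is only defined up to that
  rescaling wherever it is bounded away from zero; the interpretable
  quantity is the effective weight (weight × coefficient), which `tidy()`
  exposes alongside both factors.
* **PSO details.** Initialization is uniform in the box; velocities start
  uniform in `±vmax` and stay clamped there (`vmax = 0.2` of the range —
  unstated in the architecture's description, chosen to prevent
  wall-bouncing); positions are clipped to the box (absorbing walls). The
  fitness CV partition is drawn once per search and shared by all
  particles and iterations, making fitness a deterministic function of the
  weights — otherwise global-best monotonicity would be ill-defined under
  resampling noise.
* **Metrics.** ACC, SN, SP and MCC from pooled confusion counts; any
  zero-denominator metric is defined as 0. Balanced data never hits this;
  synthetic edge cases do. The decision threshold is fixed at 0.5
  (balanced benchmarks).
* **Evaluation protocol.** `cross_validate()` refits the *entire*
  pipeline — selection, stacking, PSO — inside each outer fold (the honest
  protocol); pooled and per-fold metrics are both reported. Plain stacking
  (all weights 1) and PSO-weighted stacking are evaluated from the same
  fold models, so their comparison is paired and cheap.
* **Determinism.** Every stage derives its seed from `config$seed`
  (per-column offsets keep fold models independent but reproducible);
  single-threaded tree fitting makes refits bit-identical.

## The synthetic generator

`generate_windows()` draws uridine-centered windows with class-conditional
position-specific nucleotide distributions: a handful of offsets near the
center carry enrichment (the `human_like` preset puts A/U at ±1 in
positives and C/G at ±1 in negatives, with milder U-at--5 / C-at-+9
preferences in negatives; `yeast_like` puts G/U upstream and C/G
downstream of positives), all other positions are uniform background, and
a `strength` dial blends the motif with the background (`strength = 0` is
an exact null; the default 1 uses the enrichment probabilities as stated).
The enrichment values are fictitious but shaped like the
position-preference structure reported for real PseU benchmarks. Because
positions are independent given the class, the generator's Bayes-optimal
accuracy has a closed form (a sum over the joint states of the enriched
positions); for the human-like preset it is about 0.93 at full strength,
the yardstick against which pipeline recovery should be read. Positions
are independent given the class by default; an optional first-order
stickiness parameter copies the previous base with some probability,
creating dinucleotide structure that k = 2, 3 features can exploit but
k = 1 marginals cannot.

What the generator does *not* emulate: the composition statistics,
sequence redundancy, and label noise of real transcriptome-derived
benchmarks, nor any long-range secondary-structure signal. Tests passing
on synthetic data therefore demonstrate that the machinery recovers
planted signal and stays at chance on null data — not that any particular
accuracy will transfer to real datasets, which must be evaluated with
`cross_validate()` on the user's own FASTA files.

## Problem sizes and the fast profile

The default configuration (60 × 100 PSO, 10 stacking folds, full
threshold sweeps) is the production setting. `fast_config()` keeps the
full 30-column architecture but shrinks the search (10 particles × 20
iterations, 5-fold fitness, 5 stacking folds, 6-point 3-fold sweeps,
lighter boosted ensembles); it is what the package's own test suite and
acceptance script use, at dataset sizes of 400 windows (enriched) and 200
windows (null). These sizes were chosen so that a complete nested 10-fold
cross-validation — thirty base learners refitted per sweep point, fold and
outer fold — remains an interactive-scale computation while still giving
binomial confidence intervals of a few percent on pooled accuracy.

## Known limitations

* The two gradient-boosting families share one backend (configured
  differently), so their profile columns are more correlated than a
  five-backend ensemble's would be; the correlation heatmap
  (`plot_profile_correlation()`) makes this visible.
* The threshold sweep's cost grows with the number of distinct importance
  values; the quantile cap trades optimality for cost on the k = 3
  one-hot matrices.
* No ROC/AUC machinery and no significance tests between predictors; the
  evaluation surface is the four threshold metrics.
* Windowing of full-length transcripts (scanning every U) is out of
  scope; inputs are pre-cut fixed-length windows.
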