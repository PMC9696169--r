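---
title: "Methods: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, simulation design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cytosig)
```

This vignette documents the statistical models the package implements, the
assumptions behind them, the synthetic-data generator that the test suite
and the acceptance script run against, and the numerical conventions that
were deliberately pinned where more than one reasonable choice existed.

## 1. The analysis pipeline

The package targets microarray studies of reconstituted human epidermis
(RHE) in which tissues are stimulated with a Th2/TNF-α cytokine cocktail
and co-treated with candidate topical compounds. The canonical design has
five groups of three replicates — control (CTL), cytokines (CYT), and
cytokines plus one of three treatments — and four two-group comparisons,
each using only its own six samples: the cytokine contrast (CYT vs CTL) and
three treatment contrasts (each treatment vs CYT).

### 1.1 Gene universe

`collapse_probesets()` reduces a probe-level matrix to one row per gene
symbol, keeping for each symbol the probe with the highest average
intensity over all samples (ties broken by the lexicographically smallest
probe ID). A protein-coding restriction is delegated to an
`is_protein_coding` annotation column; the package never queries an
annotation database.

Two per-comparison filters then define the tested universe:

* **Detection** (`filter_detection()`): a gene is detected in a sample when
  its intensity strictly exceeds the 20th percentile of that sample's
  intensities over all genes in the matrix; genes detected in at least 2 of
  the 6 comparison samples are retained. Whether the detection threshold
  should be computed per sample or from the pooled comparison-sample
  intensities is ambiguous for this class of rule; the per-sample reading
  is the default and the pooled variant is available via `scope = "pooled"`.
* **Variance** (`filter_variance()`): genes whose SD across the comparison
  samples falls strictly below the 5th percentile of the SD distribution
  are excluded.

On the default synthetic scenario these filters remove roughly a fifth of
the universe, the expected behaviour for arrays of this type.

### 1.2 Differential expression

`fit_contrast()` fits the group-mean model per gene: `log2fc` is the
difference of group means, and the residual variance is pooled within
groups with `d = n_a + n_b − 2` degrees of freedom. `moderate()` adds
empirical-Bayes variance moderation under the standard hierarchical model

* `s²_g | σ²_g ~ σ²_g · χ²_d / d`
* `σ²_g ~ scaled-inv-χ²(d₀, s₀²)`

The hyperparameters are estimated by method of moments on
`z_g = log s²_g`: after subtracting `digamma(d/2) − log(d/2)`, the excess of
`var(z)` over `trigamma(d/2)` identifies `trigamma(d₀/2)` (inverted by
Newton iteration), and the mean identifies `s₀²`. When the excess variance
is non-positive, `d₀ = ∞` and all variances collapse to the prior — the
correct degenerate limit rather than an error. Posterior variances are the
usual precision-weighted combination, and moderated t-statistics are
referred to `t(d₀ + d)` (normal when `d₀ = ∞`). This is the plain
no-trend, non-robust form of moderation; intensity-dependent trends and
robust estimation are out of scope.

Genes with zero pooled variance and zero mean difference are assigned
`t = 0, p = 1` (an exactly constant gene carries no evidence); zero
variance with a non-zero difference yields `p = 0`.

DEG calling (`call_degs()`) applies strict joint thresholds: significance
(FDR for the cytokine contrast at 0.10; raw p for the weaker treatment
contrasts at 0.05) *and* linear fold-change above 1.50 or below 0.67. All
inequalities are strict, matching the thresholds as printed conventions.

### 1.3 Signature statistics

Four statistics summarise a signature against a contrast, all computed on
the contrast's post-filter universe with case-insensitive symbol matching:

* **Overlap**: upper hypergeometric tail `P(X ≥ k)` for the intersection of
  the DEG list with the detected members.
* **Resampled mean fold-change**: the observed mean *linear* fold-change of
  detected members against B random same-size draws (without replacement)
  from the universe. The empirical p uses the add-one estimator
  `(1 + #{null ≥ obs})/(B + 1)`, so p is never 0 and its minimum is
  `1/(B + 1)`. Linear-scale averaging is the default because results of the
  form "members increased by 22% on average" are linear-scale statements; a
  log-scale option exists.
* **Sign majority**: exact two-sided binomial test of the fraction of
  members with FC > 1 against 0.5. Members with FC exactly 1 carry no sign
  information and are dropped (count reported); this conditioning is a
  documented choice.
* **Rank enrichment**: one-sided Wilcoxon rank-sum of member fold-change
  ranks against the rest of the universe, exact for universes ≤ 20 without
  ties, otherwise the tie-corrected normal approximation.

The overlap and rank tests are interpretive choices: studies of this type
typically name neither test, and the hypergeometric/Wilcoxon pair is the
most common reading. Both sit behind `signature_report()` so alternatives
can be added without touching callers.

### 1.4 Cross-contrast concordance

`align_contrasts()` inner-joins two contrasts case-insensitively.
`spearman_fc()` uses mid-rank ties with the t approximation (exact
permutation for n ≤ 8). `quadrant_proportions()` classifies genes by the
signs of the two log2 fold-changes; genes exactly on an axis have no
quadrant and are excluded from the proportions but counted, so every pair
is accounted for. `mahalanobis_ellipse()` marks the central fraction of
genes by squared Mahalanobis distance to the sample centroid under the
sample covariance; the threshold is the *empirical* coverage quantile
(exactly `⌈coverage·n⌉` points, ties broken by original order) rather than
the χ²₂ theoretical quantile, because "the middle 90% of genes" is an
empirical statement. `discordant_genes()` extracts reference-significant
genes whose response crosses a fold-change threshold in the opposite
direction.

### 1.5 Sample structure

`pca_scores()` centres each gene (no unit-variance scaling by default —
standard for log-intensity matrices; a `scale.` switch exists) and uses the
SVD, with the sign of each component fixed so its largest-magnitude gene
loading is positive, making scores reproducible and invariant to gene
order. `hierarchical_cluster()` defaults to correlation distance with
average linkage — the common choice for expression arrays; samples are
sorted by label first so merge order is deterministic under ties.

### 1.6 Assay statistics

`fit_slopes()` pools all replicate wells of a condition into a single
regression of absorbance on time (matching a single per-condition
least-squares slope estimate with its SE); per-replicate slopes can be had
by filtering the input. Percent inhibition is
`(1 − slope_t/slope_c) × 100`, reported unclipped (negative values indicate
activation) with a clipping display option. The default time grid includes
t = 0 — reads "at 5, 10 and 15 min" leave t = 0 ambiguous, and dropping it
is a one-line filter on the input. `interaction_test()` fits
`absorbance ~ time × condition` over the two conditions and reads the
two-sided t p-value of the interaction coefficient.

`fisher_lsd()` uses the one-way-ANOVA pooled MSE for all pairwise t-tests.
The compact letter display assigns the maximal cliques of the
non-significance graph (p ≥ α edges) as letters, ordered by group mean —
this guarantees, by construction, that two groups share a letter iff their
pairwise test is non-significant, with a minimal letter set for the group
counts used here. `one_tailed_t()` uses pooled variance, consistent with
the LSD's pooled-error philosophy at n = 3 per group; degenerate
zero-variance equal-mean input returns p = 0.5 by symmetry.

## 2. The synthetic-data generator

`simulate_expression()` draws
`value = baseline_g + shift_{g,group} + N(0, sd_g)` with per-gene baselines
`N(baseline_mean, gene_effect_sd²)` and residual SDs from
`scaled-inv-χ²(d₀, s₀²)` — the same family the moderation model assumes, so
the variance prior is a true, recoverable parameter of the simulation.
Defaults: baseline 7 log2 units, gene spread 1.5, `d₀ = 4`, `s₀ = 0.2–0.25`
log2 units, values typical of normalized single-channel arrays.

`build_scenario()` assembles the full study emulation:

* **Design**: 14,000 genes, five groups × 3 replicates.
* **Cytokine program**: 350 genes shifted +1 and 150 shifted −1 log2 unit
  in every cytokine-containing group. The magnitude distribution of real
  cytokine effects is unknown; a single planted magnitude keeps power
  calculations transparent and is configurable, not a claim about real data.
* **Treatment programs**: diffuse genome-wide effects
  `N(0, 0.4²)` per gene, constructed bivariate-normally with correlation
  −0.4 to a TNF-like reference program and 0 to a Th2-like program. A
  diffuse program (rather than a sparse one) makes the planted genome-wide
  correlation itself the recoverable truth for the concordance module.
* **External contrasts**: the reference programs plus `N(0, 0.1²)`
  estimation noise, with synthetic significance flags (q = 0.01) on true
  effects exceeding 1.5-fold — a labelled stand-in for an external study's
  FDR calls.
* **Signature**: 150 members drawn from the planted cytokine program with
  their true direction labels plus 50 non-differential members, split into
  increased/decreased arms for reporting.
* **Kinetic assay**: control slope 0.04 absorbance/min, intercept 0.05,
  noise SD 0.01, reads at 0/5/10/15 min, 3 replicates, planted inhibition
  fractions 0 (vehicle), 0.5 and 0.9.

What the generator does **not** emulate: probe-level effects and spatial
artifacts, batch effects, intensity-dependent variance trends,
correlation between genes beyond the planted programs, and non-Gaussian
noise. Passing tests therefore demonstrate correctness of the statistical
machinery under the stated model, not robustness to those real-data
features.

## 3. Numerical conventions

* Percentiles use linear interpolation between order statistics
  (`quantile` type 7) throughout, pinned for reproducibility.
* Detection is "strictly above" its threshold; the SD filter removes genes
  "strictly below" its percentile; DEG thresholds are strict inequalities.
* Percentile filters are *not* idempotent if thresholds are re-derived
  from their own output (the percentile moves); both filters therefore
  expose the thresholds they used (attributes + arguments), and
  re-application with pinned thresholds is exactly idempotent.
* The BH step-up adjustment is a fixed point only where the adjusted
  vector is constant over the affected suffix (e.g. evenly spaced
  p-values); general re-application is a different operation.
* Empirical p-values use the add-one estimator; resampling is without
  replacement from the tested universe (not the full array), since
  signatures are evaluated against what was detectable.
* All random draws are seeded; scenario sub-streams (programs, signature,
  external noise, kinetics) use fixed integer offsets of the master seed so
  stages remain independently reproducible.

## 4. Problem sizes used by the packaged checks

The test suite validates oracle equivalence on toy fixtures (universes
≤ 200; exhaustive enumeration at universe 12–15), calibration on planted
nulls (5,000-gene moderated-t uniformity; 500 replicate null signatures at
B = 199; 2,000 null kinetic assays), parameter recovery at study scale
(14,000 genes × 10 seeds; kinetic recovery over 10 seeds), and the
qualitative end-to-end pattern over 10 seeded full-scale pipeline runs at
B = 999. The acceptance script runs one full-scale scenario at B = 10,000.
These sizes were chosen so the whole validation remains comfortably
desk-scale while keeping Monte-Carlo error well inside the asserted
tolerances.

## 5. Known limitations

* Only two-group contrasts are supported — no covariates, paired designs
  or surrogate-variable correction.
* Moderation is no-trend and non-robust.
* Enrichment is set-based only; ontology-graph methods and weighted
  (GSEA-style) statistics are out of scope.
* External contrasts are consumed as (gene, fc, q) tables; the package
  never reprocesses external expression series.
* Dose series in the kinetic module are treated as independent conditions;
  mechanistic (Michaelis–Menten, IC50) fits are out of scope.
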