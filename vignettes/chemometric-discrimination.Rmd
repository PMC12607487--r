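---
title: "Discriminating metabolite profiles with cutoff filtering, PLS-DA and synergy statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating metabolite profiles with cutoff filtering, PLS-DA and synergy statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemodiscrim)
```

## The problem

GC/MS metabolite profiling of plant extracts yields compositional feature
tables: each sample is described by the relative abundance (percent of total
identified peak area) of tens of metabolites. A recurring question is whether
two groups of samples — here, hemp seed extracts of two geographic origins,
each extracted three ways (oil, hexane, ethanolic) — can be discriminated
from such profiles, and which metabolites carry the discrimination. With a
dozen samples and dozens of features, naive analysis is dominated by noise
from minor constituents, and an apparently excellent fit can have no
predictive value at all. `chemodiscrim` implements the full chain of
defensible steps for this setting:

1. **Cutoff filtering** — keep only "major component" features;
2. **Unsupervised structure** — hierarchical clustering (HCA) of z-scored
   abundances and PCA with explained-variance bookkeeping;
3. **Correlation-based feature selection** — collapse clusters of mutually
   correlated features to representatives;
4. **PLS-DA** — supervised two-class discrimination with honest validation:
   training R², cross-validated Q², a label permutation test, and VIP
   feature importances;
5. **Synergy arithmetic** — percent inhibition and pairwise-combination
   percent improvement for the downstream bioactivity experiments that such
   discriminative metabolites motivate.

## Data model

An `abundance_table` is a features × samples matrix of percentages with
unique identifiers on both axes. Values must be finite and non-negative and
each sample's column may sum to at most 100 (plus a small tolerance for
rounded tables); sums below 100 are expected because unidentified peaks are
excluded. Missing cells written as `-` in source CSVs mean "not detected"
and are read as 0. Class labels live in a `sample_classes` object: class
names are mapped to codes {0, 1} in order of first appearance in the file
and the mapping is stored, so the sign conventions of every downstream
model are reproducible. `align()` joins the two without ever reordering the
table's columns.

One deliberate type distinction: `zscore()` returns a plain matrix, not an
`abundance_table`, because standardized values are signed and are no longer
relative abundances; the container's invariants (non-negativity, bounded
column sums) are meaningful and would have to be abandoned otherwise.
`hca()` and `pca()` accept both forms.

## Cutoff filtering

`cutoff_filter()` retains a feature if its abundance reaches the threshold
(default 10%) in **at least one sample**, with an inclusive boundary. The
any-sample reading is the weakest rule that still yields a per-group "major
component" list — a marker metabolite of one class may be a trace compound
in the other, and a rule demanding the threshold in all samples (or on the
mean) would discard exactly the features that discriminate. Both stricter
rules remain available (`rule = "all_samples"`, `"mean"`) for sensitivity
analysis. Filtering is idempotent, and the retained set is monotone
non-increasing in the threshold.

## HCA and PCA

`hca()` wraps Euclidean-distance agglomerative clustering (average linkage
by default, the default of the common heatmap tools for this kind of
figure) of both samples and features, and returns *data artifacts* — merge
tables (node indices, heights, sizes) and dendrogram leaf orders — rather
than rendered images, so figures can be rebuilt and asserted on. Merge
heights are cross-checked in the test suite against a naive O(n³)
agglomeration oracle.

`pca()` computes the SVD of the column-centered (and by default
column-autoscaled) matrix. Explained-variance ratios are singular values
squared over their total, so they sum to one when every component is kept,
and the cumulative variance of the first two components is the number to
compare against the 40–90% range typical of such reduced tables. The sign
of each component is fixed so its largest-magnitude loading is positive;
without a convention, signs are arbitrary and tests (and collaborators)
disagree across BLAS builds.

Scaling choice: z-scoring is part of the HCA figure convention, while for
PCA and PLS-DA column autoscaling is this package's documented default —
with features on wildly different abundance scales, unscaled PCA is
dominated by the most abundant metabolite.

## Correlation clusters and representatives

`pearson_matrix()` gives the feature-feature Pearson matrix (n − 1
convention, exact unit diagonal). `correlation_clusters()` partitions
features into connected components of the graph with an edge wherever
|r| ≥ threshold (default 0.7). Connected components are the simplest
construction that is a true partition, order-invariant, and reproducible;
the threshold is exposed because the "right" number of clusters is a
property of the data. `select_representatives()` keeps one feature per
cluster — by default the most abundant one, since abundance is what makes
a marker practical to measure and high-abundance features are what such
studies report selecting; by `max_vip` when a fitted PLS-DA model is
available. All ties break alphabetically. Note the cluster count is
monotone: lowering the threshold merges, never splits.

## PLS-DA

`plsda_fit()` implements single-response NIPALS PLS1 on the autoscaled
matrix with a 0/1-coded class response: for each component the weight
vector is `w ∝ X'y` (exact for one response — no inner iteration), scores
`t = Xw`, loadings `p = X't/t't`, y-loading `q = y't/t't`, then X (and y)
are deflated. Regression coefficients are `W(P'W)⁻¹q`. Two components is
the default, matching two-axis score plots. The test suite cross-checks
the coefficients against an independently coded SIMPLS oracle, which is
algebraically equivalent for a single response but algorithmically
disjoint.

### Validation statistics

* **R²** (`r_squared`): `1 − SSE/SST` with `SSE = Σ(yᵢ − ŷᵢ)²` and
  `SST = Σ(yᵢ − ȳ)²` on the training data.
* **Q²** (`q_squared`): `1 − PRESS/TSS` over stratified k-fold
  cross-validation (default k = 5). For each fold, the scaling statistics
  and the model are re-estimated on the training portion only. Two
  ambiguities had to be decided:
  * *Which mean anchors TSS?* Default: the **training-fold mean**, applied
    to the held-out samples in both the PRESS baseline sense and TSS, so
    Q² = 0 means exactly "no better than predicting the training mean".
    The global-mean variant is exposed (`tss_mean = "global"`); with
    balanced classes and stratified folds the two coincide.
  * *Fold construction*: stratified by class and shuffled under a caller
    seed. With 12 samples in 5 folds, unstratified splits can produce
    single-class training sets, which are rejected with an instructive
    error rather than silently fit.
* **Permutation test** (`permutation_test`): the class labels are permuted
  uniformly at random, X fixed, and the *full* cross-validation (fresh
  stratified folds per run) is re-run each time; the p-value is the literal
  counting fraction `#{Q²_perm ≥ Q²_obs}/runs`, so p = 0 is attainable.
  The conventional `(count + 1)/(runs + 1)` estimator is available behind
  `add_one = TRUE`. Rationale for re-running CV per shuffle: reusing the
  observed fold assignment would correlate the null draws with the observed
  statistic.
* **VIP** (`vip`): the standard Wold formulation,
  `VIPⱼ = sqrt(p · Σₐ SSYₐ wⱼₐ² / Σₐ SSYₐ)` with `SSYₐ = qₐ² tₐ'tₐ` and
  unit-norm weights. This is the formula whose "VIP > 1 = important"
  convention the field uses; by construction the mean squared VIP is
  exactly 1, which the tests assert to 1e-9 on every fitted model.

### Q² interpretation

Q² above ~0.3 is conventionally read as moderate predictability and Q² ≤ 0
as none. On twelve samples Q² is a noisy quantity; the permutation test, not
the point value, is the significance statement.

## Bioactivity synergy arithmetic

`percent_inhibition()` is the absorbance formula
`(A_control − A_sample)/A_control × 100` (negative values = activation,
reported as-is). `improvement_pct()` compares a two-agent combination
against each of its constituent singles:

* **plain** mode for inhibition percentages:
  `(combined − single)/single × 100`;
* **magnitude** mode for docking scores:
  `(|combined| − |single|)/|single| × 100`. Docking scores are binding
  free-energy estimates where more negative is stronger; comparing
  magnitudes is the only simple rule consistent with published bracket
  values even when a score is printed with a positive sign.

Report columns round half away from zero (so 90.68 → 91, 119.08 → 119);
raw values are retained at full precision. `build_synergy_table()` always
computes the improvement for **both** reference agents of each pair and
keys rows by explicit reference agent rather than by printing position,
which is ambiguous in published tables.

## The synthetic-data generator

`simulate_abundance()` produces the study-shaped fixture every pipeline
stage is tested on: 12 samples in two classes of 6 (two cultivars × three
extract types per class, named accordingly), 61 compositional features of
which exactly 13 are "major" (≥ 10% somewhere) and 3 of the majors are
class-discriminative, named `linoleic_acid_like`, `clionasterol_like`,
`vitamin_E_like` — one dominant marker per class, alternating.

Construction, and why:

* **Log-normal intensities** (σ_log = 0.4) before closure to percentages:
  GC/MS peak areas are positive and right-skewed, and closure reproduces
  the compositional character (negative correlation bias included) of
  relative-abundance data. The σ_log default gives within-class
  coefficients of variation around 40%, a realistic figure for extract
  replicates; it is a tunable, not a calibrated, value since the
  within-class variance of the real data is unknown.
* **Fixed budget split**: minors share 25% of every sample's composition,
  majors 75%. This decouples the major/minor cutoff guarantees from each
  other, at the cost of a slightly rigid total — a documented
  simplification.
* **Class effect in log space**: discriminative features are multiplied by
  `exp(effect_size · σ_log)` in their elevated class. At the default
  `effect_size = 4` the class-mean separation is about four noise standard
  deviations, a strong-marker regime.
* **Deterministic cutoff guarantee**: each major has a "spotlight" sample
  (cycled; for discriminative features, cycled *within the elevated
  class*, so that reaching the cutoff reinforces the class structure
  rather than fighting it) in which an adjustment loop multiplies its
  intensity by 1.25 until its maximum share reaches 10%. Minors are
  symmetrically damped below 10%. The 61 → 13 reduction is therefore exact
  by construction, not probable, and the boosts are applied only when
  needed so the injected extra variance stays small.
* **Infeasible configurations** (too many majors per sample for the budget,
  or too few minors to stay under the cutoff) are rejected with an error
  rather than silently violated.

What the generator does *not* emulate: instrument drift, censored trace
peaks, retention-time misalignment, heteroscedastic detector noise, or any
real metabolite covariance beyond what closure induces. Passing tests on
this fixture demonstrate the pipeline's statistical machinery, not
performance on any particular real dataset.

Problem sizes used in the shipped tests were chosen to keep the full suite
fast while leaving the conclusions stable: permutation tests run at
200–1000 permutations, the null-calibration study at 100 datasets × 200
permutations, and replicate studies at 20–50 replicates.

## The pipeline and reporting

`run_pipeline()` chains filter → HCA → PCA → correlation selection → PCA
(selected) → PLS-DA → Q² → permutation → VIP, with every stage parameter
recorded in the summary (no silent defaults) and a single seed governing
all randomness, so reruns are byte-identical. `render_report()` produces a
deterministic plain-text account; with `out_dir` set, per-stage CSVs and a
`summary.json` are written. This package is function-first: the pipeline
functions and this vignette are the interface, and `scripts/acceptance.R`
in the source repository reproduces the headline numbers from a shell.

## Numerical choices and degenerate inputs

* Standard deviations use the n − 1 convention everywhere (z-score,
  correlation, autoscaling, PCA variance bookkeeping) for internal
  consistency.
* Zero-variance features/columns are errors naming the offender, never
  silent zeros — a constant feature carries no information and silently
  z-scoring it to 0 hides upstream problems.
* A PLS component whose weight vector has vanishing norm (no covariance
  left) raises an error instead of dividing by ~0.
* Ties: HCA ties resolve to the lower input index (the `hclust`
  convention); representative selection and feature ranking break ties
  alphabetically.
* All seeds are recorded in the result objects; package functions restore
  the caller's RNG state.

## Known limitations

* Two classes only; no multi-class PLS-DA, OPLS-DA or sparse variants.
* No external test-set validation — with twelve samples there is nothing
  to hold out beyond cross-validation, and the cross-validated Q² of such
  small designs is itself high-variance.
* The correlation-cluster count depends on a threshold the user must
  justify; the package exposes it rather than pretending to know it.
* `Q² ≤ R²` holds throughout the well-posed regimes exercised here but is
  not a theorem for arbitrary ill-posed fits, and is asserted only on the
  synthetic suite.
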