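---
title: "Classifying disease states from CDR3 k-mer composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying disease states from CDR3 k-mer composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdr3kmer)
```

## The problem

The third complementarity-determining region (CDR3) is the most variable
loop of a T- or B-cell receptor and dominates antigen binding. Across a
cohort, the *composition* of CDR3 amino-acid sequences in a cell subset
shifts with disease state, and short subsequences (k-mers, also called
amino-acid concatemers) capture those shifts without requiring any
sequence alignment or V(D)J annotation. `cdr3kmer` implements the full
path from per-cell repertoire tables to a disease-state classifier:

1. **Featurize** — every CDR3 string is cut into overlapping k-mers
   (step-1 sliding window) and each (sample, cell-subset) repertoire
   becomes one row of a count matrix over the *complete* k-mer space:
   all $20^k$ concatemers get a column, absent ones hold an explicit 0.
   For k = 2, 3, 4 the spaces have 400, 8&#8201;000 and 160&#8201;000 columns, and
   every non-empty combination of the chosen k values forms a dataset —
   seven datasets for k ∈ {2, 3, 4}.
2. **Filter** — columns that are zero in too large a fraction of rows are
   removed (zero-fraction threshold, default 0.95).
3. **Select** — each remaining feature is scored by a one-way ANOVA F
   test of its counts across the three states (healthy = 0,
   mild/moderate = 1, severe = 2); features with $p < \alpha$
   (default 0.05) are retained.
4. **Classify** — seven classifier families (LR, SVM, MLP, KNN, DC, RF,
   XGB) are compared on a stratified 4:1 train/test split with a small
   cross-validated hyperparameter grid per family, scored by
   one-vs-rest **macro AUC**: per class, the AUC of that class against
   the rest; the macro value is their unweighted mean, so small classes
   count as much as large ones.
5. **Assess** — the best model per dataset is gated on a
   label-permutation p-value, and top-ranked k-mers can be intersected
   across cell subsets to expose shared sequence structure.

## Statistical details

**ANOVA selection.** For feature $j$ with group sums of squares
decomposition $SS_B$ (between states) and $SS_W$ (within),
$F_j = (SS_B/(g-1)) / (SS_W/(n-g))$ with $g$ groups and $n$ rows, and
$p_j$ from the $F_{g-1,\,n-g}$ distribution. The computation is
vectorized over all columns (at k = 4 there are 160&#8201;000 of them), and a
direct `oneway.test()` computation is used as an independent oracle in
the test suite. Features with zero total variance are *degenerate* and
dropped before testing; features with zero within-group variance get
$F = \infty$, $p = 0$ and are also excluded from the kept set so that
every retained feature has a finite, comparable statistic. Raw p-values
are the default (Benjamini–Hochberg is available by option) — with
selection feeding a classifier rather than an inference, per-feature
error control is not the goal.

**Selection placement.** Selection is fitted on the training partition
only and applied unchanged to the test partition. Running selection on
the full matrix before splitting leaks test information into the
features and inflates test AUC; the package still exposes
`select_before_split = TRUE` to reproduce the reduce-then-split ordering
some analyses use, but the default is the safer ordering, and an
anti-leakage sentinel in the test suite (label-permuted data must score
macro AUC ≈ 0.5 for every family) guards it.

**Permutation p-value.** The significance attached to a model is a
label-permutation test on its test macro AUC:
$p = (1 + \#\{\mathrm{AUC}_{perm} \ge \mathrm{AUC}_{obs}\}) / (1 + B)$.
Every permutation re-runs the *entire* pipeline — selection on the
permuted training labels, refit, re-score — so selection optimism is
part of the null. Labels are shuffled within each partition, which
keeps every class represented on both sides and is a valid exchange
under the null (the partition is ancillary). The smallest achievable p
is $1/(B+1)$; reports use $B = 199$ by default (49 in quick mode).

**Probability scores.** Macro AUC needs a per-class score from every
family. Most families provide probabilities natively; the SVM's
internal probability calibration is randomized and not seedable from R,
so its one-vs-one decision values are summed per class and softmaxed
instead — a deterministic, rank-preserving mapping, which is all AUC
requires. Per-class one-vs-rest AUC itself is computed by the
Mann–Whitney rank statistic (ties credited 0.5), cross-checked in the
tests against both `pROC` and exhaustive concordant-pair counting.

## Tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| `ks` | 2, 3, 4 | feature space grows as $20^k$; k = 5 (3.2M columns) is possible but rarely informative at cohort-scale row counts |
| `zero_fraction_threshold` | 0.95 | keep a feature iff its zero fraction is *strictly* below the threshold; 0.95 removes only near-empty columns |
| `alpha` | 0.05 | ANOVA retention level |
| `train_fraction` | 0.8 | the 4:1 stratified split |
| `cv_folds` | 5 | grid-search folds; reduced automatically (with a warning) when a class is too small |
| `n_perm` | 199 | permutation-test resolution: min p = 1/200 |
| `max_features` | 2000 | cap on selected features, top by F. At k = 4 a null signal alone passes ~5% × 160&#8201;000 = 8&#8201;000 features at α = 0.05; the cap keeps the classifier sweep tractable without touching ranking-based results |
| hyperparameter grids | ≤ 6 points/family | deliberately small so 7 datasets × 7 families runs at desk scale; override per family via `grids` |

## What the generator emulates — and what it does not

`generate_repertoire()` draws CDR3 strings i.i.d. from a background
amino-acid composition with lengths from a configurable distribution
(default uniform on 8–20 residues), then overwrites class-specific
motifs into cells of the non-healthy classes with a configurable
insertion probability. Overwriting, rather than inserting, keeps the
length distribution identical across classes, so the planted signal is
purely compositional — exactly the signal k-mer counting claims to
detect, and nothing else. The benchmark defaults are 3 classes × 30
samples × 200 cells with three 3-mer motifs per non-healthy class at
insertion probability 0.9 — at that effect size the states separate
essentially perfectly, which is what makes it a useful correctness
benchmark rather than a difficulty benchmark.

The generator deliberately omits V(D)J recombination statistics, clonal
expansion (cells are independent, real repertoires are not), somatic
hypermutation, germline-gene-driven positional biases, and batch
effects. Passing the synthetic benchmarks therefore demonstrates that
the pipeline recovers compositional class signal through counting,
filtering, selection and classification — it does not demonstrate that
real repertoires carry such signal, nor that real-data AUCs will match
the benchmark's.

## Numerical and design choices

* **Window semantics.** Overlapping windows with step 1; windows
  containing a non-standard character (X, \*, gaps) are skipped so the
  feature space stays exactly $20^k$; the record itself is kept
  (`strict = TRUE` drops it instead).
* **Aggregation unit.** Rows are (sample × subset) repertoires: disease
  state is a property of a sample, not of a cell. One record per cell
  is counted (no clonotype deduplication by default), so expanded
  clones weigh in proportion to their cell count.
* **Degenerate inputs.** Empty record sets produce a 0-row matrix with
  the full column set; a sample with conflicting state labels is a hard
  error naming the sample; duplicate metadata barcodes are a hard error.
* **Tie-breaks.** Equal macro AUC in the best-model table resolves to
  the simpler family in the fixed order LR < SVM < MLP < KNN < DC < RF
  < XGB; equal CV scores in the grid search keep the earlier grid point.
* **Determinism.** Every stochastic stage takes a seed; permutations
  are drawn before any fit (fits reset the RNG internally); XGB runs
  single-threaded with an explicit seed; no output file contains a
  timestamp. Identical config + seed reproduces every output file
  byte-identically.
* **Fallback.** If fewer than two features pass selection (possible
  under permuted labels), the top ten by F are used so every classifier
  family stays defined; a warning marks the event.

## Problem sizes used in the shipped checks

The validation suite runs the anti-leakage sentinel at 75 samples × 25
cells over 20 seeds, the signal-recovery benchmark at the full 90 × 200
benchmark scale over 10 seeds, and permutation-null uniformity with 50
repeats of a 39-permutation test on 45-row null matrices. These sizes
were chosen so each property is tested with adequate statistical power
while the whole suite stays a desk-scale run.

## Limitations

* ANOVA on counts assumes approximate within-group normality; for
  strongly skewed counts at small n the F-test's nominal calibration
  degrades (the null-calibration test bounds this at benchmark scale).
* The three states are treated as nominal classes; the ordinal
  structure healthy < mild < severe is not exploited.
* Macro AUC on few test samples per class is coarse-grained; the
  permutation p-value, not the point AUC, should carry the inferential
  weight at small n.
* K-mer counting is position- and context-free; motifs that matter only
  at specific CDR3 positions are represented only through their
  composition.
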