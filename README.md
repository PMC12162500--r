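# cdr3kmer

Disease-state classification from the k-mer composition of immune-repertoire
CDR3 sequences.

## What problem this solves

Adaptive immune receptors (TCRs and BCRs) record a person's antigen
exposure, and the CDR3 loop — the most variable part of the antigen-binding
site — shifts in composition with disease state. `cdr3kmer` is for
immunologists and computational biologists who have per-cell CDR3
amino-acid sequences (e.g. from paired single-cell/AIRR experiments,
annotated with cell subset and disease state) and want an
alignment-free, end-to-end answer to: *can this cell subset's repertoire
composition distinguish healthy, mild and severe disease — and which
sequence motifs carry the signal?*

## The method

For a chosen set of k values (default k ∈ {2, 3, 4}):

1. Every CDR3 string is segmented into overlapping k-mers (step-1
   window). Each (sample × cell-subset) repertoire becomes one row of a
   count matrix over the **complete** concatemer space — all 20^k
   columns (400 / 8 000 / 160 000 for k = 2/3/4), with unobserved
   concatemers explicitly 0. Every non-empty combination of the k values
   is a dataset: seven datasets for three k values
   (`kmer2 … kmer2_3_4`).
2. Features are filtered by zero fraction (default: keep iff < 0.95
   zeros), then selected by a per-feature one-way ANOVA F-test of counts
   across states (classes 0/1/2 = healthy/mild/severe), keeping p < 0.05.
   Selection is fitted on the training partition only.
3. Seven classifier families — logistic regression (LR), SVM, multilayer
   perceptron (MLP), k-nearest neighbours (KNN), decision tree (DC),
   random forest (RF), XGBoost (XGB) — are tuned by a small
   cross-validated grid search on a stratified 4:1 split and scored by
   one-vs-rest **macro AUC** (unweighted mean of per-class AUCs, robust
   to class imbalance), with a label-permutation p-value
   p = (1 + #{AUC_perm ≥ AUC_obs}) / (1 + B) that re-runs selection +
   fit inside every permutation.
4. Per dataset, the best significant model is tabulated
   (`kmer, Model, macro_AUC, p_value, H, M, S`), and top-ranked k-mers
   can be intersected across cell subsets to reveal shared CDR3
   structure.

A seeded synthetic-repertoire generator with planted class motifs makes
the whole pipeline testable without any external data; see the methods
vignette (`vignettes/cdr3-kmer-classification.Rmd`) for the model,
defaults and limitations.

## Worked example

A tiny synthetic repertoire (9 samples × 12 cells, planted 3-mer motifs)
ships with the package:

```r
library(cdr3kmer)

rep_path  <- system.file("extdata", "synthetic_repertoire.tsv", package = "cdr3kmer")
meta_path <- system.file("extdata", "synthetic_metadata.csv",  package = "cdr3kmer")

records <- read_repertoire(rep_path, chain = "BCRH")   # AIRR columns: cell_id, locus, junction_aa
records <- join_annotations(records, read.csv(meta_path))

mat <- build_count_matrix(records, ks = 3)
mat
#> kmer_count_matrix: 9 repertoire(s) x 8000 concatemers (k = {3}), 1066 non-zero entries

sel <- anova_select(mat)
sel
#> selection_result: 17 of 8000 features kept (zero-fraction < 0.95, ANOVA p < 0.05, df = 2,6)
head(top_features(sel, n = 5))
#>     feature f_stat rank
#> PHT     PHT 1156.0    1
#> YDY     YDY 1057.0    2
#> GKQ     GKQ  169.0    3
#> DYD     DYD   64.0    4
#> DLW     DLW   30.7    5
```

The top-ranked concatemers are exactly the planted class motifs (PHT,
GKQ for the mild class; YDY, DLW for the severe class; DYD arises from
YDY overlaps) — the selection stage recovers the signal the generator
embedded. An end-to-end run on a larger simulated cohort:

```r
cfg <- run_config(simulate = list(n_samples_per_class = 10, cells_per_sample = 60),
                  ks = c(2, 3), families = c("LR", "RF"), n_perm = 49,
                  quick = TRUE, seed = 7)
res <- run_pipeline(cfg)
res$best
#>      kmer Model macro_AUC p_value H M S significant best_overall subset
#> 1   kmer2    LR         1    0.02 1 1 1        TRUE         TRUE    sim
#> 2   kmer3    LR         1    0.02 1 1 1        TRUE        FALSE    sim
#> 3 kmer2_3    LR         1    0.02 1 1 1        TRUE        FALSE    sim
```

Each row is one k-mer dataset: its best classifier family, test macro
AUC, per-class one-vs-rest AUCs for the healthy (H), mild (M) and severe
(S) states, and the permutation p-value (0.02 is the floor at
B = 49 — the observed AUC beat every permutation). With the strong
default motif signal the states separate perfectly; real repertoires
will not be this clean.

Setting `out_dir` in `run_config()` additionally writes
`results_full.csv`, `best_models.csv`, `roc_points.csv`,
`length_distribution.csv`, selection tables, `shared_kmers.csv` (when
several subsets are analysed) and a `provenance.json` that makes the run
fully reproducible. A thin command-line front end lives at
`inst/cli/cdr3kmer-cli.R` (`simulate`, `run --config file.yaml`,
`shared-kmers`).

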