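# regionboost

Tissue-of-origin (TOO) and cell-of-origin (COO) prediction from somatic
mutation density profiles, with **informative genomic region selection**.

Cancers of unknown primary account for roughly 3% of diagnoses, and the
primary site is the dominant factor guiding treatment.  Whole-genome somatic
mutation density — counts of point mutations in fixed 1 Mbp autosomal
windows — carries a strong tissue signature, because regional mutation rates
track the chromatin organisation and replication timing of the cell a tumor
arose from.  `regionboost` implements that classification pipeline end to
end and, at its core, a resampling procedure that identifies the *small*
subsets of windows that actually carry the signal, so that tens to a few
hundred regions can replace thousands of whole-genome features.

## What it does

* **Window catalogue** (`read_chrom_sizes`, `partition_autosomes`,
  `apply_window_filters`): consecutive 1 Mbp autosomal windows, filtered on
  length-weighted mean mappability (≥ 0.5), GC content (20–80%) and
  exclusion tracks, exported/imported as BED4.
* **Profiles** (`read_variants`, `bin_mutation_density`,
  `bin_chromatin_signal`, `assemble_feature_matrix`): VCF/TSV variants to
  per-sample window count vectors, with SNV filtering, deduplication,
  hypermutant removal (TMB > 10 × cohort median) and chromatin-track
  binning.
* **Classifier** (`fit_model`, `cross_validated_outcomes`, `grid_search`):
  multiclass gradient boosting over symmetric (oblivious) trees minimising
  multinomial cross-entropy,
  `ŷ_m(x) = ŷ_{m−1}(x) + η·h_m(x)` with each tree `h_m` fit to the negative
  gradient `g_i = y_i − p_i`; ordered target encoding for categorical
  covariates; grid search over η ∈ [0.005, 0.5], depth 3–7, 10–100
  iterations with early stopping (tuned defaults η = 0.01, d = 5, M = 30).
* **Informative region selection** (`run_random_subset_trials`,
  `rank_informative_regions`, `sweep_subset_sizes`): repeatedly train on
  random window subsets (default 1,000 repeats per size in
  {25, 50, 100, 150, 200}), record each sample's out-of-fold correctness,
  then flag windows whose inclusion is enriched among correct predictions
  of a cancer type (one-sided Fisher exact test, Benjamini–Hochberg
  q < 0.05 per type), and chart accuracy against subset size (50–600)
  versus random and whole-genome baselines.
  `backward_eliminate_chromatin` prunes chromatin features to a top-20 set
  over 20 rounds of 10-fold cross-validation.
* **Synthetic cohorts** (`generate_cohort`, `write_cohort_files`,
  `generate_chromatin_fixture`): seeded Poisson window counts with planted
  per-class high-density regions and lognormal per-sample exposure, so the
  whole pipeline is testable without access data.

## Worked example

```r
library(regionboost)

cfg <- synthetic_config(samples_per_class = 10, n_windows = 100,
                        planted_per_class = 8, effect_multiplier = 5,
                        seed = 42)
cohort <- generate_cohort(cfg)

sel <- selection_config(subset_sizes = c(15, 25), repeats = 60, folds = 5,
                        seed = 42)
ledger  <- run_random_subset_trials(cohort$fm, sel)
ranking <- rank_informative_regions(ledger, sel)
head(ranking[ranking$class == "ME",
             c("window", "p", "q", "odds_ratio", "significant")])
#>     window        p        q odds_ratio significant
#> 301     69 5.60e-08 5.60e-06       2.93        TRUE
#> 302     78 8.29e-06 4.06e-04       3.00        TRUE
#> 303      4 1.22e-05 4.06e-04       2.64        TRUE
#> 304     98 2.13e-05 5.33e-04       2.46        TRUE
#> 305     51 3.94e-05 7.89e-04       2.50        TRUE
#> 306     34 1.21e-04 2.02e-03       2.36        TRUE
```

Each row is one window scored for the melanoma-like class: `p` is the
one-sided Fisher p-value for enrichment of correct melanoma predictions
among trials that included the window, `q` its BH-adjusted value within the
class, and `odds_ratio` the (continuity-corrected) enrichment strength.
Three of the top six (`w69`, `w78`, `w34`) are windows the generator
actually planted for this class (`w34 w69 w73 w76 w78 w86 w88 w93`); the
rest of the planted set follows further down the ranking.  Retraining on
each class's top 15 windows and comparing with random 15-window subsets:

```r
rbind(
  sweep_subset_sizes(cohort$fm, ranking, sizes = 15, mode = "informative",
                     cfg = sel),
  sweep_subset_sizes(cohort$fm, NULL, sizes = 15, mode = "random",
                     cfg = sel, n_random_draws = 5))
#>           mode size class accuracy
#> 1  informative   15   CRC     1.00
#> 2  informative   15   ESO     0.90
#> 3  informative   15   GBM     0.90
#> 4  informative   15    ME     1.00
#> 5  informative   15    MM     1.00
#> 6  informative   15    RK     1.00
#> 7       random   15   CRC     0.88
#> 8       random   15   ESO     0.64
#> 9       random   15   GBM     0.94
#> 10      random   15    ME     0.88
#> 11      random   15    MM     0.88
#> 12      random   15    RK     0.82
```

Accuracies are per-class out-of-fold rates: 15 selected windows recover
near-perfect classification, while 15 random windows do measurably worse.

A thin command-line wrapper over the same functions ships at
`inst/cli/regionboost` (subcommands `simulate`, `windows`, `profile`,
`select-regions`, `sweep`, `report`).

## Vignette

`vignettes/informative-region-selection.Rmd` describes the model, the
selection statistics and their assumptions, all tunable parameters with
defaults, what the synthetic generator does and does not emulate, and known
limitations.
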