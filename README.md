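# phoptima

Machine-learning prediction of enzyme pH optima from protein sequences,
built around basidiomycete AA1_1 laccases — multi-copper oxidases whose
industrial value depends on whether they work at acidic or alkaline pH.
Characterized alkaline laccases are rare, curated training data are
small (tens of enzymes), and candidate pools mined from fungal genomes
are large (thousands), so the package combines careful small-data
regression with downstream filters rather than a single big model.

## What it does

For a labeled benchmark of mature laccase sequences with experimentally
determined pH optima, `phoptima`:

1. **Featurizes** each sequence: a 25-dimensional composition vector
   (20 residue fractions + 5 side-chain group fractions), theoretical
   molecular weight and isoelectric point (Henderson–Hasselbalch root by
   bisection over the Bjellqvist pKa set), an N-X-[S/T] glycosylation
   sequon flag, coil/helix/strand percentages from ss2 files, a
   phylogenetic leaf branch length, a docking-rank feature, habitat
   one-hots, and substrate-binding residue group counts projected
   through an MSA from a reference structure (residues within 5 Å of the
   ligand). Missing numerics become −1; missing categoricals an all-zero
   block.
2. **Screens** a learner roster (random forest, gradient-boosted trees,
   k-NN, penalized linear, hinge-basis piecewise-linear) at default
   hyperparameters, retaining learners with validation
   RMSE ≤ 1.30 and |RMSE_train − RMSE_val| ≤ 0.30, where
   RMSE = √(Σᵢ(yᵢ − ŷᵢ)²/n).
3. **Tunes** retained learners by nested cross-validation (5 inner /
   3 outer folds, grid search), refits on all data, and draws learning
   curves (20→100% of training data in 2% steps).
4. **Interprets** models by permutation importance (100 repetitions;
   median, 5% and 95% quantiles of the shuffled/baseline RMSE ratio) and
   Monte-Carlo Shapley values (50 permutation draws per instance, local
   accuracy by construction), aggregated to mean |SHAP| and top-20
   feature-type weights.
5. **Selects candidates** from batch predictions: a sequence passes when
   ≥ 3 learners predict pH ≥ 7.0, its minimum cophenetic distance to
   known alkaline laccases lies strictly within (1.1, 1.5), and it is
   closer to alkaline than to neutral references.
6. **Characterizes structures**: Kabsch superposition of paired Cα atoms
   with a 2 Å unaligned threshold, Shrake–Rupley SASA (960 deterministic
   spiral points, 1.4 Å probe), surface residues at 30 Å², and surface
   side-chain group counts.

A synthetic benchmark generator (`generate_benchmark()`) emulates the
curated data — a 55-record acidic/alkaline mixture whose composition
carries a planted linear signal that is exactly true on the emitted
records — so the full pipeline runs and is validated without any
external data. See `vignettes/phoptima-methods.Rmd` for the models,
assumptions and design decisions.

## Worked example

```r
library(phoptima)

bench <- generate_benchmark(synthetic_config(n_records = 55, seed = 7))
bench
#> synthetic laccase benchmark: 55 records (39 acidic, 16 alkaline)
#>   pH range 0.00-11.20; 1 clipped label(s)

split <- benchmark_split(bench$records, validation_size = 5, seed = 7)
raw <- build_raw_features(bench$records, ss2 = bench$ss2,
                          leaf_lengths = leaf_branch_lengths(bench$tree))
features <- encode_feature_table(raw, default_feature_schema())
features
#> feature_table: 55 records x 42 encoded columns
#>   feature types: binding=6, biochemical=4, composition=20,
#>   group_composition=5, host=3, phylogenetic=1, secondary_structure=3

x <- features$matrix
screen_learners(x[split$train$id, ], split$train$ph_optimum,
                x[split$validation$id, ], split$validation$ph_optimum,
                seed = 7)
#> learner screening (val RMSE <= 1.30, |train-val| <= 0.30):
#>  learner rmse_train rmse_val failed selected
#>       rf      0.339    0.397  FALSE     TRUE
#>      gbt      0.016    0.308  FALSE     TRUE
#>      knn      2.298    2.819  FALSE    FALSE
#>   glmnet      0.238    0.434  FALSE     TRUE
#>    hinge      0.261    0.845  FALSE    FALSE

tuned <- nested_cv("glmnet", x, bench$records$ph_optimum, seed = 7)
summary(tuned)
#> learner:         glmnet (penalized linear model)
#> outer-fold RMSE: 0.386, 0.552, 0.340
#> mean outer RMSE: 0.426
#> final hyperparameters:
#>   alpha = 1
#>   lambda = 0.1
```

The screening table says three learners generalize acceptably on this
draw (k-NN suffers from the unscaled feature mix; the hinge learner
overfits the 5-record validation set), and the tuned penalized linear
model predicts held-out pH optima to about 0.43 RMSE — close to the
σ = 0.5 label noise floor of the generator, i.e. near the best
achievable on these data.

The whole stage sequence, with per-stage artifacts, manifests and
resume-on-rerun, is available as
`run_pipeline(pipeline_config(out_dir, seed))`.

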