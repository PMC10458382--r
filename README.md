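# neoseizr

Neonatal EEG seizure detection in R: an end-to-end pipeline from
multi-channel EDF recordings (or a built-in synthetic EEG generator) to a
tuned gradient-boosted seizure/non-seizure classifier, with hyperparameter
search driven by a modified Aquila Optimizer.

## Who this is for

Researchers in biomedical signal processing who want a reproducible,
desk-scale implementation of the windowed-feature + swarm-tuned-classifier
approach to neonatal seizure detection: every stage — preprocessing,
feature extraction, metaheuristic tuning, evaluation — is an exported,
tested function, and the whole pipeline runs offline on synthetic data.

## The method

A recording is cut into 8-second single-channel windows (after
downsampling 256 → 32 Hz, a 0.5 Hz zero-phase high-pass, and per-channel
min-max scaling). A window is labeled ictal when its count of
expert-marked seizure seconds strictly exceeds a threshold VT (default
4 s). Each window is summarized by 15 features — mean, median, variance,
RMS, SD, skewness (Pearson's second coefficient 3(mean − median)/σ),
kurtosis, IQR, Hjorth activity/mobility/complexity, and permutation,
Shannon, approximate and sample entropy.

An XGBoost classifier is tuned over a 7-dimensional box (learning rate,
column subsampling, γ, max depth, row subsampling, min child weight, α) by
minimizing

&nbsp;&nbsp;&nbsp;&nbsp;f(p) = 1 − Accuracy(XGB(p))

on an inner validation split, using the Aquila Optimizer: four
eagle-hunting search steps with greedy replacement. The modified variant
(MAO) replaces the Levy-flight factor of the glide step with an
epoch-decaying, sign-flipping search control factor
2·exp(1 − 0.1 t²/T)·dir, which empirically reaches a given fitness in
fewer epochs than the original (AO). Final models are evaluated on a
held-out stratified 30 % test split: accuracy, AUC, F1, Cohen's kappa,
sensitivity, specificity, ROC.

## Worked example

```r
library(neoseizr)

# 20-minute, 18-channel synthetic recording with six injected seizures
spec <- synthetic_spec(
  n_channels = 18, duration_s = 1200, ictal_amp_ratio = 5,
  seizure_segments = list(c(100, 20), c(280, 15), c(460, 25),
                          c(640, 15), c(820, 30), c(1050, 20)),
  seed = 101)
out <- generate_recording(spec)

ws  <- run_preprocess(out$recording, out$annotation, preprocess_config())
ws
#> <window_set> 2700 windows x 256 samples (8 s @ 32 Hz), 108 seizure-labeled

tab   <- extract_features(ws)
parts <- split_data(tab, split_spec(0.30, seed = 1))

report <- tune_xgb(parts$train,
                   aocfg = ao_config(pop_size = 10, max_iter = 10, seed = 1),
                   inner_split = split_spec(0.2, seed = 1))
model  <- fit_final(parts$train, report$best_hyperparams, seed = 1)

metrics_report(parts$test$label,
               predict_labels(model, parts$test),
               predict_scores(model, parts$test))
#> <metrics_report> n=810 acc=0.9988 auc=1.0000 f1=0.9938 kappa=0.9931 sens=0.9877 spec=1.0000
```

The test accuracy (0.9988) and AUC (1.0) say the six injected 3 Hz
spike-wave bursts are recovered almost perfectly from the 810 held-out
windows; kappa near 1 confirms this is not a majority-class artifact
(ictal windows are only ~4 % of the data).

The optimizer can also be benchmarked directly:

```r
res <- cmd_benchmark_opt(fn = "sphere", dims = 10, pop = 30, T = 250,
                         seeds = 1:20, target_fitness = 1e-2)
res$summary
#>   variant median_epochs_to_target reached n_seeds median_final_fitness
#> 1     MAO                    83.5      20      20         1.688751e-16
#> 2      AO                   122.5      20      20         2.522660e-08
```

A thin command-line front-end (`inst/cli/neoseizr`) wraps the same
functions: `neoseizr synth`, `neoseizr run --config config.yaml`,
`neoseizr benchmark-opt`.

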