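---
title: "Methods: neonatal seizure detection with an Aquila-optimized gradient-boosted classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neonatal seizure detection with an Aquila-optimized gradient-boosted classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the pipeline

Neonatal seizures are electrographic events — sharp, rhythmic EEG activity
sustained for more than about 10 seconds — that are clinically silent often
enough that bedside EEG review by experts is the reference standard.
`neoseizr` implements an automated detector as a windowed binary
classification pipeline:

1. **Ingest** a multi-channel EEG recording (EDF) with per-second binary
   expert annotations (CSV, one column per subject, one row per second), or
   synthesize both.
2. **Preprocess**: keep the EEG channels, downsample 256 Hz to 32 Hz,
   high-pass at 0.5 Hz, min-max scale each channel to [0, 1], cut each
   channel into non-overlapping 8-second windows, and label each window by a
   threshold on the count of seizure-marked seconds inside it.
3. **Features**: summarize every one-dimensional window by 15 features —
   mean, median, population variance, RMS, standard deviation, Pearson's
   second skewness coefficient, moment-ratio kurtosis, interquartile range,
   the three Hjorth parameters, and permutation, Shannon, approximate and
   sample entropy.
4. **Tune**: search a seven-dimensional XGBoost hyperparameter box with a
   population metaheuristic (the Aquila Optimizer, in original and modified
   form), minimizing one minus classification accuracy on an inner
   validation split of the training data.
5. **Evaluate** on a held-out 30 % test split: confusion matrix, accuracy,
   AUC, F1, Cohen's kappa, sensitivity, specificity, ROC points, and a
   model-comparison table against decision-tree, random-forest and
   gradient-boosting baselines.

Each 8-second, single-channel window is an independent classification
sample; the annotation-derived label of a time slot is broadcast to all
channels of that slot. This "sample per channel-window" design multiplies
the training set by the channel count and lets a single-channel model serve
any montage.

## Window labeling and the VT threshold

A window receives label 1 (seizure) iff the number of seizure-marked seconds
inside it *strictly exceeds* a threshold `vt_threshold` (default 4 s, half
an 8-s window). The strict comparison means `vt = 4` requires at least 5
marked seconds. Raising the threshold is label-monotone: it can only turn
labels off, never on — a property the test suite checks. When several
expert tracks are present they are first collapsed by a consensus rule:
`any` (default — a second is ictal if any expert marked it), `majority`, or
`all`. The three rules satisfy the pointwise implication
`all ⇒ majority ⇒ any`.

## Preprocessing choices

- **Stage order** is select → downsample → high-pass → scale → window →
  label. A flag (`filter_before_downsample`) swaps the first two filters for
  users who prefer to high-pass at the acquisition rate.
- **Downsampling** uses a zero-phase order-8 Butterworth anti-alias low-pass
  at 0.8 of the target Nyquist followed by decimation by the integer factor
  (the source rate must be an integer multiple of the target; 256 → 32 Hz is
  a factor of 8).
- **High-pass** is an order-5 Butterworth applied forward-backward
  (zero-phase), preserving spike morphology: no group delay, and the
  effective attenuation is the squared magnitude response. Both filters use
  odd-reflection padding with steady-state initial conditions, so a constant
  signal produces no edge transient and DC is removed essentially exactly.
- **Min-max scaling** is per channel over the whole recording, *not* per
  window: per-window scaling would erase the amplitude contrast between
  ictal and background windows, which is precisely the signal the variance
  features carry. A constant channel is an error by default
  (`constant_channel_zero = TRUE` maps it to zeros instead).
- Windows are non-overlapping by default; `segment_windows()` exposes a
  stride for sliding-window use.

## The 15 features

Two deliberate definitional choices follow the tabulated formulas this
pipeline standardizes on rather than the more common moment conventions:

- **Skewness** is Pearson's second coefficient, `3 (mean − median) / sd`,
  not the third standardized moment. It is 0 for any window whose mean
  equals its median, and defined as 0 (with a warning path) for a constant
  window.
- **Variance** is the population variance (divide by N), so that
  `sd = sqrt(variance)` and Hjorth activity ≡ variance hold exactly as
  identities; kurtosis is the (non-excess) moment ratio
  `N Σ(x−µ)⁴ / (Σ(x−µ)²)²`, which is 3 for a Gaussian and 1.5 for a sine.

**Hjorth mobility** is implemented with the square root,
`sqrt(var(Δx)/var(x))`, the standard dimensionless definition (the
ratio-of-variances reading is available via `hjorth_sqrt = FALSE` in
`feature_config()`); complexity is the mobility of the first difference
over the mobility of the signal.

The entropy features need hyperparameters that are conventional in EEG
work and live in `feature_config()`:

| parameter | default | meaning |
|---|---|---|
| `pe_order`, `pe_delay` | 3, 1 | permutation-entropy embedding (ties broken by position; range [0, ln m!]) |
| `apen_m`, `apen_r_coeff` | 2, 0.2 | ApEn template length and tolerance r = 0.2 × population sd |
| `sampen_m`, `sampen_r_coeff` | 2, 0.2 | SampEn template length and tolerance |
| `shannon_bins` | 16 | equal-width amplitude histogram bins |

ApEn uses Chebyshev distance with self-matches included
(`φ^m − φ^{m+1}`); SampEn excludes self-matches and returns `−ln(A/B)`,
capped at its `ln(N − m)` upper bound (and flagged) when no template pair
matches. Both are O(N²) direct counts implemented in C++; the test suite
holds them to independent naive R implementations at 1e−6 (1e−9 for the
non-entropy features) over batches of seeded random windows.

## The Aquila Optimizer and its modification

The optimizer is a population method with four search steps named after
eagle hunting behavior. With best-so-far solution `S_best`, population mean
`S_M`, a random population member `S_R`, epoch `t` of `T`:

1. *Vertical dive* (expanded exploration):
   `S_best (1 − t/T) + (S_M − S_best r)`.
2. *Glide attack* (narrowed exploration):
   `S_R + F (S_best − S) r (y − x)` with per-dimension spiral coordinates
   `x, y` (constants U = 0.00565, ω = 0.005, r1 = 10).
3. *Search around prey* (expanded exploitation), per dimension j:
   `lb_j + r1 (ub_j − lb_j) + r2 (S_R,j − S_best,j) F (1 − t/T)`.
4. *Walk and grab* (narrowed exploitation):
   `QF S_best − G1 S r − G2 lev(D)`, with quality function
   `QF = t^{(2r−1)/(1−T)²}`, `G1 = 2r − 1`, `G2 = 2(1 − t/T)`, and a
   Mantegna Levy-stable step `lev(D)` (β = 1.5, scale 0.01).

The first `phase_switch` fraction of epochs (default 2/3) uses steps 1–2
with a fair coin per candidate per epoch, the remainder steps 3–4.
Replacement is greedy — a candidate keeps its new position only when the
fitness improves — which guarantees a non-increasing convergence trace.
Positions are hard-clamped to the box after every step.

The **modified variant (MAO, the default)** sets the factor `F` in steps 2
and 3 to the *modified search control factor*

&nbsp;&nbsp;&nbsp;&nbsp;`M-SCF(t) = 2 exp(1 − 0.1 t²/T) · dir`, &nbsp; `dir = +1 if r < 0.5 else −1`,

a sign-flipping factor that starts at magnitude 2e and decays monotonically
with the epoch, narrowing the glide/search range faster than the
Levy-flight factor of the original algorithm. The **original variant
(AO)** uses a Levy-flight vector in step 2 and the classic constant
exploitation factor 0.1 in step 3. The printed form of the decay is
typographically ambiguous; the adopted reading `2 exp(1 − 0.1 t²/T)` is the
one that actually decays with the epoch and starts at 2e, and the
alternative algebraic reading `2 exp(1 − t)(0.1 t/T)` is available behind
`mscf_alt = TRUE`. Likewise the grouping of the step-2/step-3 update
expressions was chosen so the modified formulas reduce to the original
algorithm's structure when `F` is swapped back.

On the 10-D sphere (box ±100, population 30, 250 epochs) the modified
variant reaches 1e−2 in a median of roughly 85 epochs against roughly 120
for the original, and both drive the sphere to ~1e−16; the benchmark
command (`cmd_benchmark_opt()`) reproduces this comparison, which the
acceptance script reports as a directional (logged, not hard-asserted)
check.

Two practical conventions: dimensions flagged `log_mask` are searched in
log10 coordinates (their printed ranges span up to 15 decades; linear
search would be degenerate) and mapped back at decode time; dimensions
flagged `integer_mask` stay continuous during search and are rounded
half-up only when decoded for the learner.

## Hyperparameter tuning

The seven-dimensional search box (bounds exactly as standardized in
`hyperparam_space_xgb()`):

| dimension | bounds | scale |
|---|---|---|
| learning_rate | [1.5e−15, 0.9] | log10 |
| colsample_bytree | [0.001, 1] | linear |
| gamma | [1e−9, 1] | log10 |
| max_depth | [1, 200] | integer |
| subsample | [1, 200] | linear, mapped |
| min_child_weight | [1, 200] | integer |
| alpha | [1e−6, 1] | log10 |

The printed subsample bounds [1, 200] lie outside the learner's valid
(0, 1] row-sampling domain. The decoder divides by 200 and clamps to
[0.005, 1]; `subsample_as_printed = TRUE` passes the raw value through for
anyone who wants the literal behavior. This mapping is the one deliberate
departure from the printed box and is flagged in the decoder
documentation.

The objective is `1 − accuracy` evaluated on an inner 80:20 stratified
validation split of the *training* data — the outer 30 % test split is
never touched during the search (the test suite audits row-index
disjointness). A learner failure scores the worst case 1.0 with a warning
so a pathological corner of the box cannot kill the search. Every
evaluation refits with 50 boosting rounds, single-threaded, making the
whole tuning run bit-reproducible per seed.

The study-scale budget (population 250 × 250 epochs) means ~63,000 model
fits and is hours of compute; `tune_xgb()` therefore defaults to a
desk-scale budget of population 20 × 30 epochs, and the package's own
acceptance runs use population 10 × 10 epochs on a 20-minute synthetic
recording (2,700 windows), which completes in seconds per run while still
demonstrating the tuned-vs-untuned ordering. Pass `ao_config()` unchanged
to restore the 250 × 250 budget.

## Evaluation

Metrics are computed from the confusion matrix with the seizure class
positive: accuracy, sensitivity (= seizure recall), specificity, F1,
Cohen's kappa `(p_o − p_e)/(1 − p_e)`, and rank-based AUC with midranks for
ties (equivalently the Mann-Whitney statistic; invariant under monotone
transforms of the scores). Published figures for this kind of detector
sometimes quote a "sensitivity" that equals accuracy, which is the
micro-averaged recall over both classes; the report therefore carries a
`micro_recall` column (identical to accuracy for single-label binary data)
alongside the standard per-class sensitivity, so both readings are
available. Metrics with zero denominators are reported `NA` and named in
an `undefined` field rather than silently dropped.

## The synthetic generator: what it does and does not emulate

`generate_recording()` produces per-channel pink noise (1/f spectral
shaping of seeded white noise, exponent configurable, background RMS
default 20 µV) and adds, inside each declared seizure segment, a rhythmic
spike-wave train: a 3 Hz fundamental plus sharpened second and third
harmonics, scaled so the burst RMS is `ictal_amp_ratio` (default 5) times
the channel's background RMS, with a half-second raised-cosine taper at
segment edges. Segments must exceed 10 s — shorter rhythmic runs do not
count as electrographic seizures — and the per-second annotation marks
exactly the seconds inside segments. Generation is a pure function of the
spec, seed included.

This emulates the gross statistical signature real detectors rely on —
rhythmicity and amplitude contrast against colored background — and aligned
annotations. It does **not** emulate electrode artifacts, inter-channel
correlation structure and montage geometry, seizure morphology evolution,
expert disagreement (unless `disagreement_rate > 0`), or the heavy class
imbalance of clinical data. Passing the end-to-end tests on synthetic data
therefore demonstrates that the pipeline's plumbing, labeling arithmetic,
tuning and evaluation are correct — not that the classifier reaches any
particular clinical performance. Reproducing published clinical numbers
requires the external neonatal EEG archive and a study-scale tuning run,
for which `cmd_run()` accepts real EDF + CSV inputs unchanged.

## Numerical and degenerate-input conventions

- EDF I/O is 16-bit; physical min/max header fields are 8 ASCII characters,
  rounded *outward* so no sample clips; a write/read round trip is exact to
  the quantization step (range/65535). Signals with heterogeneous sampling
  rates are rejected naming the channels; corrupted or truncated files
  error immediately rather than being skipped.
- Constant windows: skewness 0, ApEn 0, SampEn 0 (all templates match);
  Hjorth parameters are an error (variance 0).
- Permutation-entropy ties break by position (stable order), making the
  feature exactly invariant under strictly monotone transforms.
- The quality-function exponent divides by `(1 − T)²`, so `ao_config()`
  requires `T ≥ 2`.
- All randomness (generator, splits, optimizer, learners) is seeded and
  scoped: no function disturbs the caller's RNG state, and every command
  rerun with the same config produces byte-identical reports.

## Known limitations

- The per-channel-window design cannot express cross-channel features; a
  `--concat-channels`-style mode is a possible extension but is untested.
- Which 3 of 21 channels of a clinical montage are non-EEG is
  recording-specific; channel pruning is driven entirely by user-supplied
  labels.
- The threshold `vt_threshold` and the expert-consensus rule materially
  change the label distribution; both are exposed rather than fixed,
  defaults `4` s and `any`.
- The EDF writer requires integer sampling rates and whole-second
  recordings (one-second records), which covers standard clinical EEG but
  not every physiological format variant.
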