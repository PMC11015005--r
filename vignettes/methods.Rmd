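---
title: "Self-supervised pre-training for wrist accelerometer activity recognition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised pre-training for wrist accelerometer activity recognition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Human activity recognition from wrist-worn tri-axial accelerometers is
label-starved: unlabelled free-living recordings exist at population scale,
while labelled benchmarks have tens of subjects. `harssl` implements a
multi-task self-supervised approach to this asymmetry: a 1D convolutional
encoder is pre-trained, without any human labels, to predict whether each of
three signal transformations was applied to a 10-second window — time
reversal (arrow of time), chunk permutation, and time warping — and is then
fine-tuned on small labelled datasets under a harmonised subject-wise
evaluation protocol.

All signals are in gravitational units (g), linearly resampled to 30 Hz
(above the ~20 Hz Nyquist rate of human movement) and cut into
non-overlapping 10-s windows (300 samples). Gravity is deliberately not
removed: a still wrist shows a constant ~1 g orientation offset, so
*standard deviation*, not mean, distinguishes stillness from movement — the
fact the weighted sampler relies on.

## Pretext tasks and their self-labels

Each enabled task is a binary problem: was the transformation applied?

* **Arrow of time** reverses the window on all three axes simultaneously; it
  is an exact involution.
* **Permutation** cuts the window into 4 chunks of at least 10 samples and
  concatenates them in a shuffled order. Cut points are drawn uniformly over
  all feasible compositions via the spacings construction (compose the slack
  `L - n*min_len` into non-negative parts, add `min_len` back). The identity
  permutation is excluded, so a positive label always corresponds to a
  genuinely shuffled signal — otherwise 1/24 of positives would be
  unlearnable.
* **Time warping** resamples the window along a random monotone time map:
  log-normal local speeds at 6 equally spaced knots (4 interior;
  `tw_sigma = 0.2` by default), cubic-spline interpolated, integrated, and
  endpoint-normalised. `tw_sigma = 0` is the exact identity; outputs are
  linear interpolations and therefore bounded by the per-axis input range.
  The exact warp hyper-parameters used at scale are not published; ours are
  exposed in `transform_config()`.

Batch construction composes the tasks: per window, an orientation
augmentation (random signed axis permutation or uniform 3-D rotation, never
entering the labels) is applied first, then an independent Bernoulli(0.5)
indicator per enabled task decides whether that transformation is applied,
in the fixed order AoT, permutation, time-warp. Independent draws keep every
head's labels balanced and let one forward pass serve all heads. Whether the
original work composed transforms on one window or used separate copies per
task is unstated; the independent-composition choice is ours.

## Movement-weighted sampling

Free-living data is dominated by low-movement periods that the
transformations barely change, so training windows are sampled in proportion
to their standard deviation. The default weight is the mean of the three
per-axis sample standard deviations (invariant under the axis-swap
augmentation); `weight_mode = "magnitude_std"` is the documented
alternative. A batch loads up to 4 subjects, one uniformly drawn calendar
day each, and draws 1500 windows per subject with replacement within that
day — the 4 × 1500 = 6000-window batch. Days with no movement at all
(every weight at or below `weight_floor` = 1e-4 g) fall back to uniform
draws and signal a loggable condition.

## The encoder

The trunk is an 18-layer pre-activation (V2) residual network with 1D
convolutions: stem convolution (3 → w, kernel 5, stride 2), four stages of
two pre-activation blocks with widths (w, 2w, 4w, 8w), stride-2
downsampling and a 1×1 projection shortcut at each stage entry, then batch
norm, ReLU, global average pooling over time, and a linear projection to the
1024-dimensional feature. The published description fixes 18 layers, 10M
parameters and the 1024-d feature but not widths, kernel or downsampling;
our counting convention is stem + 16 block convolutions + feature projection
= 18 (projection shortcuts and batch-norm parameters are not "layers"), and
the base width w = 78 is frozen because it lands the trainable-parameter
count at 9,977,458, which rounds to the 10M budget. `build_encoder()`
refuses configurations outside [9.5M, 10.5M) unless the budget is disabled
for reduced-width experiments. 'Same' zero padding with ceiling semantics
means the input length need not divide the total downsampling factor; the
pooling head absorbs any length.

No deep-learning framework ships with this R installation, so the forward
and backward passes (convolution via im2col in C++, batch normalisation,
ReLU, pooling, linear layers) and the Adam optimiser are implemented in the
package. The backward pass is verified against central-difference numerical
gradients in the test suite (relative error below 1e-6).

Heads: one independent 1024 → 2 softmax readout per pretext task on the
shared feature; downstream, a fully connected layer of 512 units (ReLU)
between the feature extractor and the softmax readout, fixed for all
evaluations.

## Training

Pre-training minimises the unweighted mean over tasks of the per-task mean
cross-entropy (uniform predictions give ln 2 regardless of the task count).
Adam runs at a base rate of 1e-3 linearly scaled by batch size —
`base_lr * batch / 1500`, so the 6000-window batch trains at 4e-3 — with a
five-epoch linear burn-in from the base rate. The reference batch of 1500
(one subject's draw) is our reading of the unstated linear-scaling
reference. Subjects split 8:2 into train/held-out sets (subject-wise, to
prevent leakage; the published split ratio does not say at which
granularity). Early stopping monitors the held-out multi-task loss with a
patience of five epochs; the monitored quantity is our choice, the patience
is not.

Fine-tuning has three regimes: `all_layers` (load trunk, train everything),
`head_only` (freeze the trunk, train the 1024→512→softmax head), and
`scratch` (random initialisation). Early stopping monitors validation
macro-F1, patience 5. A run whose best validation macro-F1 does not exceed
1.1 × the majority-class frequency is deemed unconverged and retried with up
to three seeds, keeping the best validation model; the convergence
definition is ours.

## Evaluation protocol

Datasets with fewer than 10 subjects use held-one-subject-out
cross-validation and drop activity classes not performed by every subject;
datasets with 10 or more use five-fold subject-wise cross-validation. Folds
honour a 7:1:2 train/validation/test ratio at subject granularity. Scores
are computed per test subject — macro-F1 over the classes present in that
subject's truth (avoiding undefined per-class F1), and Cohen's kappa — and
aggregated as unweighted mean ± SD across subjects, pooled across folds.
"Subject-wise F1" is nowhere defined precisely in the source; per-subject
macro-F1 then mean ± SD is our documented reading. Relative improvement is
`100 * (all_layers - scratch) / scratch`, reported to one decimal; the
median over datasets uses the mean-of-central-two convention.

The classical baseline is a random forest on per-window time-series
features (per-axis moments, quartiles and mean absolute deviation,
inter-axis correlations, vector-magnitude moments, dominant frequency and
power, spectral entropy, roll/pitch means). The published feature list lives
in an unavailable supplement; ours is a documented stand-in and a named
extension point. No random-forest package is installed in this environment,
so a compact bagged-CART forest (gini splits, random feature subsets) backs
`rf_baseline()`.

`project_features()` embeds encoder features in 2-D with UMAP (uwot, default
parameters, seeded) and attaches the mean silhouette width by class, so
"better clustering" is a number rather than a picture.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure that motivates the method, not
the biomechanics: per subject and day, long near-stationary segments
(gravity orientation plus white noise, default 2 mg) alternate with activity
bouts under a semi-Markov model with exponential durations; the stationary
mean duration is set so the expected stationary time fraction equals
`stationary_fraction` (default 0.7). Bouts are narrow-band oscillations —
amplitude × envelope × sinusoid — along a direction with a 0.6
gravity-parallel component (vertical impact acceleration; this also keeps
the oscillation fundamental, not just its second harmonic, in the magnitude
spectrum), plus gravity and noise. The default catalogue spans a sawtooth-
envelope 1 Hz "walk" (time-asymmetric, so AoT is learnable), a steady 3 Hz
"run" (narrow-band, so time warping is learnable; the two periodic classes
differ by 2 Hz), and two still postures ("sit", "stand") distinguished by
orientation. A synthetic "day" defaults to one hour: it preserves the
free-living bout/stillness alternation at a desk-scale memory and time
budget (a true 86,400-s day at 30 Hz for a 20-subject cohort would exceed
1 GB).

What a green test on this generator does establish: the sampling, transform,
training and evaluation machinery behave as specified, and the directional
claims (weighted sampling rescues pretext training on stationary-rich data;
pre-training transfers downstream) reproduce. What it does not establish:
absolute accuracy on real benchmarks, robustness to device calibration
error, non-wear, or the diversity of real human movement.

## Desk-scale experiment design

The directional experiments run with a width-4 encoder (~31k parameters),
batches of 4 subjects × 16 windows, base rate 3e-3 referenced to the toy
batch size (the full-scale 1e-3@1500 rule would give vanishing rates at toy
batches), and at most 10 epochs of 20 batches. Two findings shaped the
design, both reproducible with the package:

* With few distinct movement windows the encoder "solves" AoT by memorising
  window templates (training loss near zero, held-out accuracy at or below
  chance). Test cohorts therefore simulate a week of days per subject,
  mirroring week-long wearable deployments, so that generalisation — not
  memorisation — is what the held-out accuracy measures.
* The orientation augmentation, while essential at scale for
  device-invariance, makes single-task AoT unlearnable within a desk-scale
  step budget (the loss sits at ln 2). The directional tests therefore
  pre-train with `augment = FALSE`; the flag defaults to TRUE, keeping the
  full protocol for real use.

The weighted-vs-uniform contrast uses a cohort that is 95% stationary with
sawtooth walk bouts (amplitude 0.5 g) over 0.5 mg device noise, so that
std-proportional mass concentrates on movement windows; uniform sampling
then caps held-out AoT accuracy near 0.5 × 0.95 + 0.05 ≈ 0.53 even for a
perfect detector, which is the chance-level behaviour the contrast asserts.

## Numerical choices and degenerate inputs

* Batch-norm epsilon 1e-5, momentum 0.1; inference uses running statistics,
  which makes `extract_features()` batch-size equivariant to
  floating-point accuracy.
* Probability clamping at 1e-12 in every cross-entropy.
* Windows with constant signal have weight exactly 0; undefined inter-axis
  correlations are imputed 0 in the feature extractor.
* Modal window labels break ties by first-seen order; grids are half-open at
  window boundaries; sample indexing is 0-based in the bundle sidecar
  conventions.
* Mini-batches of size 1 are skipped during supervised epochs (batch norm
  needs at least two rows).

## Known limitations

Single-process determinism is the contract; there is no multi-worker data
loading. The encoder accepts only tri-axial input at the configured window
length. The generator's activities are stylised oscillations — adequate for
testing the learning machinery, not for benchmarking against real human
movement. Layer-wise relevance interpretability and large-scale supervised
transfer baselines are out of scope.
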