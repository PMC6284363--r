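---
title: "Staging epileptic EEG with image volumes and a 3D convolutional network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging epileptic EEG with image volumes and a 3D convolutional network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Scalp EEG of epilepsy patients moves through three electrographic states:
baseline **inter-ictal** activity, a **pre-ictal** period preceding a seizure
(clinically taken here as the hour before onset), and the **ictal** discharge
itself. `ictalcnn` implements a window-level three-class classifier for these
states. Its distinctive step is representational: instead of feeding the raw
multi-channel time series to a recurrent or 1-D convolutional model, each
channel's window is drawn as a square grayscale image and the per-channel
images are stacked into a 3-D volume, so that a convolutional network with
3×3×3 kernels can aggregate information across time, amplitude and
neighbouring electrodes simultaneously.

## Stage labeling and windowing

`label_intervals()` partitions a recording into half-open intervals
`[start, end)`:

* each annotated seizure contributes an ictal interval `[onset, offset)`;
* the `preictal_horizon_s` seconds before each onset (default 3600 s) are
  pre-ictal, clipped at the recording start and truncated by any earlier
  ictal interval — ictal always wins, which matters for patients who seize
  many times per day;
* everything else is inter-ictal. There is no separate post-ictal class:
  samples after an offset revert to inter-ictal, which follows the
  three-state definition at the cost of some immediate post-ictal
  contamination.

`segment_windows()` cuts each interval into consecutive non-overlapping
windows starting at the interval's left edge (the simplest reproducible
alignment): 5 s for ictal intervals, 10 s otherwise (2500 and 5000 samples
at 500 Hz), discarding any trailing remainder. No guard interval is applied
around onsets; a pre-ictal window may abut the seizure directly.

Class imbalance (rare seizures versus abundant background) is handled by
`balance_classes()`: random oversampling with replacement of the minority
stages up to the majority count, seeded for reproducibility. Oversampling
(rather than discarding background) was chosen because the majority class
carries most of the specificity information.

## From waveform to image volume

`series_to_image()` performs three steps:

1. **Min–max normalization** of the window to `[0, 1]`. A constant window
   maps to 0.5. This makes the image invariant to positive affine amplitude
   transforms, so microvolt calibration and per-channel gain cannot leak
   into the classifier.
2. **Rasterization** onto an `n × n` binary grid (`n` = number of samples,
   row 0 at the top): sample *j* becomes pixel
   `(round((n−1)(1−x̂_j)), j)`, and consecutive samples are joined with a
   discrete midpoint-split (Bresenham-style) line so the trace is connected.
   A waveform line-trace is the natural reading of "an image whose
   resolution equals the number of points"; a reshape-style embedding was
   rejected because an `n`-sample series cannot fill an `n × n` grid.
3. **Area averaging** down to `side × side` (default 256) with exact
   fractional-block handling, yielding grayscale values in `[0, 1]` that
   preserve trace density under the ~20× downscaling (nearest-neighbour
   sampling would drop most of the trace). The full-resolution grid is
   never materialized; the C++ rasterizer accumulates block overlaps
   directly, so a 5000×5000 conceptual grid costs memory proportional to
   the output.

Both 2500- and 5000-sample windows pass through their own `n × n` grid and
land on the same `side × side` output, so ictal and non-ictal volumes have
identical shapes.

`build_volume()` stacks the per-channel images along the depth axis in a
fixed channel order. Two orderings are available through
`compute_channel_ordering()`:

* `correlation_chain` (default): a greedy chain over the absolute Pearson
  correlation matrix of a calibration signal — start from the channel with
  the largest total off-diagonal |correlation|, repeatedly append the
  unvisited channel most correlated with the chain end, ties to the lower
  index. The pipeline calibrates on the first inter-ictal minute of each
  recording (per-recording rather than global, since montage quality varies
  by patient; both are deterministic).
* `montage_fixed`: a documented anatomical 10–20 chain (left temporal →
  frontal → central → parietal → occipital → right temporal).

Ordering matters because the 3D kernels span three consecutive depth
planes: adjacent planes should be statistically related for the kernel to
see coherent local structure.

Volumes are stored channel-first `[C, H, W]`; the depth axis (z) is the
EEG channel.

## Architectures

`build_3d_cnn()` produces the declarative stack

| block | layer | width | kernel | stride |
|---|---|---|---|---|
| 1 | Conv3D + norm + LeakyReLU(0.01) | 64 | 3×3×3 | 1 |
| 2 | MaxPool3D | — | 2×2×2 | 2×2×2 |
| 3 | Conv3D + norm + LeakyReLU | 128 | 3×3×3 | 1 |
| 4 | MaxPool3D | — | 2×2×2 | 1×2×2 |
| 5–6 | Conv3D + norm + LeakyReLU (×2, back to back) | 256 | 3×3×3 | 1 |
| 7 | MaxPool3D | — | 2×2×2 | 1×2×2 |
| 8–9 | Dense 4096, Dense 2048 (+ LeakyReLU + dropout 0.5) | | | |
| 10 | Dense 3 + softmax | | | |

Only the first pool strides the depth axis, so channel structure survives
deep into the network; the two back-to-back 256-channel convolutions retain
channel information before the final pool. `build_2d_cnn()` is the
baseline: five Conv2D blocks (32@5×5, then 64/128/256/256@3×3, each with
batch normalization and LeakyReLU), five max-pools (3×3 stride 2 then
2×2 stride 2), Dense 2048 and 1024 with dropout 0.5, softmax. EEG channels
enter the 2D net as image channels, so it sees all electrodes but has no
kernel locality across them.

Choices the source architecture leaves open, fixed here:

* **Padding**: unspecified; `same` is the default (it keeps the documented
  pool-driven shape cascade exact), `valid` is available and both are
  covered by `output_shape()` and the probe-equivalence tests.
* **Dropout on the 3D net's dense layers**: rate unspecified; 0.5 adopted,
  mirroring the 2D net's stated rate.
* **Group count** for group normalization: unspecified; 32 requested, per
  layer reduced to the largest divisor of the width (so reduced-width desk
  configurations degrade gracefully toward instance normalization).
* **Normalization placement**: after the convolution, before the
  activation — the conventional reading of a "Conv + norm + activation"
  block row.
* **Initialization**: He fan-in scaled Gaussians from a seeded generator.

`width_scale` multiplies every width without touching the stack, which is
how the desk-scale experiments shrink the model (1/8 below).

## Group normalization

With batch size 10, batch statistics are noisy; `group_normalize()`
standardizes each sample's channels in contiguous groups over (group
channels × spatial positions), then applies a per-channel affine. Limiting
cases: `groups = 1` standardizes the whole sample, `groups = C` is instance
normalization. The training engine uses a C++ implementation; the exported
R function is an independent implementation used as its cross-check in the
tests (tolerance 1e-5). Batch normalization (with running statistics for
inference) remains available on both architectures.

## Training regimen

`train_network()` minimizes mean cross-entropy with minibatch Adam
(defaults: batch 10, lr 0.01, β₁ = 0.9, β₂ = 0.999, no weight decay),
shuffling with a seeded generator, and returns the parameters of the epoch
with the lowest validation error. The learning-rate schedule has two rules,
replayed statelessly from the validation history by `next_learning_rate()`:

* **plateau rule** — a counter tracks consecutive epochs whose validation
  error improved by less than `plateau_tolerance` (1e-4; "unchanged" is
  operationalized as sub-tolerance improvement because exact float equality
  never occurs). When it reaches 10 the rate is divided by 10 and the
  counter resets. The first epoch opens the run, so a constant validation
  error triggers the first cut when the 10th epoch completes.
* **step rule** — otherwise the rate is divided by 10 after every 40th
  epoch.

The rate never rises and is floored at `min_lr`. One published figure is
arithmetically inconsistent (6000 iterations × batch 10 exceeds the stated
30,000-image training set), so an epoch defaults to one pass over the
training data; `iterations_per_epoch` can override it.

Data protocol: `split_dataset()` makes the 10:1:1 train/validation/test
split first (stratified by stage when labels are supplied; validation and
test rounded down, remainder to train), then `kfold_splits()` /
`cross_validate()` run k-fold CV inside the train+validation pool — the
hold-out-first reading is the only one that reconciles a fixed test set
with 10-fold CV. Early stopping (`early_stop_val_error`, default 0) ends
training on a perfect validation epoch; at desk scale that saves most of
the budget on easy tasks without touching model selection.

## The synthetic generator

The clinical recordings behind the published numbers are not public, so
`generate_recording()` fabricates annotated 22-channel 500 Hz recordings
(both defaults configurable) with three regimes:

* **inter-ictal**: per-channel independent pink (1/f) noise (RMS 20 µV,
  synthesized by spectral shaping, deterministic given the seed) plus a
  10 Hz alpha sine (10 µV, random phase per channel);
* **pre-ictal**: the same background mixed with a common source as
  `√ρ·source + √(1−ρ)·private` (target mean pairwise correlation ρ = 0.6),
  the source carrying Poisson spike-wave transients (0.5 /s, sharp 70 ms
  spike + 200 ms slow wave, ~3× background RMS);
* **ictal**: background plus a shared rhythmic discharge at 4 Hz with
  per-channel phase jitter, scaled so total RMS is `ictal_amp_factor`
  (default 4) times background RMS.

The three knobs — amplitude factor, spike rate, correlation — control task
difficulty. The generator emulates *class structure*, not biology: no
patient-specific seizure morphology, no evolving seizure frequency, no
artifacts, no sleep staging. A passing end-to-end test therefore
demonstrates that the pipeline mechanics (labeling, windowing,
rasterization, ordering, optimization, evaluation) separate controlled
regimes; it says nothing about clinical performance.

## Desk-scale problem sizes

Full-scale training (22×256×256 volumes, widths up to 4096) is a GPU-class
workload; the package's experiments run a reduced configuration chosen as
the package's standard desk protocol: 8 channels at 250 Hz, a 5000 s
recording with eight seizures (250 s pre-ictal horizon) giving exactly 200
windows per stage (600 balanced volumes), 64×64 images, `width_scale = 1/8`,
Adam at 1e-3 (a conventional Adam rate for a small model; the full-scale
default 0.01 remains), batch 10, at most 4 epochs for the 3D net and 2 for
the 2D baseline, early stop on a perfect validation epoch. The split is the
stratified 10:1:1 (500/50/50). `scripts/acceptance.R` re-runs exactly this
protocol from a command-line seed.

## Evaluation

`metrics()` reduces the 3×3 confusion matrix (rows = actual) one-vs-rest
per class: accuracy `(TP+TN)/total`, specificity `TN/(TN+FP)`, sensitivity
`TP/(TP+FN)`, FNR and FPR as complements, reported in percent and rounded
only for display; macro values are unweighted class means. Two published
quirks are handled explicitly rather than silently: the printed accuracy
formula contains an obvious typo (only `(TP+TN)/(TP+TN+FP+FN)` reproduces
every printed accuracy), and the reference table's caption swaps rows and
columns relative to its own layout (the rows-are-actual convention is the
one under which all printed cells check out). `reproduce_tables()`
recomputes every percentage of the reference tables from the embedded
confusion matrices — per-class cells from the matrices, macro rows as means
of the printed per-class cells, which is how they were derived — and flags
the single internally inconsistent cell (the 3D ictal-row specificity,
printed 94.15 where its matrix yields 95.65) instead of reconciling it.

## Known limitations

* Windows are classified independently; there is no event-level (per
  seizure) detection or latency scoring, and no ROC/AUC.
* No filtering, re-referencing or artifact rejection is applied — raw
  signals go straight to rasterization, as in the source protocol.
* The EDF writer emits 16-bit samples; round-trips quantize at half a
  digital step of each channel's physical range.
* The segment/volume container uses R's native serialization with the
  documented per-stage layout (signal, label, start_s, patient_id).
* The from-scratch CNN engine is CPU-only and double-precision; it is
  exact (gradient-checked) but not a performance substitute for a GPU
  framework at full scale.
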