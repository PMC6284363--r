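# ictalcnn

Seizure staging from multi-channel scalp EEG with a 3D-kernel convolutional
network, for researchers studying automatic seizure detection.

Epileptic EEG moves through three electrographic states: baseline
**inter-ictal** activity, the **pre-ictal** hour before a seizure, and the
**ictal** discharge. `ictalcnn` classifies fixed-length EEG windows into
these three classes by recasting signals as images: every channel's window
(5 s ictal / 10 s otherwise, non-overlapping) is min–max normalized, drawn
as a line trace on an amplitude×time grid, area-averaged to a 256×256
grayscale image, and the per-channel images are stacked — ordered by
inter-channel correlation so neighbouring planes are statistically related —
into a `[channels, 256, 256]` volume. A CNN with 3×3×3 kernels (4 conv
blocks of 64/128/256/256 channels with group normalization and LeakyReLU,
3 max-pools that stride the channel axis only once, dense 4096/2048,
softmax) classifies the volume; a conventional 2D CNN (5 conv blocks with
batch normalization, dense 2048/1024) is included as the baseline.
Evaluation is one-vs-rest per class: accuracy (TP+TN)/total, specificity
TN/(TN+FP), sensitivity TP/(TP+FN), FNR/FPR as complements, macro values
as unweighted class means.

The package is self-contained: EDF input/output, a two-column CSV
annotation sidecar (`onset_s`, `offset_s`), a deterministic synthetic EEG
generator with the three regimes (pink-noise + alpha background, correlated
spike-wave pre-ictal activity, high-amplitude rhythmic ictal discharge),
a from-scratch gradient-checked CNN engine (R + C++, convolutions as
im2col/GEMM), Adam with the two-rule learning-rate schedule (plateau cut
after 10 stagnant epochs, otherwise a step cut every 40), stratified
10:1:1 splitting and 10-fold cross-validation.

## Worked example

```r
library(ictalcnn)

# a 5000 s, 8-channel synthetic recording with eight 125 s seizures
cfg <- synthetic_config(n_channels = 8, sampling_rate_hz = 250,
                        duration_s = 5000,
                        seizures = data.frame(onset_s = 250 + 0:7 * 625,
                                              duration_s = 125),
                        preictal_horizon_s = 250, ictal_amp_factor = 4,
                        seed = 1)
rec  <- generate_recording(cfg)
segs <- segment_windows(rec, label_intervals(rec, preictal_horizon_s = 250))
segment_counts(segs)
#> inter_ictal   pre_ictal       ictal
#>         200         200         200

ord  <- compute_channel_ordering(rec$signal[, 1:(60 * 250)])
vols <- build_volumes(segs, ord, side = 64)          # 600 x 8 x 64 x 64
sp   <- split_dataset(600, labels = vols$labels, seed = 2)

spec <- build_3d_cnn(input_shape = c(8, 64, 64), width_scale = 1/8)
fit  <- train_network(spec,
                      vols$volumes[sp$train, , , ], vols$labels[sp$train],
                      vols$volumes[sp$validation, , , ], vols$labels[sp$validation],
                      train_config(epochs = 4, lr0 = 1e-3, seed = 3))
pred <- predict_stage(fit$net, vols$volumes[sp$test, , , ])
metrics(confusion_matrix(vols$labels[sp$test], pred))
```

The metric report prints one row per stage plus a macro row, e.g. a
perfectly separated test set shows sensitivity/specificity 100 and FNR/FPR
0 for every stage; the held-out macro accuracy is the headline number of
the desk-scale experiment.

Reference results ship with the package: `published_tables()` returns the
three published test-set confusion matrices (1000 actual windows per
stage) and their printed percentages, and `reproduce_tables()` recomputes
every derived cell, flagging the single internally inconsistent one (the
3D ictal-row specificity).

```r
print(reproduce_tables())
#> ... 38/39 cells reproduced
```

A command-line entry point covering the same pipeline is installed at
`inst/cli/ictalcnn.R` with subcommands `simulate`, `preprocess`, `train`,
`evaluate`, `reproduce-tables`.

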