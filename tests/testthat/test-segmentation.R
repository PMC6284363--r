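test_that("stage intervals follow the horizon/priority rules", {
  rec <- tiny_recording(dur = 3600, fs = 1,
                        seizures = data.frame(onset_s = 3000, offset_s = 3060))
  iv <- label_intervals(rec, preictal_horizon_s = 3600)
  expect_equal(iv$label, c("pre_ictal", "ictal", "inter_ictal"))
  expect_equal(iv$start_s, c(0, 3000, 3060))
  expect_equal(iv$end_s, c(3000, 3060, 3600))

  # no annotations: single inter-ictal interval
  iv0 <- label_intervals(tiny_recording(dur = 100, fs = 1))
  expect_equal(iv0, data.frame(start_s = 0, end_s = 100, label = "inter_ictal"))

  # an earlier seizure truncates the next pre-ictal interval
  rec2 <- tiny_recording(dur = 400, fs = 1, seizures = data.frame(
    onset_s = c(100, 200), offset_s = c(160, 260)))
  iv2 <- label_intervals(rec2, preictal_horizon_s = 3600)
  expect_equal(iv2$label, c("pre_ictal", "ictal", "pre_ictal", "ictal", "inter_ictal"))
  expect_equal(iv2$start_s[3], 160)
  expect_equal(iv2$end_s[3], 200)
  # intervals always partition [0, duration)
  expect_equal(iv2$start_s[-1], head(iv2$end_s, -1))
  expect_equal(iv2$start_s[1], 0)
  expect_equal(iv2$end_s[nrow(iv2)], 400)
})

test_that("interval labeling is invariant to annotation order", {
  ann <- data.frame(onset_s = c(300, 100), offset_s = c(340, 130))
  r1 <- tiny_recording(dur = 500, fs = 1, seizures = ann)
  r2 <- tiny_recording(dur = 500, fs = 1, seizures = ann[2:1, ])
  expect_equal(label_intervals(r1, 50), label_intervals(r2, 50))
})

test_that("window extraction matches per-interval floor arithmetic", {
  fs <- 500
  rec <- tiny_recording(dur = 3600, fs = fs, n_channels = 2,
                        seizures = data.frame(onset_s = 3000, offset_s = 3060))
  iv <- label_intervals(rec, 3600)
  segs <- segment_windows(rec, iv)
  counts <- segment_counts(segs)
  expect_equal(unname(counts), c(54L, 300L, 12L))  # inter, pre, ictal
  expect_equal(length(segs), 366L)
  # window lengths: 2500 points ictal, 5000 otherwise at 500 Hz
  for (s in segs[c(1, 301, 320)]) {
    expect_equal(ncol(s$signal), if (s$label == "ictal") 2500 else 5000)
    expect_equal(nrow(s$signal), 2)
  }
  # windows never straddle an interval boundary and never overlap
  starts <- vapply(segs, function(s) s$start_s, 0)
  lens <- vapply(segs, function(s) ncol(s$signal) / fs, 0)
  for (i in seq_along(segs)) {
    k <- which(iv$start_s <= starts[i] & starts[i] < iv$end_s)
    expect_lte(starts[i] + lens[i], iv$end_s[k])
    expect_equal(iv$label[k], segs[[i]]$label)
  }
  ord <- order(starts)
  expect_true(all(starts[ord][-1] - (starts[ord] + lens[ord])[-length(segs)] > -1e-9))
})

test_that("short intervals yield the floor number of windows, down to zero", {
  rec <- tiny_recording(dur = 12, fs = 100)
  segs <- segment_windows(rec, label_intervals(rec))
  expect_equal(length(segs), 1)
  expect_equal(ncol(segs[[1]]$signal), 1000)

  rec2 <- tiny_recording(dur = 10, fs = 100,
                         seizures = data.frame(onset_s = 3, offset_s = 7))
  iv2 <- label_intervals(rec2, preictal_horizon_s = 3)
  segs2 <- segment_windows(rec2, iv2)
  expect_equal(sum(vapply(segs2, function(s) s$label == "ictal", TRUE)), 0)
})

test_that("oversampling balances classes, keeps originals, and is seed-reproducible", {
  rec <- tiny_recording(dur = 1200, fs = 20, seizures = data.frame(
    onset_s = 1000, offset_s = 1050))
  segs <- segment_windows(rec, label_intervals(rec, preictal_horizon_s = 200))
  counts <- segment_counts(segs)
  expect_true(length(unique(counts)) > 1)
  bal <- balance_classes(segs, seed = 9)
  expect_equal(unname(segment_counts(bal)), rep(max(counts), 3))
  # originals retained as a prefix
  expect_identical(bal[seq_along(segs)], segs)
  bal2 <- balance_classes(segs, seed = 9)
  expect_identical(vapply(bal2, function(s) s$start_s, 0),
                   vapply(bal, function(s) s$start_s, 0))
  # already balanced input comes back unchanged
  even <- rep(segs[1:3], 1)
  even[[2]]$label <- "pre_ictal"; even[[3]]$label <- "ictal"
  expect_equal(length(balance_classes(even, 1)), 3)
  # a missing class is an error naming the class
  expect_error(balance_classes(segs[vapply(segs, function(s)
    s$label != "ictal", TRUE)], 1), "ictal")
})
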