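# Stage labeling and non-overlapping window extraction. Intervals are
# half-open [start_s, end_s) and partition [0, duration); priority is
# ictal > pre-ictal > inter-ictal.

#' One labeled, fixed-length multi-channel window
#'
#' The unit of classification: a `n_channels x n_points` slice of a
#' recording with its stage label and provenance.
#'
#' @param signal numeric matrix `n_channels x n_points`, finite.
#' @param label one of [stage_levels()].
#' @param start_s window start in seconds from recording start.
#' @param patient_id provenance identifier.
#' @return A `window_segment` object.
#' @export
window_segment <- function(signal, label, start_s, patient_id = "P00") {
  if (!is.matrix(signal) || !all(is.finite(signal))) {
    stop("window signal must be a finite numeric matrix")
  }
  if (!label %in% stage_levels()) stop("unknown stage label: ", label)
  structure(list(signal = signal, label = label, start_s = start_s,
                 patient_id = patient_id), class = "window_segment")
}

#' Label a recording into inter-ictal / pre-ictal / ictal intervals
#'
#' Each seizure contributes an ictal interval `[onset, offset)` and a
#' pre-ictal interval covering the `preictal_horizon_s` seconds before its
#' onset, clipped to the recording start and truncated by any earlier ictal
#' interval (ictal takes priority). Everything else is inter-ictal. The
#' returned intervals are disjoint, sorted, and partition `[0, duration)`.
#'
#' @param recording an [eeg_recording()].
#' @param preictal_horizon_s pre-ictal horizon in seconds (clinical
#'   convention: 3600).
#' @return Data frame with columns `start_s`, `end_s`, `label`.
#' @export
label_intervals <- function(recording, preictal_horizon_s = 3600) {
  dur <- recording_duration(recording)
  ann <- recording$annotations
  n <- nrow(ann)
  if (n == 0) {
    return(data.frame(start_s = 0, end_s = dur, label = "inter_ictal",
                      stringsAsFactors = FALSE))
  }
  ann <- ann[order(ann$onset_s), , drop = FALSE]
  pieces <- list()
  for (i in seq_len(n)) {
    pre_start <- max(0, ann$onset_s[i] - preictal_horizon_s)
    if (i > 1) pre_start <- max(pre_start, ann$offset_s[i - 1])
    if (pre_start < ann$onset_s[i]) {
      pieces[[length(pieces) + 1]] <- c(pre_start, ann$onset_s[i], 1)
    }
    pieces[[length(pieces) + 1]] <- c(ann$onset_s[i], min(ann$offset_s[i], dur), 2)
  }
  m <- do.call(rbind, pieces)
  # fill gaps with inter-ictal
  out <- list()
  cursor <- 0
  for (r in seq_len(nrow(m))) {
    if (m[r, 1] > cursor) out[[length(out) + 1]] <- c(cursor, m[r, 1], 0)
    out[[length(out) + 1]] <- m[r, ]
    cursor <- m[r, 2]
  }
  if (cursor < dur) out[[length(out) + 1]] <- c(cursor, dur, 0)
  res <- do.call(rbind, out)
  data.frame(start_s = res[, 1], end_s = res[, 2],
             label = stage_levels()[res[, 3] + 1], stringsAsFactors = FALSE)
}

#' Cut labeled intervals into non-overlapping fixed-length windows
#'
#' Within each interval, consecutive windows of the stage's length start at
#' the interval's left edge; a trailing remainder shorter than one window is
#' discarded. Ictal windows are 5 s (2500 points at 500 Hz) and all other
#' stages 10 s, following the convention that seizure discharge is stable
#' over shorter spans than background activity.
#'
#' @param recording an [eeg_recording()].
#' @param intervals output of [label_intervals()].
#' @param ictal_window_s ictal window length, seconds.
#' @param other_window_s pre-ictal / inter-ictal window length, seconds.
#' @return List of [window_segment()]s in temporal order.
#' @export
segment_windows <- function(recording, intervals, ictal_window_s = 5,
                            other_window_s = 10) {
  fs <- recording$sampling_rate_hz
  out <- list()
  for (r in seq_len(nrow(intervals))) {
    lab <- intervals$label[r]
    win_s <- if (lab == "ictal") ictal_window_s else other_window_s
    n_pts <- round(win_s * fs)
    n_win <- floor((intervals$end_s[r] - intervals$start_s[r]) / win_s)
    if (n_win < 1) next
    for (w in seq_len(n_win)) {
      t0 <- intervals$start_s[r] + (w - 1) * win_s
      i0 <- round(t0 * fs)
      if (i0 + n_pts > ncol(recording$signal)) break
      out[[length(out) + 1]] <- window_segment(
        recording$signal[, (i0 + 1):(i0 + n_pts), drop = FALSE],
        lab, t0, recording$patient_id)
    }
  }
  out
}

#' Count segments per stage
#' @param segments list of [window_segment()]s.
#' @return Named integer vector over [stage_levels()].
#' @export
segment_counts <- function(segments) {
  labs <- vapply(segments, function(s) s$label, "")
  vapply(stage_levels(), function(l) sum(labs == l), 0L)
}

#' Balance class counts by random oversampling
#'
#' Minority stages are oversampled with replacement until all three stage
#' counts equal the majority count. All original segments are retained;
#' duplicates are sampled with a seeded generator, so the result is
#' reproducible.
#'
#' @param segments list of [window_segment()]s covering all three stages.
#' @param seed integer seed for the resampling.
#' @return List of segments with equal per-stage counts.
#' @export
balance_classes <- function(segments, seed = 1L) {
  counts <- segment_counts(segments)
  empty <- names(counts)[counts == 0]
  if (length(empty) > 0) {
    stop("cannot balance: no segments for stage(s) ", paste(empty, collapse = ", "))
  }
  target <- max(counts)
  labs <- vapply(segments, function(s) s$label, "")
  extra <- with_seed(seed, {
    idx <- integer(0)
    for (lev in stage_levels()) {
      need <- target - counts[[lev]]
      if (need > 0) idx <- c(idx, sample(which(labs == lev), need, replace = TRUE))
    }
    idx
  })
  c(segments, segments[extra])
}
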