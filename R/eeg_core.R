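#' @useDynLib ictalcnn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor rnorm runif fft
#' @importFrom utils read.csv write.csv head
NULL

#' Electrographic stage labels
#'
#' The three brain states the classifier separates, in their canonical
#' serialization order: `inter_ictal` (0), `pre_ictal` (1), `ictal` (2).
#'
#' @return Character vector of the three stage names, in order.
#' @export
stage_levels <- function() c("inter_ictal", "pre_ictal", "ictal")

#' @rdname stage_levels
#' @param x character vector of stage names.
#' @return `stage_factor()`: a factor over the three ordered levels.
#' @export
stage_factor <- function(x) {
  bad <- setdiff(unique(x), stage_levels())
  if (length(bad) > 0) {
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  }
  factor(x, levels = stage_levels())
}

validate_annotations <- function(annotations, duration_s) {
  if (is.null(annotations) || nrow(annotations) == 0) {
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0)))
  }
  if (!all(c("onset_s", "offset_s") %in% names(annotations))) {
    stop("annotations need columns onset_s and offset_s")
  }
  ann <- annotations[, c("onset_s", "offset_s")]
  for (i in seq_len(nrow(ann))) {
    on <- ann$onset_s[i]; off <- ann$offset_s[i]
    if (!is.finite(on) || !is.finite(off) || on < 0 || on >= off || off > duration_s) {
      stop(sprintf(
        "annotation row %d (onset %.3f, offset %.3f) violates 0 <= onset < offset <= %.3f",
        i, on, off, duration_s))
    }
  }
  ann <- ann[order(ann$onset_s), , drop = FALSE]
  rownames(ann) <- NULL
  if (nrow(ann) > 1 && any(ann$onset_s[-1] < ann$offset_s[-nrow(ann)])) {
    stop("seizure annotations overlap")
  }
  ann
}

#' Construct an annotated multi-channel EEG recording
#'
#' The core container of the pipeline: a channels-by-samples signal matrix in
#' microvolts plus sampling rate, montage labels and seizure annotations.
#' Annotations are validated (within the recording, non-overlapping) and
#' sorted by onset.
#'
#' @param signal numeric matrix, `n_channels x n_samples`, microvolts.
#' @param sampling_rate_hz samples per second (> 0).
#' @param channel_names character vector of montage labels, one per row of
#'   `signal`. Defaults to the standard 10-20 chain (see [montage_chain()]).
#' @param annotations data frame with columns `onset_s`, `offset_s` (seconds
#'   from recording start), one row per seizure; may be `NULL`.
#' @param patient_id identifier string carried through to windows and volumes.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, sampling_rate_hz,
                          channel_names = montage_chain(nrow(signal)),
                          annotations = NULL, patient_id = "P00") {
  if (!is.matrix(signal) || !is.numeric(signal)) stop("signal must be a numeric matrix")
  if (nrow(signal) < 1) stop("at least one channel required")
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be positive")
  }
  if (length(channel_names) != nrow(signal)) {
    stop("channel_names length must equal the number of signal rows")
  }
  duration_s <- ncol(signal) / sampling_rate_hz
  ann <- validate_annotations(annotations, duration_s)
  structure(list(
    patient_id = patient_id,
    channel_names = as.character(channel_names),
    sampling_rate_hz = sampling_rate_hz,
    signal = signal,
    annotations = ann
  ), class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> patient %s: %d channels x %d samples @ %g Hz (%.1f s), %d seizure(s)\n",
              x$patient_id, nrow(x$signal), ncol(x$signal), x$sampling_rate_hz,
              ncol(x$signal) / x$sampling_rate_hz, nrow(x$annotations)))
  invisible(x)
}

#' Recording duration in seconds
#' @param recording an [eeg_recording()].
#' @return duration in seconds.
#' @export
recording_duration <- function(recording) {
  ncol(recording$signal) / recording$sampling_rate_hz
}

pad_str <- function(s, width) {
  s <- substr(s, 1, width)
  formatC(s, width = width, flag = "-")
}

num_field <- function(x, width) {
  s <- formatC(x, format = "fg", width = -1)
  if (nchar(s) > width) s <- substr(formatC(x, format = "g", digits = width - 6), 1, width)
  pad_str(s, width)
}

#' Write a recording to EDF (with optional CSV annotation sidecar)
#'
#' Writes standard 16-bit EDF with one-second data records; each channel is
#' scaled to its own physical range. The recording length must be a whole
#' number of seconds. Seizure annotations go to a two-column CSV sidecar
#' (`onset_s`, `offset_s`) when `annotation_path` is given.
#'
#' @param recording an [eeg_recording()].
#' @param path output EDF file path.
#' @param annotation_path optional CSV sidecar path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, annotation_path = NULL) {
  sig <- recording$signal
  fs <- recording$sampling_rate_hz
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- ncol(sig)
  if (ns %% fs != 0) stop("EDF writer requires a whole number of 1-s records")
  n_rec <- ns %/% fs
  n_sig <- nrow(sig)

  # physical limits widened outward to one decimal so the 8-character EDF
  # header fields represent them exactly
  pmin <- floor(apply(sig, 1, min) * 10) / 10 - 0.1
  pmax <- ceiling(apply(sig, 1, max) * 10) / 10 + 0.1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_str("0", 8),
    pad_str(recording$patient_id, 80),
    pad_str("ictalcnn", 80),
    pad_str("01.01.00", 8), pad_str("00.00.00", 8),
    num_field(256L * (1L + n_sig), 8),
    pad_str("", 44),
    num_field(n_rec, 8),
    num_field(1, 8),
    num_field(n_sig, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    vapply(recording$channel_names, pad_str, "", width = 16),
    rep(pad_str("", 80), n_sig),
    rep(pad_str("uV", 8), n_sig),
    vapply(pmin, num_field, "", width = 8),
    vapply(pmax, num_field, "", width = 8),
    rep(num_field(dmin, 8), n_sig),
    rep(num_field(dmax, 8), n_sig),
    rep(pad_str("", 80), n_sig),
    rep(num_field(fs, 8), n_sig),
    rep(pad_str("", 32), n_sig))
  for (f in fields) writeChar(paste0(f, collapse = ""), con, eos = NULL)

  # re-read the physical ranges exactly as a reader will parse them, so the
  # digital conversion is consistent to full double precision
  pmin_r <- as.numeric(vapply(pmin, num_field, "", width = 8))
  pmax_r <- as.numeric(vapply(pmax, num_field, "", width = 8))
  scale <- (dmax - dmin) / (pmax_r - pmin_r)
  dig <- round((sig - pmin_r) * scale + dmin)
  dig[dig < dmin] <- dmin; dig[dig > dmax] <- dmax
  storage.mode(dig) <- "integer"
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2, endian = "little")
  }
  if (!is.null(annotation_path)) {
    write_annotations(recording$annotations, annotation_path)
  }
  invisible(path)
}

#' @rdname write_edf
#' @param annotations data frame with `onset_s`, `offset_s`.
#' @export
write_annotations <- function(annotations, path) {
  write.csv(annotations[, c("onset_s", "offset_s")], path, row.names = FALSE)
  invisible(path)
}

read_header_field <- function(con, width) {
  trimws(readChar(con, width, useBytes = TRUE))
}

#' Read an EDF recording (with optional annotation sidecar)
#'
#' Parses standard 16-bit EDF: header, per-signal headers, then data records,
#' converting digital values back to physical units. All signals must share
#' one sampling rate. If `annotation_path` is given, seizure onsets/offsets
#' are read from the two-column CSV sidecar and validated against the
#' recording duration (a row outside the recording is an error naming the row).
#'
#' @param path EDF file path.
#' @param annotation_path optional CSV sidecar with `onset_s`, `offset_s`.
#' @param patient_id overrides the patient field stored in the file header.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, annotation_path = NULL, patient_id = NULL) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_header_field(con, 8)
  if (version != "0") stop("not an EDF file (version field '", version, "'): ", path)
  pid <- read_header_field(con, 80)
  read_header_field(con, 80)  # recording id
  read_header_field(con, 8); read_header_field(con, 8)  # date, time
  hdr_bytes <- as.integer(read_header_field(con, 8))
  read_header_field(con, 44)
  n_rec <- as.integer(read_header_field(con, 8))
  rec_dur <- as.numeric(read_header_field(con, 8))
  n_sig <- as.integer(read_header_field(con, 4))
  if (is.na(n_sig) || n_sig < 1 || is.na(n_rec) || n_rec < 1 || is.na(rec_dur) || rec_dur <= 0) {
    stop("invalid EDF header in ", path)
  }
  labels <- vapply(seq_len(n_sig), function(i) read_header_field(con, 16), "")
  for (i in seq_len(n_sig)) read_header_field(con, 80)  # transducer
  for (i in seq_len(n_sig)) read_header_field(con, 8)   # phys dim
  pmin <- vapply(seq_len(n_sig), function(i) as.numeric(read_header_field(con, 8)), 0)
  pmax <- vapply(seq_len(n_sig), function(i) as.numeric(read_header_field(con, 8)), 0)
  dmin <- vapply(seq_len(n_sig), function(i) as.numeric(read_header_field(con, 8)), 0)
  dmax <- vapply(seq_len(n_sig), function(i) as.numeric(read_header_field(con, 8)), 0)
  for (i in seq_len(n_sig)) read_header_field(con, 80)  # prefiltering
  spr <- vapply(seq_len(n_sig), function(i) as.integer(read_header_field(con, 8)), 0L)
  for (i in seq_len(n_sig)) read_header_field(con, 32)
  if (any(is.na(pmin)) || any(is.na(spr)) || any(spr < 1)) stop("invalid EDF signal headers in ", path)
  if (length(unique(spr)) != 1) stop("EDF signals with mixed sampling rates are not supported")
  seek(con, hdr_bytes)
  total <- sum(spr) * n_rec
  raw16 <- readBin(con, "integer", n = total, size = 2, endian = "little", signed = TRUE)
  if (length(raw16) < total) stop("EDF data truncated in ", path)
  fs <- spr[1] / rec_dur
  sig <- matrix(0, n_sig, spr[1] * n_rec)
  scale <- (pmax - pmin) / (dmax - dmin)
  pos <- 0L
  for (r in seq_len(n_rec)) {
    for (s in seq_len(n_sig)) {
      chunk <- raw16[(pos + 1):(pos + spr[s])]
      sig[s, ((r - 1) * spr[s] + 1):(r * spr[s])] <- (chunk - dmin[s]) * scale[s] + pmin[s]
      pos <- pos + spr[s]
    }
  }
  ann <- NULL
  if (!is.null(annotation_path)) ann <- read_annotations(annotation_path)
  eeg_recording(sig, fs, channel_names = labels, annotations = ann,
                patient_id = if (is.null(patient_id)) pid else patient_id)
}

#' @rdname read_edf
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ann <- read.csv(path)
  if (!all(c("onset_s", "offset_s") %in% names(ann))) {
    stop("annotation CSV needs columns onset_s and offset_s: ", path)
  }
  ann[, c("onset_s", "offset_s")]
}

#' Persist labeled windows / image volumes
#'
#' A dataset container with one group per stage, each holding the stacked
#' signal arrays plus `label`, `start_s` and `patient_id` provenance. The
#' round trip is lossless. `save_volumes()`/`load_volumes()` use the same
#' layout for rasterized `[C x H x W]` volumes.
#'
#' @param segments list of [window_segment()] objects (possibly empty).
#' @param path output file path.
#' @return `path` invisibly; `load_segments()` returns the list of segments.
#' @export
save_segments <- function(segments, path) {
  groups <- list()
  for (lev in stage_levels()) {
    sel <- segments[vapply(segments, function(s) s$label == lev, TRUE)]
    if (length(sel) == 0) { groups[[lev]] <- NULL; next }
    groups[[lev]] <- list(
      signal = lapply(sel, function(s) s$signal),
      label = lev,
      start_s = vapply(sel, function(s) s$start_s, 0),
      patient_id = vapply(sel, function(s) s$patient_id, ""))
  }
  saveRDS(list(format = "ictalcnn-segments-v1", groups = groups), path)
  invisible(path)
}

#' @rdname save_segments
#' @export
load_segments <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("corrupt or unreadable segment container: ", path)
  })
  if (!is.list(obj) || !identical(obj$format, "ictalcnn-segments-v1")) {
    stop("not an ictalcnn segment container: ", path)
  }
  out <- list()
  for (lev in stage_levels()) {
    g <- obj$groups[[lev]]
    if (is.null(g)) next
    for (i in seq_along(g$signal)) {
      out[[length(out) + 1]] <- window_segment(g$signal[[i]], lev,
                                               g$start_s[i], g$patient_id[i])
    }
  }
  out
}

#' @rdname save_segments
#' @param volumes array `[N x C x H x W]` (or a list of `image_volume`s).
#' @param labels character stage labels, length N.
#' @param provenance data frame with `patient_id`, `start_s`, length N.
#' @export
save_volumes <- function(volumes, labels, provenance, path) {
  if (is.list(volumes) && !is.array(volumes)) {
    arr <- array(0, c(length(volumes), dim(volumes[[1]]$data)))
    for (i in seq_along(volumes)) arr[i, , , ] <- volumes[[i]]$data
    labels <- vapply(volumes, function(v) v$label, "")
    provenance <- data.frame(
      patient_id = vapply(volumes, function(v) v$patient_id, ""),
      start_s = vapply(volumes, function(v) v$start_s, 0))
    volumes <- arr
  }
  stopifnot(length(labels) == dim(volumes)[1], nrow(provenance) == dim(volumes)[1])
  saveRDS(list(format = "ictalcnn-volumes-v1", volumes = volumes,
               labels = labels, provenance = provenance), path)
  invisible(path)
}

#' @rdname save_segments
#' @export
load_volumes <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("corrupt or unreadable volume container: ", path)
  })
  if (!is.list(obj) || !identical(obj$format, "ictalcnn-volumes-v1")) {
    stop("not an ictalcnn volume container: ", path)
  }
  obj[c("volumes", "labels", "provenance")]
}
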