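# Time-series-to-image rasterization and 3D volume assembly. A window's
# waveform is drawn as a line trace on an n x n amplitude-by-time pixel grid
# (n = number of samples) and area-averaged down to side x side grayscale,
# so both 2500- and 5000-point windows yield volumes of identical shape.

#' Standard 10-20 montage chain
#'
#' A fixed anatomical ordering of scalp electrodes running left temporal ->
#' left frontal -> midline/right frontal -> central -> parietal ->
#' occipital -> right temporal, so that adjacent entries are spatial
#' neighbors on the scalp. Used both as default channel naming and as the
#' `montage_fixed` channel ordering.
#'
#' @param n number of channels; beyond the 22 standard labels, synthetic
#'   `EXTk` labels are appended.
#' @return Character vector of `n` electrode labels.
#' @export
montage_chain <- function(n = 22) {
  chain <- c("A1", "T3", "T5", "F7", "Fp1", "F3", "Fz", "F4", "Fp2", "F8",
             "C3", "Cz", "C4", "P3", "Pz", "P4", "O1", "Oz", "O2", "T6",
             "T4", "A2")
  if (n <= length(chain)) chain[seq_len(n)]
  else c(chain, sprintf("EXT%d", seq_len(n - length(chain))))
}

#' Rasterize a time series into a square grayscale image
#'
#' Three steps: (1) min-max normalize the series to `[0, 1]` (a constant
#' series maps to 0.5 everywhere), making the image invariant to positive
#' affine amplitude transforms; (2) draw the waveform on an `n x n` binary
#' grid -- sample j becomes the pixel `(round((n-1)(1-x_j)), j)` with row 0
#' at the top, and consecutive samples are joined by a discrete
#' (Bresenham-style midpoint-split) line so the trace is connected; (3)
#' area-average the grid down to `side x side`, with fractional block
#' boundaries handled exactly. The full-resolution grid is never
#' materialized.
#'
#' @param x numeric vector, length >= 2, finite.
#' @param side output image side in pixels (>= 2).
#' @return `side x side` matrix in `[0, 1]`.
#' @export
series_to_image <- function(x, side = 256) {
  n <- length(x)
  if (n < 2) stop("series must have at least 2 samples")
  if (side < 2) stop("side must be >= 2")
  if (!all(is.finite(x))) stop("series contains non-finite values")
  rng <- range(x)
  xhat <- if (rng[2] - rng[1] < .Machine$double.eps * max(abs(rng), 1)) {
    rep(0.5, n)
  } else (x - rng[1]) / (rng[2] - rng[1])
  ypix <- as.integer(round((n - 1) * (1 - xhat)))
  rasterize_trace(ypix, as.integer(side))
}

#' Greedy correlation-chain channel order
#'
#' Given a channel correlation matrix, starts from the channel with the
#' largest total absolute off-diagonal correlation and repeatedly appends
#' the unvisited channel most correlated (in absolute value) with the
#' current chain end; ties go to the smaller channel index. Exposed
#' separately from [compute_channel_ordering()] so the greedy rule can be
#' checked directly against exhaustive evaluation.
#'
#' @param cormat square correlation matrix.
#' @return Integer permutation (1-based) of the channels.
#' @export
chain_order_from_cor <- function(cormat) {
  n <- nrow(cormat)
  if (n == 1) return(1L)
  a <- abs(cormat); diag(a) <- 0
  perm <- integer(n)
  perm[1] <- which.max(rowSums(a))
  visited <- rep(FALSE, n); visited[perm[1]] <- TRUE
  for (i in 2:n) {
    cand <- a[perm[i - 1], ]
    cand[visited] <- -Inf
    perm[i] <- which.max(cand)
    visited[perm[i]] <- TRUE
  }
  perm
}

#' Order EEG channels for volume stacking
#'
#' The depth axis of the 3D volume should place similar channels next to
#' each other so 3x3x3 kernels see coherent local structure. Two methods:
#' `correlation_chain` computes the Pearson correlation matrix of the
#' calibration signal and chains channels greedily by absolute correlation
#' (see [chain_order_from_cor()]); `montage_fixed` uses the anatomical
#' 10-20 chain of [montage_chain()]. Both are deterministic.
#'
#' @param x calibration signal: an [eeg_recording()], a [window_segment()],
#'   or a numeric matrix `n_channels x m` (m >= 2).
#' @param method `"correlation_chain"` or `"montage_fixed"`.
#' @param channel_names channel labels (required for `montage_fixed` when
#'   `x` is a bare matrix).
#' @return A `channel_ordering`: list with `permutation` (1-based),
#'   `method`, and a short `source` description.
#' @export
compute_channel_ordering <- function(x, method = c("correlation_chain", "montage_fixed"),
                                     channel_names = NULL) {
  method <- match.arg(method)
  src <- "matrix"
  if (inherits(x, "eeg_recording")) {
    channel_names <- x$channel_names
    src <- paste0("recording ", x$patient_id)
    x <- x$signal
  } else if (inherits(x, "window_segment")) {
    src <- paste0("window @", x$start_s, "s")
    x <- x$signal
  }
  n <- nrow(x)
  if (method == "correlation_chain") {
    if (ncol(x) < 2) stop("calibration signal needs at least 2 samples")
    sds <- apply(x, 1, stats::sd)
    if (any(sds == 0)) {
      stop("zero-variance channel(s): ",
           paste(if (is.null(channel_names)) which(sds == 0)
                 else channel_names[sds == 0], collapse = ", "))
    }
    perm <- chain_order_from_cor(stats::cor(t(x)))
  } else {
    if (is.null(channel_names)) stop("montage_fixed ordering needs channel names")
    chain <- montage_chain(max(n, 22))
    pos <- match(channel_names, chain)
    pos[is.na(pos)] <- length(chain) + seq_len(sum(is.na(pos)))
    perm <- order(pos)
  }
  structure(list(permutation = as.integer(perm), method = method, source = src),
            class = "channel_ordering")
}

#' Stack one window into a 3D image volume
#'
#' Rasterizes each channel of the window with [series_to_image()] and
#' stacks the planes along the depth axis in the given channel order,
#' producing the `[n_channels x side x side]` grayscale volume the 3D
#' network consumes. Label and provenance are carried over.
#'
#' @param window a [window_segment()].
#' @param ordering a `channel_ordering` from [compute_channel_ordering()]
#'   (default: identity order).
#' @param side image side in pixels.
#' @return An `image_volume`: list with `data` (array `C x side x side` in
#'   `[0, 1]`), `label`, `patient_id`, `start_s`.
#' @export
build_volume <- function(window, ordering = NULL, side = 256) {
  nc <- nrow(window$signal)
  perm <- if (is.null(ordering)) seq_len(nc) else ordering$permutation
  if (length(perm) != nc) {
    stop("ordering has ", length(perm), " channels but the window has ", nc)
  }
  data <- array(0, c(nc, side, side))
  for (k in seq_len(nc)) {
    data[k, , ] <- series_to_image(window$signal[perm[k], ], side)
  }
  structure(list(data = data, label = window$label,
                 patient_id = window$patient_id, start_s = window$start_s),
            class = "image_volume")
}

#' Export one volume plane as a PNG image for inspection
#'
#' @param volume an `image_volume` from [build_volume()].
#' @param channel depth index of the plane to export.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
export_plane_png <- function(volume, channel, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("PNG export requires the png package")
  }
  png::writePNG(volume$data[channel, , ], path)
  invisible(path)
}

#' Rasterize a list of windows into a stacked volume array
#'
#' @param segments list of [window_segment()]s.
#' @param ordering a `channel_ordering` (default identity).
#' @param side image side in pixels.
#' @return List with `volumes` (array `N x C x side x side`), `labels`
#'   (character), `provenance` (data frame `patient_id`, `start_s`).
#' @export
build_volumes <- function(segments, ordering = NULL, side = 256) {
  n <- length(segments)
  if (n == 0) stop("no segments to rasterize")
  nc <- nrow(segments[[1]]$signal)
  volumes <- array(0, c(n, nc, side, side))
  for (i in seq_len(n)) {
    volumes[i, , , ] <- build_volume(segments[[i]], ordering, side)$data
  }
  list(volumes = volumes,
       labels = vapply(segments, function(s) s$label, ""),
       provenance = data.frame(
         patient_id = vapply(segments, function(s) s$patient_id, ""),
         start_s = vapply(segments, function(s) s$start_s, 0)))
}
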