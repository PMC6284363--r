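# Shared fixtures, all generated in code at test time.

# small annotated recording: `dur` seconds at `fs` Hz with optional seizures
tiny_recording <- function(dur = 60, fs = 100, n_channels = 3, seizures = NULL,
                           seed = 1) {
  set.seed(seed)
  sig <- matrix(rnorm(n_channels * dur * fs), n_channels)
  eeg_recording(sig, fs, annotations = seizures, patient_id = "T01")
}

# reduced synthetic config used across tests: short horizons, few channels
desk_config <- function(duration_s = 360, seizures = data.frame(onset_s = 180,
                                                                duration_s = 60),
                        seed = 5, ...) {
  synthetic_config(n_channels = 4, sampling_rate_hz = 100,
                   duration_s = duration_s, seizures = seizures,
                   preictal_horizon_s = 60, seed = seed, ...)
}

# brute-force one-vs-rest metrics straight from label pairs (independent of
# the confusion-matrix route)
brute_metrics <- function(y_true, y_pred, classes) {
  per <- lapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    fp <- sum(y_true != cl & y_pred == cl)
    tn <- sum(y_true != cl & y_pred != cl)
    c(accuracy = 100 * (tp + tn) / length(y_true),
      specificity = 100 * tn / (tn + fp),
      sensitivity = 100 * tp / (tp + fn))
  })
  do.call(rbind, per)
}

# direct (slow) reference rasterizer implementing the same midpoint-split
# line rule on an explicit n x n grid, then exact block averaging
reference_raster <- function(x, side) {
  n <- length(x)
  rng <- range(x)
  xhat <- if (diff(rng) < 1e-300) rep(0.5, n) else (x - rng[1]) / diff(rng)
  y <- round((n - 1) * (1 - xhat))
  grid <- matrix(0, n, n)  # rows = amplitude, cols = time
  for (j in seq_len(n)) {
    lo <- y[j]; hi <- y[j]
    if (j > 1) {
      dy <- y[j] - y[j - 1]; npix <- abs(dy) + 1
      ntail <- npix - (npix + 1) %/% 2
      if (ntail > 0) {
        s <- sign(dy); start <- y[j] - s * (ntail - 1)
        lo <- min(lo, start, y[j]); hi <- max(hi, start, y[j])
      }
    }
    if (j < n) {
      dy <- y[j + 1] - y[j]; npix <- abs(dy) + 1
      nhead <- (npix + 1) %/% 2
      s <- sign(dy); end <- y[j] + s * (nhead - 1)
      lo <- min(lo, end, y[j]); hi <- max(hi, end, y[j])
    }
    grid[max(0, lo):min(n - 1, hi) + 1, j] <- 1
  }
  # exact area average onto side x side via overlap weights
  out <- matrix(0, side, side)
  sc <- side / n
  for (r in seq_len(n)) for (cc in seq_len(n)) {
    if (grid[r, cc] == 0) next
    rows <- floor((r - 1) * sc):floor((r - 1e-9) * sc)
    cols <- floor((cc - 1) * sc):floor((cc - 1e-9) * sc)
    for (R in rows) for (C in cols) {
      if (R >= side || C >= side) next
      ov_r <- min((R + 1) / sc, r) - max(R / sc, r - 1)
      ov_c <- min((C + 1) / sc, cc) - max(C / sc, cc - 1)
      out[R + 1, C + 1] <- out[R + 1, C + 1] + ov_r * ov_c
    }
  }
  pmin(out * sc^2, 1)
}

# write a minimal EDF file byte by byte, independently of write_edf()
handcraft_edf <- function(path, sig, fs) {
  n_sig <- nrow(sig); ns <- ncol(sig); n_rec <- ns %/% fs
  pad <- function(s, w) formatC(substr(s, 1, w), width = w, flag = "-")
  # integer physical ranges so the 8-char header fields are exact
  pmin_v <- floor(apply(sig, 1, min)) - 1; pmax_v <- ceiling(apply(sig, 1, max)) + 1
  con <- file(path, "wb"); on.exit(close(con))
  writeChar(paste0(pad("0", 8), pad("HC01", 80), pad("handcrafted", 80),
                   pad("01.01.00", 8), pad("00.00.00", 8),
                   pad(as.character(256 * (1 + n_sig)), 8), pad("", 44),
                   pad(as.character(n_rec), 8), pad("1", 8),
                   pad(as.character(n_sig), 4)), con, eos = NULL)
  f <- function(v) vapply(v, function(z) pad(format(z), 8), "")
  writeChar(paste0(c(vapply(seq_len(n_sig), function(i) pad(paste0("CH", i), 16), ""),
                     rep(pad("", 80), n_sig), rep(pad("uV", 8), n_sig),
                     f(pmin_v), f(pmax_v),
                     rep(pad("-32768", 8), n_sig), rep(pad("32767", 8), n_sig),
                     rep(pad("", 80), n_sig),
                     rep(pad(as.character(fs), 8), n_sig),
                     rep(pad("", 32), n_sig)), collapse = ""), con, eos = NULL)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(n_sig)) {
      x <- sig[s, ((r - 1) * fs + 1):(r * fs)]
      dig <- round((x - pmin_v[s]) / (pmax_v[s] - pmin_v[s]) * 65535 - 32768)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  path
}
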