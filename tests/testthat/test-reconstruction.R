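test_that("rasterizer matches a direct grid-based reference on random series", {
  set.seed(21)
  for (trial in 1:5) {
    n <- sample(20:60, 1)
    side <- sample(c(8, 12, 16), 1)
    x <- cumsum(rnorm(n))
    expect_equal(series_to_image(x, side), reference_raster(x, side),
                 tolerance = 1e-10)
  }
})

test_that("constant series produce one horizontal line at mid-amplitude", {
  n <- 101
  img <- series_to_image(rep(3.7, n), side = n)  # side = n: the raw grid
  nz <- which(rowSums(img) > 0)
  expect_equal(nz, round(0.5 * (n - 1)) + 1)
  expect_true(all(img[nz, ] == 1))
  # after compression every column is identical
  img2 <- series_to_image(rep(3.7, 5000), side = 256)
  expect_equal(img2, img2[, rep(1, 256)], tolerance = 1e-12)
})

test_that("trace images are within [0,1], column-covering, and affine-invariant", {
  set.seed(4)
  for (trial in 1:4) {
    x <- rnorm(500)
    img <- series_to_image(x, side = 64)
    expect_equal(dim(img), c(64, 64))
    expect_gte(min(img), 0)
    expect_lte(max(img), 1)
    expect_true(all(colSums(img) > 0))  # the trace visits every time column
    a <- runif(1, 0.1, 10); b <- rnorm(1, sd = 50)
    expect_equal(series_to_image(a * x + b, side = 64), img, tolerance = 1e-12)
  }
  expect_error(series_to_image(1), "at least 2")
  expect_error(series_to_image(c(1, NA, 3)), "finite")
})

test_that("correlation-chain ordering follows the greedy rule exactly", {
  cm <- matrix(c(1, 0.9, 0.1,
                 0.9, 1, 0.8,
                 0.1, 0.8, 1), 3, 3)
  expect_equal(chain_order_from_cor(cm), c(2L, 1L, 3L))  # 0-based: [1, 0, 2]
  # exhaustive check of the greedy invariant on random matrices
  set.seed(8)
  for (trial in 1:20) {
    n <- sample(3:6, 1)
    a <- matrix(runif(n * n, -1, 1), n); a <- (a + t(a)) / 2; diag(a) <- 1
    perm <- chain_order_from_cor(a)
    expect_setequal(perm, seq_len(n))
    aa <- abs(a); diag(aa) <- 0
    expect_equal(perm[1], which.max(rowSums(aa)))
    visited <- perm[1]
    for (i in 2:n) {
      cand <- aa[perm[i - 1], ]
      cand[visited] <- -Inf
      expect_equal(perm[i], which.max(cand))
      visited <- c(visited, perm[i])
    }
  }
})

test_that("channel ordering handles recordings, degenerate cases and montage mode", {
  set.seed(2)
  base <- rnorm(400)
  sig <- rbind(base + rnorm(400, sd = 0.1),
               rnorm(400),
               base + rnorm(400, sd = 0.1))
  ord <- compute_channel_ordering(sig)
  expect_setequal(ord$permutation, 1:3)
  # the two near-duplicates end up adjacent in the chain
  pos <- match(c(1, 3), ord$permutation)
  expect_equal(abs(diff(pos)), 1)
  expect_equal(compute_channel_ordering(matrix(rnorm(10), 1))$permutation, 1L)
  expect_error(compute_channel_ordering(rbind(rnorm(50), rep(1, 50))), "zero-variance")
  # montage mode: shuffled standard names map back to the anatomical chain
  rec <- tiny_recording(dur = 10, fs = 10, n_channels = 4)
  rec$channel_names <- c("Cz", "A1", "Fp1", "T3")
  ord2 <- compute_channel_ordering(rec, method = "montage_fixed")
  expect_equal(rec$channel_names[ord2$permutation], c("A1", "T3", "Fp1", "Cz"))
})

test_that("volumes stack ordered channel images with labels and provenance", {
  set.seed(6)
  seg <- window_segment(matrix(rnorm(3 * 200), 3), "pre_ictal", 40, "P07")
  vol <- build_volume(seg, side = 32)
  expect_equal(dim(vol$data), c(3, 32, 32))
  expect_equal(vol$label, "pre_ictal")
  expect_equal(vol$data[2, , ], series_to_image(seg$signal[2, ], 32))
  expect_gte(min(vol$data), 0); expect_lte(max(vol$data), 1)
  # permuting the ordering permutes the planes identically
  ord <- structure(list(permutation = c(3L, 1L, 2L), method = "correlation_chain",
                        source = "test"), class = "channel_ordering")
  vol2 <- build_volume(seg, ord, side = 32)
  for (k in 1:3) expect_equal(vol2$data[k, , ], vol$data[ord$permutation[k], , ])
  expect_error(build_volume(seg, structure(list(permutation = 1:2),
                                           class = "channel_ordering")), "channels")
  # stacked container round-trip
  segs <- list(seg, window_segment(matrix(rnorm(600), 3), "ictal", 60, "P07"))
  vols <- build_volumes(segs, side = 16)
  expect_equal(dim(vols$volumes), c(2, 3, 16, 16))
  path <- withr::local_tempfile(fileext = ".rds")
  save_volumes(vols$volumes, vols$labels, vols$provenance, path)
  back <- load_volumes(path)
  expect_identical(back$volumes, vols$volumes)
  expect_identical(back$labels, vols$labels)
})
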