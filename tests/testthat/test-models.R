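test_that("3D architecture matches the reference stack", {
  spec <- build_3d_cnn()
  kinds <- vapply(spec$layers, function(l) l$kind, "")
  expect_equal(sum(kinds == "conv3d"), 4)
  expect_equal(sum(kinds == "maxpool3d"), 3)
  convs <- spec$layers[kinds == "conv3d"]
  expect_equal(vapply(convs, function(l) l$width, 0L), c(64L, 128L, 256L, 256L))
  for (l in convs) {
    expect_equal(l$kernel, c(3L, 3L, 3L))
    expect_equal(l$stride, c(1L, 1L, 1L))
    expect_equal(l$activation, "leaky_relu")
    expect_equal(l$leaky_slope, 0.01)
    expect_equal(l$normalization, "group")
  }
  pools <- spec$layers[kinds == "maxpool3d"]
  expect_equal(lapply(pools, function(l) l$stride),
               list(c(2L, 2L, 2L), c(1L, 2L, 2L), c(1L, 2L, 2L)))
  dense <- spec$layers[kinds == "dense"]
  expect_equal(vapply(dense, function(l) l$width, 0L), c(4096L, 2048L, 3L))
  expect_equal(vapply(dense[1:2], function(l) l$dropout_rate, 0), c(0.5, 0.5))
  expect_equal(kinds[length(kinds)], "softmax")
})

test_that("2D baseline matches its reference stack and accepts single-channel input", {
  spec <- build_2d_cnn()
  kinds <- vapply(spec$layers, function(l) l$kind, "")
  expect_equal(sum(kinds == "conv2d"), 5)
  expect_equal(sum(kinds == "maxpool2d"), 5)
  convs <- spec$layers[kinds == "conv2d"]
  expect_equal(vapply(convs, function(l) l$width, 0L), c(32L, 64L, 128L, 256L, 256L))
  expect_equal(convs[[1]]$kernel, c(5L, 5L))
  for (l in convs[-1]) expect_equal(l$kernel, c(3L, 3L))
  for (l in convs) expect_equal(l$normalization, "batch")
  dense <- spec$layers[kinds == "dense"]
  expect_equal(vapply(dense, function(l) l$width, 0L), c(2048L, 1024L, 3L))
  expect_equal(vapply(dense[1:2], function(l) l$dropout_rate, 0), c(0.5, 0.5))
  expect_s3_class(build_2d_cnn(input_shape = c(1, 256, 256)), "model_spec")
})

test_that("shape arithmetic reproduces the documented cascades", {
  spec <- build_3d_cnn()  # SAME padding
  sh <- output_shape(spec)
  pools <- which(vapply(spec$layers, function(l) l$kind, "") == "maxpool3d")
  expect_equal(sh[[pools[1]]], c(64L, 11L, 128L, 128L))
  expect_equal(sh[[pools[2]]], c(128L, 10L, 64L, 64L))
  expect_equal(sh[[pools[3]]], c(256L, 9L, 32L, 32L))

  spec_v <- build_3d_cnn(padding = "valid")
  sh_v <- output_shape(spec_v)
  expect_equal(sh_v[[pools[3]]], c(256L, 2L, 29L, 29L))  # pre-flatten
  expect_equal(sh_v[[pools[3] + 1]], 256L * 2L * 29L * 29L)

  spec2 <- build_2d_cnn()
  sh2 <- output_shape(spec2)
  pools2 <- which(vapply(spec2$layers, function(l) l$kind, "") == "maxpool2d")
  expect_equal(vapply(pools2, function(i) sh2[[i]][2], 0L),
               c(127L, 63L, 31L, 15L, 7L))
  # final layer is the class distribution
  expect_equal(sh2[[length(sh2)]], 3L)
  # exhausted pooling cascade names the failing layer
  expect_error(build_3d_cnn(input_shape = c(2, 16, 16)), "maxpool3d")
})

test_that("declared shapes match engine execution under both paddings", {
  for (padding in c("same", "valid")) {
    spec <- build_3d_cnn(input_shape = c(22, 32, 32), width_scale = 1 / 16,
                         padding = padding)
    net <- init_network(spec, seed = 1)
    expect_equal(probe_shapes(net), output_shape(spec))
    spec2 <- build_2d_cnn(input_shape = c(3, 128, 128), width_scale = 1 / 16,
                          padding = padding)
    net2 <- init_network(spec2, seed = 1)
    expect_equal(probe_shapes(net2), output_shape(spec2))
  }
})

test_that("group normalization standardizes each group and handles limits", {
  set.seed(5)
  x <- array(rnorm(4 * 8 * 5 * 6, mean = 3, sd = 2), c(4, 8, 5, 6))
  y <- group_normalize(x, groups = 4)
  for (n in 1:4) for (g in 1:4) {
    blk <- y[n, (g - 1) * 2 + 1:2, , ]
    expect_lt(abs(mean(blk)), 1e-6)
    expect_lt(abs(mean(blk^2) - 1), 1e-3)  # eps-limited
  }
  # groups = 1: whole-sample standardization oracle
  y1 <- group_normalize(x, groups = 1)
  for (n in 1:4) {
    expect_equal(y1[n, , , ],
                 (x[n, , , ] - mean(x[n, , , ])) /
                   sqrt(mean((x[n, , , ] - mean(x[n, , , ]))^2) + 1e-5),
                 tolerance = 1e-12)
  }
  # groups = C: per-channel instance normalization
  yc <- group_normalize(x, groups = 8)
  ch <- x[2, 3, , ]
  expect_equal(yc[2, 3, , ], (ch - mean(ch)) / sqrt(mean((ch - mean(ch))^2) + 1e-5),
               tolerance = 1e-12)
  # affine applies per channel
  ya <- group_normalize(x, groups = 4, gamma = 1:8, beta = rep(10, 8))
  expect_equal(ya, sweep(sweep(group_normalize(x, 4), 2, 1:8, "*"), 2, rep(10, 8), "+"),
               tolerance = 1e-12)
  expect_error(group_normalize(x, groups = 3), "divide")
})

test_that("engine group norm agrees with the reference implementation", {
  set.seed(11)
  C <- 8L; S <- c(3L, 4L, 5L); N <- 3L
  z <- array(rnorm(C * prod(S) * N, 1, 3), c(C, S, N))
  gamma <- runif(C, 0.5, 2); beta <- rnorm(C)
  g <- ictalcnn:::gn_forward(z, C, prod(S), N, 4L, gamma, beta, 1e-5)
  # reference: batch-first public implementation
  zb <- aperm(z, c(5, 1, 2, 3, 4))
  ref <- group_normalize(zb, groups = 4, gamma = gamma, beta = beta)
  expect_equal(g$y, aperm(ref, c(2, 3, 4, 5, 1)), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("probabilities are normalized, deterministic, and dropout only acts in training", {
  spec <- build_3d_cnn(input_shape = c(8, 16, 16), width_scale = 1 / 16)
  net <- init_network(spec, seed = 42)
  set.seed(1)
  vols <- array(runif(5 * 8 * 16 * 16), c(5, 8, 16, 16))
  p <- predict_proba(net, vols)
  expect_equal(dim(p), c(3L, 5L))
  expect_true(all(p >= 0))
  expect_equal(colSums(p), rep(1, 5), tolerance = 1e-6)
  expect_identical(p, predict_proba(net, vols))  # frozen weights, fixed input
  expect_error(predict_proba(net, array(runif(2 * 4 * 16 * 16), c(2, 4, 16, 16))),
               "does not match")
  # two inference passes identical; training passes differ through dropout
  x <- ictalcnn:::volumes_to_input(vols, "3d")
  f1 <- ictalcnn:::network_forward(net, x, training = FALSE)$probs
  f2 <- ictalcnn:::network_forward(net, x, training = FALSE)$probs
  expect_identical(f1, f2)
  set.seed(2); t1 <- ictalcnn:::network_forward(net, x, training = TRUE)$probs
  set.seed(3); t2 <- ictalcnn:::network_forward(net, x, training = TRUE)$probs
  expect_false(identical(t1, t2))
})

test_that("architectures serialize to JSON with every layer field", {
  js <- model_to_json(build_3d_cnn())
  obj <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_equal(obj$name, "cnn3d")
  expect_equal(length(obj$layers), 12)
  expect_equal(obj$layers[[1]]$width, 64)
  expect_equal(obj$layers[[1]]$normalization, "group")
})
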