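test_that("10:1:1 split has the documented sizes and is deterministic", {
  sp <- split_dataset(36000, seed = 3)
  expect_equal(vapply(sp, length, 0L),
               c(train = 30000L, validation = 3000L, test = 3000L))
  expect_equal(sort(unname(unlist(sp))), 1:36000)
  sp12 <- split_dataset(12, seed = 1)
  expect_equal(vapply(sp12, length, 0L),
               c(train = 10L, validation = 1L, test = 1L))
  expect_identical(split_dataset(500, seed = 7), split_dataset(500, seed = 7))
  expect_false(identical(split_dataset(500, seed = 7), split_dataset(500, seed = 8)))
})

test_that("stratified split keeps every class in every part", {
  labels <- rep(stage_levels(), times = c(120, 60, 24))
  sp <- split_dataset(length(labels), labels = labels, seed = 2)
  expect_equal(sort(unname(unlist(sp))), seq_along(labels))
  for (part in sp) expect_setequal(unique(labels[part]), stage_levels())
  expect_error(split_dataset(10, labels = c(rep("a", 8), "b", "b"), seed = 1),
               "stratum")
})

test_that("k-fold splits partition the pool with near-equal validation blocks", {
  folds <- kfold_splits(1:100, k = 10, seed = 4)
  expect_length(folds, 10)
  vals <- lapply(folds, `[[`, "validation_indices")
  expect_true(all(vapply(vals, length, 0L) == 10L))
  expect_equal(sort(unlist(vals)), 1:100)
  for (f in folds) {
    expect_length(intersect(f$train_indices, f$validation_indices), 0)
    expect_setequal(c(f$train_indices, f$validation_indices), 1:100)
  }
  sizes <- vapply(kfold_splits(1:101, 10, 1), function(f)
    length(f$validation_indices), 0L)
  expect_equal(sort(sizes, decreasing = TRUE), c(11L, rep(10L, 9)))
  expect_error(kfold_splits(1:20, k = 1), "k must be")
})

test_that("learning-rate schedule follows both decay rules", {
  cfg <- train_config()
  # strictly improving validation error: only the 40-epoch step cuts fire
  err <- 0.5 - (1:120) * 0.002
  expect_equal(next_learning_rate(list(val_error = err[1:40]), cfg), 0.001)
  expect_equal(next_learning_rate(list(val_error = err[1:80]), cfg), 1e-4)
  expect_equal(next_learning_rate(list(val_error = err[1:39]), cfg), 0.01)
  # constant error: first plateau cut when the 10th stagnant epoch completes
  flat <- rep(0.3, 30)
  expect_equal(next_learning_rate(flat[1:9], cfg), 0.01)
  expect_equal(next_learning_rate(flat[1:10], cfg), 0.001)
  expect_equal(next_learning_rate(flat[1:19], cfg), 0.001)
  expect_equal(next_learning_rate(flat[1:20], cfg), 1e-4)
  # one improving epoch: no trigger
  expect_equal(next_learning_rate(c(0.5, 0.4), cfg), 0.01)
  # trajectory is non-increasing and floored at min_lr
  set.seed(9)
  traj <- ictalcnn:::lr_trajectory(runif(300, 0.2, 0.21), cfg)
  expect_true(all(diff(traj) <= 0))
  expect_true(all(traj >= cfg$min_lr))
  expect_equal(min(traj), cfg$min_lr)
})

test_that("training runs, reduces loss on a separable task, and is seed-stable", {
  set.seed(31)
  # toy volumes: class-dependent mean level in a 3-class problem
  n <- 24
  labs <- rep(stage_levels(), length.out = n)
  vols <- array(runif(n * 8 * 16 * 16, 0, 0.2), c(n, 8, 16, 16))
  for (i in seq_len(n)) {
    vols[i, , , ] <- vols[i, , , ] + (match(labs[i], stage_levels()) - 1) * 0.4
  }
  spec <- build_3d_cnn(input_shape = c(8, 16, 16), width_scale = 1 / 16)
  cfg <- train_config(epochs = 2, lr0 = 1e-3, seed = 5, batch_size = 6,
                      early_stop_val_error = NA)
  fit <- train_network(spec, vols[1:18, , , ], labs[1:18],
                       vols[19:24, , , ], labs[19:24], cfg)
  expect_equal(nrow(fit$history), 2)
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_true(all(diff(fit$history$lr) <= 0))
  # determinism: same seed, same data -> identical first-epoch loss
  fit2 <- train_network(spec, vols[1:18, , , ], labs[1:18],
                        vols[19:24, , , ], labs[19:24], cfg)
  expect_identical(fit$history$train_loss[1], fit2$history$train_loss[1])
  # longer run on the separable task: loss shrinks substantially
  cfg2 <- train_config(epochs = 8, lr0 = 1e-3, seed = 5, batch_size = 6,
                       early_stop_val_error = NA)
  fit3 <- train_network(spec, vols[1:18, , , ], labs[1:18],
                        vols[19:24, , , ], labs[19:24], cfg2)
  expect_lt(fit3$history$train_loss[8], fit3$history$train_loss[1])
})

test_that("cross-validation aggregates disjoint fold reports", {
  set.seed(13)
  n <- 24
  labs <- rep(stage_levels(), length.out = n)
  vols <- array(runif(n * 8 * 16 * 16, 0, 0.2), c(n, 8, 16, 16))
  for (i in seq_len(n)) {
    vols[i, , , ] <- vols[i, , , ] + (match(labs[i], stage_levels()) - 1) * 0.4
  }
  cfg <- train_config(epochs = 2, lr0 = 1e-3, seed = 2, batch_size = 6,
                      early_stop_val_error = NA)
  cv <- cross_validate(function() build_3d_cnn(input_shape = c(8, 16, 16),
                                               width_scale = 1 / 16),
                       vols, labs, cfg, k = 2)
  expect_length(cv$folds, 2)
  v1 <- cv$folds[[1]]$history
  expect_equal(nrow(v1), 2)
  accs <- vapply(cv$folds, function(f) f$metrics$macro$accuracy, 0)
  expect_equal(unname(cv$mean_macro["accuracy"]), mean(accs))
})
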