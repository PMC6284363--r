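# Dataset splitting, 10-fold cross-validation and the optimization regimen:
# minibatch Adam on the mean cross-entropy with a two-rule learning-rate
# schedule (plateau cut after `plateau_patience` stagnant epochs, otherwise
# a step cut every `decay_every` epochs).

#' Training configuration
#'
#' Defaults follow the reference regimen: batch size 10, up to 200 epochs,
#' Adam with initial learning rate 0.01, beta1 0.9, beta2 0.999, no weight
#' decay; the learning rate is divided by `decay_factor` after
#' `plateau_patience` consecutive epochs whose validation error improved by
#' less than `plateau_tolerance`, otherwise after every `decay_every`
#' epochs, floored at `min_lr`.
#'
#' @param batch_size minibatch size.
#' @param epochs maximum number of epochs.
#' @param iterations_per_epoch minibatch steps per epoch; `NULL` (default)
#'   means one pass over the training set.
#' @param lr0 initial learning rate.
#' @param beta1,beta2 Adam moment decay rates.
#' @param weight_decay L2 penalty coefficient.
#' @param plateau_patience stagnant epochs before a plateau cut.
#' @param plateau_tolerance minimum per-epoch improvement of validation
#'   error (absolute) that counts as progress; "unchanged" is operationalized
#'   as improvement below this, since exact float equality would never occur.
#' @param decay_every epoch period of the unconditional step cut.
#' @param decay_factor division factor for both cuts (> 1).
#' @param min_lr learning-rate floor.
#' @param early_stop_val_error stop training once the validation error
#'   reaches this level (default 0: stop only on a perfect validation
#'   epoch); set to `NA` to disable.
#' @param seed run seed; shuffling, initialization and dropout streams all
#'   derive from it.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 10, epochs = 200,
                         iterations_per_epoch = NULL, lr0 = 0.01,
                         beta1 = 0.9, beta2 = 0.999, weight_decay = 0,
                         plateau_patience = 10, plateau_tolerance = 1e-4,
                         decay_every = 40, decay_factor = 10, min_lr = 1e-8,
                         early_stop_val_error = 0, seed = 1L) {
  if (batch_size < 1 || epochs < 1) stop("counts must be positive")
  if (lr0 <= 0) stop("lr0 must be positive")
  if (decay_factor <= 1) stop("decay_factor must be > 1")
  structure(list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 iterations_per_epoch = iterations_per_epoch, lr0 = lr0,
                 beta1 = beta1, beta2 = beta2, weight_decay = weight_decay,
                 plateau_patience = as.integer(plateau_patience),
                 plateau_tolerance = plateau_tolerance,
                 decay_every = as.integer(decay_every),
                 decay_factor = decay_factor, min_lr = min_lr,
                 early_stop_val_error = early_stop_val_error,
                 seed = as.integer(seed)), class = "train_config")
}

#' Train / validation / test split
#'
#' Disjoint cover of `1:n` with sizes proportional to `proportions`
#' (validation and test rounded down, remainder to train), stratified by
#' `labels` when given, deterministic given `seed`.
#'
#' @param n number of items (>= 12 for the default 10:1:1 proportions).
#' @param proportions length-3 positive weights (train, validation, test).
#' @param labels optional per-item class labels for stratification.
#' @param seed integer seed.
#' @return List with integer index vectors `train`, `validation`, `test`.
#' @export
split_dataset <- function(n, proportions = c(10, 1, 1), labels = NULL, seed = 1L) {
  stopifnot(length(proportions) == 3, all(proportions > 0))
  frac <- proportions / sum(proportions)
  take <- function(idx) {
    m <- length(idx)
    n_val <- max(1L, floor(m * frac[2]))
    n_test <- max(1L, floor(m * frac[3]))
    idx <- with_seed(seed, sample(idx))
    list(validation = sort(idx[seq_len(n_val)]),
         test = sort(idx[n_val + seq_len(n_test)]),
         train = sort(idx[-(seq_len(n_val + n_test))]))
  }
  if (is.null(labels)) {
    if (n < 12) stop("need at least 12 items")
    parts <- take(seq_len(n))
  } else {
    stopifnot(length(labels) == n)
    parts <- list(train = integer(0), validation = integer(0), test = integer(0))
    for (lev in sort(unique(as.character(labels)))) {
      idx <- which(labels == lev)
      if (length(idx) < 3) stop("stratum '", lev, "' has fewer than 3 items")
      p <- take(idx)
      parts$train <- c(parts$train, p$train)
      parts$validation <- c(parts$validation, p$validation)
      parts$test <- c(parts$test, p$test)
    }
    parts <- lapply(parts, sort)
  }
  parts[c("train", "validation", "test")]
}

#' k-fold cross-validation splits
#'
#' One seeded shuffle, then `k` near-equal contiguous validation blocks
#' (the first `n %% k` folds get one extra item); every index is validated
#' exactly once.
#'
#' @param indices integer vector to fold.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return List of folds, each `list(fold_index, train_indices,
#'   validation_indices)`.
#' @export
kfold_splits <- function(indices, k = 10, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  n <- length(indices)
  if (n < k) stop("need at least k indices")
  shuffled <- with_seed(seed, sample(indices))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1) + 1L)
  lapply(seq_len(k), function(i) {
    val <- shuffled[starts[i]:ends[i]]
    list(fold_index = i, train_indices = sort(setdiff(shuffled, val)),
         validation_indices = sort(val))
  })
}

# learning rate in force for each epoch 1..(length(val_errors)+1), replayed
# from the start of training so the function is stateless
lr_trajectory <- function(val_errors, config) {
  lr <- config$lr0
  counter <- 0L
  lrs <- numeric(length(val_errors) + 1)
  lrs[1] <- lr
  for (t in seq_along(val_errors)) {
    impr <- if (t == 1) 0 else val_errors[t - 1] - val_errors[t]
    if (impr < config$plateau_tolerance) counter <- counter + 1L else counter <- 0L
    if (counter >= config$plateau_patience) {
      lr <- lr / config$decay_factor
      counter <- 0L
    } else if (t %% config$decay_every == 0) {
      lr <- lr / config$decay_factor
    }
    lr <- max(lr, config$min_lr)
    lrs[t + 1] <- lr
  }
  lrs
}

#' Learning rate for the next epoch
#'
#' Two-rule schedule replayed over the validation-error history: a counter
#' tracks consecutive epochs whose validation error improved by less than
#' `plateau_tolerance`; when it reaches `plateau_patience` the rate is
#' divided by `decay_factor` and the counter resets; otherwise the rate is
#' divided by `decay_factor` after every `decay_every`-th epoch. The rate
#' never falls below `min_lr` and is non-increasing over epochs.
#'
#' @param history a data frame or list with a `val_error` vector covering
#'   all completed epochs.
#' @param config a [train_config()].
#' @param epoch number of completed epochs (defaults to the history length).
#' @return Learning rate for the next epoch.
#' @export
next_learning_rate <- function(history, config, epoch = NULL) {
  err <- if (is.list(history) && !is.null(history$val_error)) history$val_error else history
  if (is.null(epoch)) epoch <- length(err)
  stopifnot(epoch <= length(err))
  traj <- lr_trajectory(err[seq_len(epoch)], config)
  traj[epoch + 1]
}

adam_update <- function(par, grad, st, lr, config, t) {
  if (is.null(st)) st <- list(m = par * 0, v = par * 0)
  g <- grad
  if (config$weight_decay > 0) g <- g + config$weight_decay * par
  st$m <- config$beta1 * st$m + (1 - config$beta1) * g
  st$v <- config$beta2 * st$v + (1 - config$beta2) * g^2
  mhat <- st$m / (1 - config$beta1^t)
  vhat <- st$v / (1 - config$beta2^t)
  list(par = par - lr * mhat / (sqrt(vhat) + 1e-8), state = st)
}

labels_to_onehot <- function(labels, n_classes = 3) {
  li <- match(labels, stage_levels())
  if (any(is.na(li))) stop("unknown stage label in training data")
  y <- matrix(0, n_classes, length(labels))
  y[cbind(li, seq_along(labels))] <- 1
  y
}

#' Train a network on labeled image volumes
#'
#' Minimizes mean cross-entropy with minibatch Adam under the two-rule
#' learning-rate schedule, shuffling each epoch with a seeded generator.
#' Records per-epoch training loss, validation error (1 - accuracy) and
#' learning rate, and returns the parameters from the epoch with the best
#' validation error.
#'
#' @param net a network from [init_network()], or a [model_spec()] (then
#'   initialized here with the config seed).
#' @param volumes array `N x C x H x W` of training volumes.
#' @param labels character stage labels, length N.
#' @param val_volumes,val_labels validation set in the same format.
#' @param config a [train_config()].
#' @param verbose print a line per epoch.
#' @return List with `net` (best-validation parameters) and `history`
#'   (data frame: epoch, train_loss, val_error, lr).
#' @export
train_network <- function(net, volumes, labels, val_volumes, val_labels,
                          config = train_config(), verbose = FALSE) {
  if (inherits(net, "model_spec")) net <- init_network(net, seed = config$seed)
  arch <- if (net$spec$name == "cnn3d") "3d" else "2d"
  n <- dim(volumes)[1]
  y_all <- labels_to_onehot(labels, net$spec$n_classes)
  n_iter_cfg <- config$iterations_per_epoch
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_error = numeric(0), lr = numeric(0))
  best <- list(err = Inf, params = net$params, state = net$state)
  lr <- config$lr0
  adam_state <- vector("list", length(net$params))
  t_step <- 0L
  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample(n)
      n_iter <- if (is.null(n_iter_cfg)) ceiling(n / config$batch_size) else n_iter_cfg
      losses <- numeric(n_iter)
      pos <- 0L
      for (it in seq_len(n_iter)) {
        if (pos >= n) { perm <- sample(n); pos <- 0L }
        idx <- perm[(pos + 1):min(n, pos + config$batch_size)]
        pos <- pos + length(idx)
        x <- volumes_to_input(volumes[idx, , , , drop = FALSE], arch)
        fw <- network_forward(net, x, training = TRUE, keep_cache = TRUE)
        net <- fw$net
        p <- fw$probs
        yb <- y_all[, idx, drop = FALSE]
        loss <- -mean(log(pmax(colSums(p * yb), 1e-12)))
        if (!is.finite(loss)) {
          stop(sprintf("non-finite loss at epoch %d, batch %d", epoch, it))
        }
        losses[it] <- loss
        grads <- network_backward(net, fw$caches, yb)
        t_step <- t_step + 1L
        for (li in seq_along(grads)) {
          if (is.null(grads[[li]])) next
          for (nm in names(grads[[li]])) {
            key <- paste0(li, ".", nm)
            up <- adam_update(net$params[[li]][[nm]], grads[[li]][[nm]],
                              adam_state[[key]], lr, config, t_step)
            net$params[[li]][[nm]] <- up$par
            adam_state[[key]] <- up$state
          }
        }
      }
      pred <- predict_stage(net, val_volumes)
      val_err <- mean(pred != val_labels)
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = mean(losses),
                                           val_error = val_err, lr = lr))
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  val_error %.4f  lr %g",
                        epoch, mean(losses), val_err, lr))
      }
      if (val_err < best$err) {
        best <- list(err = val_err, params = net$params, state = net$state)
      }
      if (!is.na(config$early_stop_val_error) &&
          val_err <= config$early_stop_val_error) break
      lr <- next_learning_rate(history$val_error, config)
    }
  })
  net$params <- best$params
  net$state <- best$state
  list(net = net, history = history)
}

#' k-fold cross-validation of an architecture
#'
#' Trains one model per fold on the fold's complement and evaluates it on
#' the fold's validation block; reports per-fold metrics and their
#' unweighted mean.
#'
#' @param model_builder zero-argument function returning a fresh
#'   [model_spec()].
#' @param volumes array `N x C x H x W`.
#' @param labels character stage labels, length N.
#' @param config a [train_config()].
#' @param k number of folds.
#' @param verbose print per-epoch progress.
#' @return List with `folds` (per-fold list: fold_index, metrics, history),
#'   `mean_macro` (named vector of macro metrics averaged over folds).
#' @export
cross_validate <- function(model_builder, volumes, labels, config = train_config(),
                           k = 10, verbose = FALSE) {
  folds <- kfold_splits(seq_len(dim(volumes)[1]), k = k, seed = config$seed)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds[[f]]$train_indices
    va <- folds[[f]]$validation_indices
    cfg <- config
    cfg$seed <- config$seed + f
    fit <- train_network(model_builder(), volumes[tr, , , , drop = FALSE],
                         labels[tr], volumes[va, , , , drop = FALSE],
                         labels[va], cfg, verbose = verbose)
    pred <- predict_stage(fit$net, volumes[va, , , , drop = FALSE])
    rep <- metrics(confusion_matrix(labels[va], pred))
    reports[[f]] <- list(fold_index = f, metrics = rep, history = fit$history)
  }
  macro <- do.call(rbind, lapply(reports, function(r)
    unlist(r$metrics$macro[c("accuracy", "specificity", "sensitivity", "fnr", "fpr")])))
  list(folds = reports, mean_macro = colMeans(macro))
}
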