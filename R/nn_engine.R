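# Runnable network engine behind the declarative model_spec. Convolutions are
# evaluated as GEMMs on im2col patch matrices (BLAS does the heavy lifting);
# every tensor is an R array in channel-first layout (C, D, H, W, N) with 2D
# operations lifted to a depth-1 third axis.

lift3 <- function(v) if (length(v) == 2) c(1L, as.integer(v)) else as.integer(v)

# per-layer execution plan: lifted kernels/strides/pads and in/out dims
plan_network <- function(spec, input_shape = NULL) {
  shape <- as.integer(if (is.null(input_shape)) spec$input_shape else input_shape)
  cur <- c(shape[1], lift3(shape[-1]))  # (C, D, H, W)
  plans <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    if (l$kind %in% c("conv3d", "conv2d")) {
      k3 <- lift3(l$kernel); s3 <- lift3(l$stride)
      pad3 <- if (l$padding == "same") {
        mapply(same_pad, cur[-1], k3, s3)
      } else c(0L, 0L, 0L)
      outsp <- (cur[-1] + 2L * pad3 - k3) %/% s3 + 1L
      if (any(outsp < 1)) stop(sprintf("layer %d (%s): non-positive output dim", i, l$kind))
      plans[[i]] <- list(op = "conv", k3 = k3, s3 = s3, pad3 = as.integer(pad3),
                         in_dim = cur, out_dim = c(l$width, outsp),
                         P = cur[1] * prod(k3), L = prod(outsp))
      cur <- c(l$width, outsp)
    } else if (l$kind %in% c("maxpool3d", "maxpool2d")) {
      k3 <- lift3(l$kernel); s3 <- lift3(l$stride)
      outsp <- (cur[-1] - k3) %/% s3 + 1L
      if (any(outsp < 1)) stop(sprintf("layer %d (%s): input smaller than pooling window", i, l$kind))
      plans[[i]] <- list(op = "pool", k3 = k3, s3 = s3,
                         in_dim = cur, out_dim = c(cur[1], outsp))
      cur <- c(cur[1], outsp)
    } else if (l$kind == "flatten") {
      plans[[i]] <- list(op = "flatten", in_dim = cur, out_dim = prod(cur))
      cur <- prod(cur)
    } else if (l$kind == "dense") {
      plans[[i]] <- list(op = "dense", in_dim = cur, out_dim = l$width)
      cur <- l$width
    } else if (l$kind == "softmax") {
      plans[[i]] <- list(op = "softmax", in_dim = cur, out_dim = cur)
    } else {
      plans[[i]] <- list(op = "identity", in_dim = cur, out_dim = cur)
    }
  }
  plans
}

#' Instantiate a runnable network from an architecture
#'
#' Allocates parameters for every convolution / dense layer (He fan-in
#' scaled Gaussian weights, zero biases, unit/zero normalization affines)
#' with a seeded generator, so initialization is reproducible.
#'
#' @param spec a [model_spec()].
#' @param seed integer seed for weight initialization.
#' @return A `network` object (spec + parameters + normalization state).
#' @export
init_network <- function(spec, seed = 1L) {
  plans <- plan_network(spec)
  params <- vector("list", length(spec$layers))
  state <- vector("list", length(spec$layers))
  with_seed(seed, {
    for (i in seq_along(spec$layers)) {
      l <- spec$layers[[i]]; p <- plans[[i]]
      if (p$op == "conv") {
        fan_in <- p$P
        params[[i]] <- list(W = matrix(rnorm(l$width * p$P, sd = sqrt(2 / fan_in)),
                                       l$width, p$P),
                            b = numeric(l$width))
        if (l$normalization != "none") {
          params[[i]]$gamma <- rep(1, l$width)
          params[[i]]$beta <- numeric(l$width)
        }
        if (l$normalization == "batch") {
          state[[i]] <- list(mean = numeric(l$width), var = rep(1, l$width))
        }
      } else if (p$op == "dense") {
        fan_in <- p$in_dim
        params[[i]] <- list(W = matrix(rnorm(l$width * fan_in, sd = sqrt(2 / fan_in)),
                                       l$width, fan_in),
                            b = numeric(l$width))
      }
    }
  })
  structure(list(spec = spec, plans = plans, params = params, state = state),
            class = "network")
}

#' @export
print.network <- function(x, ...) {
  n_par <- sum(vapply(x$params, function(p)
    if (is.null(p)) 0 else sum(vapply(p, length, 0)), 0))
  cat(sprintf("<network> %s with %s parameters\n", x$spec$name,
              format(n_par, big.mark = ",")))
  invisible(x)
}

leaky_fwd <- function(z, slope) pmax(z, 0) + slope * pmin(z, 0)
leaky_bwd <- function(dy, z, slope) dy * (slope + (1 - slope) * (z > 0))

# ---- batch norm, channel-first ----------------------------------------------

bn_fwd_cf <- function(a, gamma, beta, run, training, momentum = 0.9, eps = 1e-5) {
  d <- dim(a); C <- d[1]; M <- as.integer(prod(d) / C)
  m <- a; dim(m) <- c(C, M)
  if (training) {
    mu <- rowMeans(m)
    v <- rowMeans(m * m) - mu^2
    run$mean <- momentum * run$mean + (1 - momentum) * mu
    run$var <- momentum * run$var + (1 - momentum) * v
  } else {
    mu <- run$mean; v <- run$var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (m - mu) * inv
  y <- xhat * gamma + beta
  dim(y) <- d
  list(y = y, run = run, cache = list(xhat = xhat, inv = inv, d = d, C = C, M = M))
}

bn_bwd_cf <- function(dy, cache, gamma) {
  C <- cache$C; M <- cache$M
  dy_m <- dy; dim(dy_m) <- c(C, M)
  dgamma <- rowSums(dy_m * cache$xhat)
  dbeta <- rowSums(dy_m)
  dxhat <- dy_m * gamma
  s1 <- rowSums(dxhat); s2 <- rowSums(dxhat * cache$xhat)
  dx <- (dxhat - s1 / M - cache$xhat * (s2 / M)) * cache$inv
  dim(dx) <- cache$d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- full forward / backward ------------------------------------------------

# x: (C, D, H, W, N) lifted input. Returns probs (K x N) and, when
# keep_cache, everything the backward pass needs.
network_forward <- function(net, x, training = FALSE, keep_cache = FALSE) {
  plans <- net$plans; layers <- net$spec$layers
  caches <- if (keep_cache) vector("list", length(layers)) else NULL
  N <- dim(x)[length(dim(x))]
  cur <- x
  for (i in seq_along(layers)) {
    l <- layers[[i]]; p <- plans[[i]]; pr <- net$params[[i]]
    if (p$op == "conv") {
      col <- im2col_nd(cur, c(p$in_dim, N), p$k3, p$s3, p$pad3)
      z <- pr$W %*% col + pr$b
      dim(z) <- c(l$width, p$out_dim[-1], N)
      nc <- NULL
      if (l$normalization == "group") {
        g <- gn_forward(z, l$width, prod(p$out_dim[-1]), N, l$groups,
                        pr$gamma, pr$beta, 1e-5)
        a <- g$y
        nc <- list(xhat = g$xhat, inv = g$inv)
      } else if (l$normalization == "batch") {
        g <- bn_fwd_cf(z, pr$gamma, pr$beta, net$state[[i]], training)
        a <- g$y; nc <- g$cache
        if (training) net$state[[i]] <- g$run
      } else a <- z
      out <- if (l$activation == "leaky_relu") leaky_fwd(a, l$leaky_slope) else a
      if (keep_cache) caches[[i]] <- list(col = col, a = a, norm = nc)
      cur <- out
    } else if (p$op == "pool") {
      mp <- maxpool_fwd(cur, c(p$in_dim, N), p$k3, p$s3)
      if (keep_cache) caches[[i]] <- list(argmax = mp$argmax, in_len = length(cur),
                                          in_dim = c(p$in_dim, N))
      cur <- mp$y
    } else if (p$op == "flatten") {
      dim(cur) <- c(p$out_dim, N)
    } else if (p$op == "dense") {
      z <- pr$W %*% cur + pr$b
      a <- if (l$activation == "leaky_relu") leaky_fwd(z, l$leaky_slope) else z
      mask <- NULL
      if (training && l$dropout_rate > 0) {
        mask <- matrix(stats::rbinom(length(a), 1, 1 - l$dropout_rate) /
                         (1 - l$dropout_rate), nrow(a), ncol(a))
        a <- a * mask
      }
      if (keep_cache) caches[[i]] <- list(x_in = cur, z = z, mask = mask)
      cur <- a
    } else if (p$op == "softmax") {
      z <- cur - rep(apply(cur, 2, max), each = nrow(cur))
      e <- exp(z)
      cur <- e / rep(colSums(e), each = nrow(e))
      if (keep_cache) caches[[i]] <- list(probs = cur)
    }
  }
  list(probs = cur, caches = caches, net = net)
}

# y_onehot: K x N. Returns gradients in the same structure as params.
network_backward <- function(net, caches, y_onehot) {
  plans <- net$plans; layers <- net$spec$layers
  grads <- vector("list", length(layers))
  N <- ncol(y_onehot)
  dcur <- NULL
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]; p <- plans[[i]]; pr <- net$params[[i]]; ca <- caches[[i]]
    if (p$op == "softmax") {
      dcur <- (ca$probs - y_onehot) / N  # d(mean CE)/d(logits)
    } else if (p$op == "dense") {
      if (!is.null(ca$mask)) dcur <- dcur * ca$mask
      dz <- if (l$activation == "leaky_relu") leaky_bwd(dcur, ca$z, l$leaky_slope) else dcur
      grads[[i]] <- list(W = tcrossprod(dz, ca$x_in), b = rowSums(dz))
      dcur <- crossprod(pr$W, dz)
    } else if (p$op == "flatten") {
      dim(dcur) <- c(p$in_dim, length(dcur) / prod(p$in_dim))
    } else if (p$op == "pool") {
      dcur <- maxpool_bwd(dcur, ca$argmax, ca$in_len)
      dim(dcur) <- ca$in_dim
    } else if (p$op == "conv") {
      da <- if (l$activation == "leaky_relu") leaky_bwd(dcur, ca$a, l$leaky_slope) else dcur
      if (l$normalization == "group") {
        Nb <- dim(da)[length(dim(da))]
        nb <- gn_backward(da, ca$norm$xhat, ca$norm$inv, l$width,
                          prod(p$out_dim[-1]), Nb, l$groups, pr$gamma)
        dz <- nb$dx
        grads[[i]] <- list(gamma = nb$dgamma, beta = nb$dbeta)
      } else if (l$normalization == "batch") {
        nb <- bn_bwd_cf(da, ca$norm, pr$gamma)
        dz <- nb$dx
        grads[[i]] <- list(gamma = nb$dgamma, beta = nb$dbeta)
      } else {
        dz <- da
        grads[[i]] <- list()
      }
      dz_m <- dz; dim(dz_m) <- c(l$width, length(dz) / l$width)
      grads[[i]]$W <- tcrossprod(dz_m, ca$col)
      grads[[i]]$b <- rowSums(dz_m)
      if (i > 1) {  # no input gradient needed below the first layer
        dcol <- crossprod(pr$W, dz_m)
        Nb <- dim(dcur)[length(dim(dcur))]
        dcur <- col2im_nd(dcol, c(p$in_dim, Nb), p$k3, p$s3, p$pad3)
      } else dcur <- NULL
    }
  }
  grads
}

# convert stacked volumes (N, C, H, W) to the engine input layout
volumes_to_input <- function(volumes, arch = c("3d", "2d")) {
  arch <- match.arg(arch)
  d <- dim(volumes)
  if (length(d) == 3) { volumes <- array(volumes, c(1, d)); d <- dim(volumes) }
  x <- aperm(volumes, c(2, 3, 4, 1))  # (C, H, W, N)
  if (arch == "3d") {
    x <- array(x, c(1, d[2], d[3], d[4], d[1]))
  } else {
    x <- array(x, c(d[2], 1, d[3], d[4], d[1]))
  }
  x
}

#' Class probabilities for image volumes
#'
#' Runs the network in inference mode (dropout off, batch normalization on
#' running statistics). Output columns are softmax probabilities: each is
#' non-negative and sums to one; the row index of the maximum is the
#' predicted stage.
#'
#' @param net a fitted or freshly initialized network ([init_network()],
#'   [train_network()]).
#' @param volumes an `image_volume`, a list of them, or an array
#'   `(N, C, H, W)` (a single `(C, H, W)` volume is also accepted).
#' @param batch_size inference chunk size (memory control only).
#' @return Matrix `n_classes x N` of probabilities, with stage names as rows.
#' @export
predict_proba <- function(net, volumes, batch_size = 16L) {
  if (inherits(volumes, "image_volume")) volumes <- list(volumes)
  if (is.list(volumes) && !is.array(volumes)) {
    arr <- array(0, c(length(volumes), dim(volumes[[1]]$data)))
    for (i in seq_along(volumes)) arr[i, , , ] <- volumes[[i]]$data
    volumes <- arr
  }
  arch <- if (net$spec$name == "cnn3d") "3d" else "2d"
  d <- dim(volumes)
  if (length(d) == 3) { volumes <- array(volumes, c(1, d)); d <- dim(volumes) }
  expect_in <- net$spec$input_shape
  got <- if (arch == "3d") c(1L, d[2], d[3], d[4]) else c(d[2], d[3], d[4])
  if (!identical(as.integer(got), as.integer(expect_in))) {
    stop("volume shape (", paste(d[-1], collapse = "x"),
         ") does not match the network input (",
         paste(expect_in, collapse = "x"), ")")
  }
  N <- d[1]
  out <- matrix(0, net$spec$n_classes, N,
                dimnames = list(stage_levels()[seq_len(net$spec$n_classes)], NULL))
  for (start in seq(1, N, by = batch_size)) {
    idx <- start:min(N, start + batch_size - 1)
    x <- volumes_to_input(volumes[idx, , , , drop = FALSE], arch)
    out[, idx] <- network_forward(net, x, training = FALSE)$probs
  }
  out
}

#' Observed per-layer shapes on a probe batch
#'
#' Runs a real forward pass and records the dimensions of every layer's
#' output (batch axis dropped, depth-1 lifting removed), so the declarative
#' shape arithmetic of [output_shape()] can be checked against what the
#' engine actually produces.
#'
#' @param net a network from [init_network()].
#' @param n_probe probe batch size.
#' @return List of integer shape vectors, one per layer.
#' @export
probe_shapes <- function(net, n_probe = 2L) {
  spec <- net$spec
  in_dim <- c(spec$input_shape[1], lift3(spec$input_shape[-1]))
  x <- array(stats::rnorm(prod(in_dim) * n_probe), c(in_dim, n_probe))
  plans <- net$plans
  shapes <- vector("list", length(spec$layers))
  cur <- x
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]; p <- plans[[i]]; pr <- net$params[[i]]
    if (p$op == "conv") {
      col <- im2col_nd(cur, c(p$in_dim, n_probe), p$k3, p$s3, p$pad3)
      cur <- pr$W %*% col + pr$b
      dim(cur) <- c(l$width, p$out_dim[-1], n_probe)
    } else if (p$op == "pool") {
      cur <- maxpool_fwd(cur, c(p$in_dim, n_probe), p$k3, p$s3)$y
    } else if (p$op == "flatten") {
      dim(cur) <- c(p$out_dim, n_probe)
    } else if (p$op == "dense") {
      cur <- pr$W %*% cur + pr$b
    }
    d <- dim(cur)
    d <- d[-length(d)]                      # drop batch
    if (length(d) == 4 && length(spec$input_shape) == 3 &&
        spec$layers[[1]]$kind == "conv2d") d <- d[-2]  # unlift depth-1 axis
    shapes[[i]] <- as.integer(d)
  }
  shapes
}

#' Predicted stage labels
#' @inheritParams predict_proba
#' @return Character vector of stage labels, length N.
#' @export
predict_stage <- function(net, volumes, batch_size = 16L) {
  p <- predict_proba(net, volumes, batch_size)
  stage_levels()[apply(p, 2, which.max)]
}
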