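# Declarative CNN architecture descriptions. A model_spec is an ordered list
# of layer_spec rows; shape propagation (output_shape) is the contract the
# runnable engine (nn_engine.R) is tested against.

layer_kinds <- c("conv3d", "conv2d", "maxpool3d", "maxpool2d", "flatten",
                 "dense", "dropout", "softmax")

#' Declarative description of one network layer
#'
#' @param kind one of `conv3d`, `conv2d`, `maxpool3d`, `maxpool2d`,
#'   `flatten`, `dense`, `dropout`, `softmax`.
#' @param width output channels (conv) or units (dense/softmax).
#' @param kernel integer kernel size per spatial dim.
#' @param stride integer stride per spatial dim.
#' @param padding `"same"` or `"valid"` (convolutions; pooling is always
#'   valid-windowed).
#' @param normalization `"none"`, `"batch"` or `"group"`, applied after the
#'   convolution and before the activation.
#' @param activation `"none"` or `"leaky_relu"`.
#' @param leaky_slope negative-side slope of the leaky rectifier.
#' @param dropout_rate fraction of units dropped during training, in `[0,1)`.
#' @param groups group count for group normalization (must divide `width`).
#' @return A `layer_spec` list.
#' @export
layer_spec <- function(kind, width = NA_integer_, kernel = NULL, stride = NULL,
                       padding = "same", normalization = "none",
                       activation = "none", leaky_slope = 0.01,
                       dropout_rate = 0, groups = NA_integer_) {
  kind <- match.arg(kind, layer_kinds)
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  ndim <- switch(kind, conv3d = 3L, maxpool3d = 3L, conv2d = 2L, maxpool2d = 2L, 0L)
  if (ndim > 0) {
    if (length(kernel) != ndim || length(stride) != ndim) {
      stop(kind, " needs kernel and stride of length ", ndim)
    }
  }
  if (normalization == "group") {
    if (is.na(groups)) stop("group normalization needs a group count")
    if (width %% groups != 0) stop("groups must divide the layer width")
  }
  structure(list(kind = kind, width = as.integer(width),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 padding = match.arg(padding, c("same", "valid")),
                 normalization = match.arg(normalization, c("none", "batch", "group")),
                 activation = match.arg(activation, c("none", "leaky_relu")),
                 leaky_slope = leaky_slope, dropout_rate = dropout_rate,
                 groups = as.integer(groups)), class = "layer_spec")
}

#' @rdname layer_spec
#' @param name model name.
#' @param input_shape input shape excluding batch: `(1, D, H, W)` semantics
#'   for the 3D net (a one-feature-channel volume of depth D), `(C, H, W)`
#'   for the 2D net.
#' @param layers ordered list of [layer_spec()]s; the last must be `softmax`.
#' @param n_classes number of output classes.
#' @export
model_spec <- function(name, input_shape, layers, n_classes = 3L) {
  if (layers[[length(layers)]]$kind != "softmax") {
    stop("the last layer must be softmax")
  }
  if (layers[[length(layers)]]$width != n_classes) {
    stop("softmax width must equal n_classes")
  }
  structure(list(name = name, input_shape = as.integer(input_shape),
                 layers = layers, n_classes = as.integer(n_classes)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s: input (%s), %d layers, %d classes\n", x$name,
              paste(x$input_shape, collapse = ","), length(x$layers), x$n_classes))
  for (l in x$layers) {
    cat(sprintf("  %-9s w=%-5s k=%-7s s=%-7s %s %s%s\n", l$kind,
                ifelse(is.na(l$width), "", l$width),
                paste(l$kernel, collapse = "x"), paste(l$stride, collapse = "x"),
                ifelse(l$normalization == "none", "", l$normalization),
                ifelse(l$activation == "none", "", l$activation),
                ifelse(l$dropout_rate > 0, sprintf(" drop=%.2f", l$dropout_rate), "")))
  }
  invisible(x)
}

# largest divisor of width not exceeding the requested group count
fit_groups <- function(width, groups) {
  g <- min(groups, width)
  while (width %% g != 0) g <- g - 1
  as.integer(g)
}

#' Build the 3D-kernel CNN architecture
#'
#' Four 3x3x3 convolution blocks (64, 128, 256, 256 channels, stride 1,
#' leaky rectifier slope 0.01, normalization before activation), three
#' 2x2x2 max-pools (strides 2x2x2, 1x2x2, 1x2x2 -- the depth axis is pooled
#' only once so channel information is retained), then fully connected
#' layers of 4096 and 2048 units with dropout, and a 3-way softmax. The
#' input is a one-feature-channel volume `(depth = n EEG channels, H, W)`.
#'
#' `width_scale` shrinks every width by the same factor for desk-scale
#' experiments without altering the layer stack.
#'
#' @param input_shape `(D, H, W)`: EEG-channel depth and image side.
#' @param n_classes output classes.
#' @param norm `"group"` (default), `"batch"` or `"none"`.
#' @param groups requested group count for group normalization; per layer
#'   the largest divisor of the width not exceeding this is used.
#' @param dropout dropout rate on the fully connected layers.
#' @param padding `"same"` (default) or `"valid"` convolution padding.
#' @param width_scale multiplier on all widths (1 = full scale).
#' @return A [model_spec()].
#' @export
build_3d_cnn <- function(input_shape = c(22, 256, 256), n_classes = 3,
                         norm = "group", groups = 32, dropout = 0.5,
                         padding = "same", width_scale = 1) {
  w <- function(x) max(1L, as.integer(round(x * width_scale)))
  conv <- function(width) layer_spec("conv3d", w(width), kernel = c(3, 3, 3),
    stride = c(1, 1, 1), padding = padding, normalization = norm,
    activation = "leaky_relu", leaky_slope = 0.01,
    groups = if (norm == "group") fit_groups(w(width), groups) else NA_integer_)
  pool <- function(stride) layer_spec("maxpool3d", kernel = c(2, 2, 2), stride = stride)
  layers <- list(
    conv(64), pool(c(2, 2, 2)),
    conv(128), pool(c(1, 2, 2)),
    conv(256), conv(256), pool(c(1, 2, 2)),
    layer_spec("flatten"),
    layer_spec("dense", w(4096), activation = "leaky_relu", dropout_rate = dropout),
    layer_spec("dense", w(2048), activation = "leaky_relu", dropout_rate = dropout),
    layer_spec("dense", n_classes),
    layer_spec("softmax", n_classes))
  spec <- model_spec("cnn3d", c(1L, input_shape), layers, n_classes)
  output_shape(spec)  # fail early if the pooling cascade exhausts a dim
  spec
}

#' Build the 2D CNN baseline architecture
#'
#' Five convolution blocks (32@5x5 then 64/128/256/256@3x3, stride 1, batch
#' normalization + leaky rectifier), each followed by a max-pool (3x3 stride
#' 2, then 2x2 stride 2), fully connected layers of 2048 and 1024 units with
#' dropout 0.5, and a 3-way softmax. EEG channels enter as image channels:
#' `input_shape = (22, 256, 256)` for multi-channel, `(1, 256, 256)` for
#' single-channel experiments.
#'
#' @inheritParams build_3d_cnn
#' @return A [model_spec()].
#' @export
build_2d_cnn <- function(input_shape = c(22, 256, 256), n_classes = 3,
                         norm = "batch", groups = 32, dropout = 0.5,
                         padding = "same", width_scale = 1) {
  w <- function(x) max(1L, as.integer(round(x * width_scale)))
  conv <- function(width, k) layer_spec("conv2d", w(width), kernel = c(k, k),
    stride = c(1, 1), padding = padding, normalization = norm,
    activation = "leaky_relu", leaky_slope = 0.01,
    groups = if (norm == "group") fit_groups(w(width), groups) else NA_integer_)
  pool <- function(k) layer_spec("maxpool2d", kernel = c(k, k), stride = c(2, 2))
  layers <- list(
    conv(32, 5), pool(3),
    conv(64, 3), pool(2),
    conv(128, 3), pool(2),
    conv(256, 3), pool(2),
    conv(256, 3), pool(2),
    layer_spec("flatten"),
    layer_spec("dense", w(2048), dropout_rate = dropout),
    layer_spec("dense", w(1024), dropout_rate = dropout),
    layer_spec("dense", n_classes),
    layer_spec("softmax", n_classes))
  spec <- model_spec("cnn2d", input_shape, layers, n_classes)
  output_shape(spec)
  spec
}

conv_out_dim <- function(d, k, s, padding) {
  if (padding == "same") as.integer(ceiling(d / s))
  else as.integer(floor((d - k) / s) + 1)
}

pool_out_dim <- function(d, k, s) as.integer(floor((d - k) / s) + 1)

# symmetric-ish zero padding: left pad = floor(total/2)
same_pad <- function(d, k, s) {
  out <- ceiling(d / s)
  total <- max((out - 1) * s + k - d, 0)
  as.integer(floor(total / 2))
}

#' Per-layer output shapes of an architecture
#'
#' Propagates the input shape through the stack: same-padded convolutions
#' preserve spatial dims (stride 1), valid convolutions shrink by k - 1, and
#' pools follow `floor((in - k) / s) + 1`. Shapes are
#' `(feature channels, spatial...)` until `flatten`, unit counts after.
#'
#' @param spec a [model_spec()].
#' @param input_shape optional override of `spec$input_shape`.
#' @return List with one shape (integer vector) per layer.
#' @export
output_shape <- function(spec, input_shape = NULL) {
  shape <- as.integer(if (is.null(input_shape)) spec$input_shape else input_shape)
  out <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    if (l$kind %in% c("conv3d", "conv2d")) {
      sp <- shape[-1]
      sp_out <- mapply(conv_out_dim, sp, l$kernel, l$stride,
                       MoreArgs = list(padding = l$padding))
      if (any(sp_out < 1)) stop(sprintf("layer %d (%s): non-positive output dim", i, l$kind))
      shape <- c(l$width, as.integer(sp_out))
    } else if (l$kind %in% c("maxpool3d", "maxpool2d")) {
      sp <- shape[-1]
      sp_out <- mapply(pool_out_dim, sp, l$kernel, l$stride)
      if (any(sp_out < 1)) stop(sprintf("layer %d (%s): input smaller than pooling window", i, l$kind))
      shape <- c(shape[1], as.integer(sp_out))
    } else if (l$kind == "flatten") {
      shape <- prod(shape)
    } else if (l$kind == "dense") {
      if (length(shape) != 1) stop(sprintf("layer %d (dense): input not flattened", i))
      shape <- l$width
    } else if (l$kind %in% c("dropout", "softmax")) {
      # shape preserved
    }
    out[[i]] <- as.integer(shape)
  }
  out
}

#' Group normalization
#'
#' Per sample, channels are partitioned into `groups` contiguous groups and
#' each group is standardized by its own mean and (population) variance over
#' all its channels and spatial positions; a per-channel affine
#' `gamma`/`beta` is then applied. With `groups = C` this is instance
#' normalization; with `groups = 1` it standardizes the whole sample.
#' Independent of batch size, which is why it replaces batch normalization
#' when batches are small.
#'
#' @param x array `(batch, C, spatial...)`.
#' @param groups number of channel groups; must divide C.
#' @param eps variance floor.
#' @param gamma,beta per-channel scale and shift (default 1 and 0).
#' @return Array of the same shape as `x`.
#' @export
group_normalize <- function(x, groups, eps = 1e-5, gamma = NULL, beta = NULL) {
  d <- dim(x)
  if (is.null(d) || length(d) < 2) stop("x must be an array (batch, C, spatial...)")
  N <- d[1]; C <- d[2]; S <- if (length(d) > 2) prod(d[-(1:2)]) else 1L
  if (C %% groups != 0) stop("groups (", groups, ") must divide the channel count (", C, ")")
  cg <- C %/% groups
  m <- array(x, c(N, C, S))
  y <- array(0, c(N, C, S))
  if (is.null(gamma)) gamma <- rep(1, C)
  if (is.null(beta)) beta <- rep(0, C)
  for (g in seq_len(groups)) {
    ch <- ((g - 1) * cg + 1):(g * cg)
    sub <- m[, ch, , drop = FALSE]                       # (N, cg, S)
    flat <- array(aperm(sub, c(2, 3, 1)), c(cg * S, N))  # per-sample columns
    mu <- colMeans(flat)
    v <- colMeans(flat^2) - mu^2
    xhat <- (flat - rep(mu, each = cg * S)) / rep(sqrt(v + eps), each = cg * S)
    xhat <- aperm(array(xhat, c(cg, S, N)), c(3, 1, 2))  # (N, cg, S)
    y[, ch, ] <- xhat * rep(gamma[ch], each = N) + rep(beta[ch], each = N)
  }
  array(y, d)
}

#' Serialize an architecture to JSON
#'
#' Layer-by-layer dump of every field so architectures are diffable.
#'
#' @param spec a [model_spec()].
#' @param path optional file to write to.
#' @return JSON string, invisibly if written to file.
#' @export
model_to_json <- function(spec, path = NULL) {
  obj <- list(name = spec$name, input_shape = spec$input_shape,
              n_classes = spec$n_classes,
              layers = lapply(spec$layers, function(l) l[!vapply(l, function(f)
                length(f) == 0, TRUE)]))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
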