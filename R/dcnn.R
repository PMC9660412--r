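# Light/medium/heavy convolutional architectures over (time x channel) EEG
# window planes: valid cross-correlation layers, max/stochastic pooling, a
# softmax (or logistic) decision head and a squared-error cost.

layer_conv <- function(kernel, n_filters, activation = "tanh") {
  list(kind = "conv", kernel = as.integer(kernel), n_filters = as.integer(n_filters),
       activation = activation)
}
layer_pool <- function(pool_size = 2L, stride = 2L, pool_mode = "stochastic") {
  list(kind = "pool", pool_size = as.integer(pool_size), stride = as.integer(stride),
       pool_mode = pool_mode)
}
layer_dense <- function(units, activation = "tanh") {
  list(kind = "dense", units = as.integer(units), activation = activation)
}
layer_head <- function(n_classes, type = "softmax") {
  list(kind = "softmax", n_classes = as.integer(n_classes), type = type)
}

#' Build a light/medium/heavy network architecture
#'
#' The medium-weight network is the reference 7-layer stack: Conv1 10x1
#' (20 filters), Conv2 20x23 (20 filters), stochastic pool 2x1 stride 2,
#' Conv3 10x1 over 20 maps (40 filters), stochastic pool 2x1 stride 2,
#' Conv4 10x1 over 40 maps (80 filters), softmax head with 2 or 3 classes.
#' The light variant (4 layers) keeps the first two convolutions and one
#' pool; the heavy variant (9 layers) extends the medium stack with an extra
#' convolution and a dense layer. Kernels use valid (no padding)
#' cross-correlation; a kernel longer than the remaining extent is clipped to
#' it, with a warning.
#'
#' @param weight_class `"lw"`, `"mw"` or `"hw"`.
#' @param n_classes 2 or 3.
#' @param input_shape `c(samples_per_window, n_channels)` of the input plane
#'   (default `c(77, 23)`: 300 ms at 256 Hz over the 23-channel montage).
#' @param pool_mode Pooling used by the pooling layers (default
#'   `"stochastic"`; `"max"` available).
#' @param activation Activation of conv/dense layers: `"tanh"` (default) or
#'   `"sigmoid"`.
#' @return An object of class `architecture_spec` with the ordered layer list
#'   and the per-layer input/output shapes.
#' @examples
#' arch <- build_architecture("mw", n_classes = 2)
#' arch
#' @export
build_architecture <- function(weight_class = c("mw", "lw", "hw"), n_classes = 2L,
                               input_shape = c(77L, 23L), pool_mode = "stochastic",
                               activation = "tanh") {
  weight_class <- match.arg(weight_class)
  if (!n_classes %in% c(2L, 3L)) fail_field("n_classes", "must be 2 or 3")
  nc <- as.integer(input_shape[2])
  layers <- switch(weight_class,
    lw = list(layer_conv(c(10L, 1L), 20L, activation),
              layer_conv(c(20L, nc), 20L, activation),
              layer_pool(2L, 2L, pool_mode),
              layer_head(n_classes)),
    mw = list(layer_conv(c(10L, 1L), 20L, activation),
              layer_conv(c(20L, nc), 20L, activation),
              layer_pool(2L, 2L, pool_mode),
              layer_conv(c(10L, 1L), 40L, activation),
              layer_pool(2L, 2L, pool_mode),
              layer_conv(c(10L, 1L), 80L, activation),
              layer_head(n_classes)),
    hw = list(layer_conv(c(10L, 1L), 20L, activation),
              layer_conv(c(20L, nc), 20L, activation),
              layer_pool(2L, 2L, pool_mode),
              layer_conv(c(10L, 1L), 40L, activation),
              layer_pool(2L, 2L, pool_mode),
              layer_conv(c(10L, 1L), 40L, activation),
              layer_conv(c(10L, 1L), 80L, activation),
              layer_dense(64L, activation),
              layer_head(n_classes))
  )
  arch <- structure(list(weight_class = weight_class, layers = layers,
                         n_classes = as.integer(n_classes),
                         input_shape = as.integer(input_shape)),
                    class = "architecture_spec")
  resolved <- plan_shapes(arch)      # validates, clips kernels, warns
  arch$layers <- resolved$layers
  arch$shapes <- resolved$shapes
  arch
}

# resolve per-layer input/output shapes c(T, C, D); clip oversized kernels
plan_shapes <- function(arch) {
  shp <- c(arch$input_shape, 1L)
  shapes <- vector("list", length(arch$layers))
  for (i in seq_along(arch$layers)) {
    ly <- arch$layers[[i]]
    if (ly$kind == "conv") {
      k <- ly$kernel
      clipped <- pmin(k, shp[1:2])
      if (any(clipped < k)) {
        warn(sprintf("layer %d: %dx%d kernel clipped to %dx%d to fit a %dx%d input",
                     i, k[1], k[2], clipped[1], clipped[2], shp[1], shp[2]),
             class = "eegseize_kernel_clip")
        ly$kernel <- clipped
        arch$layers[[i]] <- ly
        k <- clipped
      }
      if (any(k < 1L)) {
        abort(sprintf("layer %d: input %dx%d too small for its kernel", i, shp[1], shp[2]),
              class = "eegseize_shape_error")
      }
      out <- c(shp[1] - k[1] + 1L, shp[2] - k[2] + 1L, ly$n_filters)
    } else if (ly$kind == "pool") {
      if (ly$pool_size > shp[1]) {
        abort(sprintf("layer %d: pool size %d exceeds the %d-sample extent",
                      i, ly$pool_size, shp[1]), class = "eegseize_shape_error")
      }
      out <- c((shp[1] - ly$pool_size) %/% ly$stride + 1L, shp[2], shp[3])
    } else if (ly$kind == "dense") {
      out <- c(ly$units, 1L, 1L)
    } else {
      out <- c(ly$n_classes, 1L, 1L)
    }
    shapes[[i]] <- list(kernel = if (ly$kind == "conv") ly$kernel else NULL,
                        input = shp, output = out)
    shp <- out
  }
  list(shapes = shapes, layers = arch$layers)
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf("<architecture_spec> %s, %d classes, input %d x %d\n",
              x$weight_class, x$n_classes, x$input_shape[1], x$input_shape[2]))
  for (i in seq_along(x$layers)) {
    ly <- x$layers[[i]]
    s <- x$shapes[[i]]
    desc <- switch(ly$kind,
      conv = sprintf("conv %dx%d, %d filters (%s)", s$kernel[1], s$kernel[2],
                     ly$n_filters, ly$activation),
      pool = sprintf("pool %dx1 stride %d (%s)", ly$pool_size, ly$stride, ly$pool_mode),
      dense = sprintf("dense %d (%s)", ly$units, ly$activation),
      softmax = sprintf("%s head, %d classes", ly$type, ly$n_classes))
    cat(sprintf("  %d. %-34s %s -> %s\n", i, desc,
                paste(s$input, collapse = "x"), paste(s$output, collapse = "x")))
  }
  invisible(x)
}

#' Number of trainable layers in an architecture
#' @param arch An `architecture_spec`.
#' @return Integer layer count (conv + pool + dense + head).
#' @export
n_layers <- function(arch) length(arch$layers)

activation_fun <- function(name) {
  switch(name,
         tanh = tanh,
         sigmoid = function(z) 1 / (1 + exp(-z)),
         identity = identity,
         fail_field("activation", "must be tanh, sigmoid or identity"))
}
# derivative expressed through the activation value
activation_dfun <- function(name) {
  switch(name,
         tanh = function(a) 1 - a^2,
         sigmoid = function(a) a * (1 - a),
         identity = function(a) rep(1, length(a)))
}

#' Convolution layer forward pass
#'
#' Valid (no padding) cross-correlation of an input tensor with a bank of
#' kernels spanning the full input depth, plus bias and activation. The
#' output spatial extent is `input - kernel + 1` on each axis.
#'
#' @param input Numeric array: `(time, channel)` matrix, `(time, channel,
#'   depth)` array, or `(time, channel, depth, batch)` array.
#' @param layer A conv layer description (see [build_architecture()]); its
#'   `activation` may be `"tanh"`, `"sigmoid"` or `"identity"`.
#' @param weights Kernel array `(k_time, k_channel, depth, n_filters)` (a
#'   `(k_time, k_channel)` matrix is a single depth-1 filter).
#' @param biases Numeric vector, one per filter.
#' @return Array `(time_out, channel_out, n_filters[, batch])`; the batch
#'   axis is kept only if the input had one.
#' @examples
#' x <- matrix(rnorm(15), 5, 3)
#' ly <- list(kind = "conv", kernel = c(2L, 2L), n_filters = 1L, activation = "identity")
#' dim(conv_forward(x, ly, array(rnorm(4), c(2, 2, 1, 1)), 0))
#' @export
conv_forward <- function(input, layer, weights, biases) {
  if (is.matrix(weights)) weights <- array(weights, c(dim(weights), 1L, 1L))
  kd <- dim(weights)
  if (length(kd) == 3L) { weights <- array(weights, c(kd, 1L)); kd <- dim(weights) }
  had_batch <- length(dim(input) %||% NULL) == 4L
  x <- as_plane_array(input)
  d <- dim(x)
  if (!identical(kd[3], d[3])) {
    abort(sprintf("kernel depth %d does not match input depth %d", kd[3], d[3]),
          class = "eegseize_shape_error")
  }
  if (kd[1] > d[1] || kd[2] > d[2]) {
    abort("kernel exceeds the input extent", class = "eegseize_shape_error")
  }
  n_filters <- kd[4]
  if (length(biases) == 1L) biases <- rep(biases, n_filters)
  if (length(biases) != n_filters) {
    abort("one bias per filter is required", class = "eegseize_shape_error")
  }
  geom <- conv_geometry(d[1:3], kd[1:2])
  W <- t(matrix(weights, ncol = n_filters))      # n_filters x K
  x_mat <- matrix(x, ncol = d[4])
  patches <- x_mat[as.vector(geom$idx), , drop = FALSE]
  dim(patches) <- c(geom$K, geom$P * d[4])
  z <- W %*% patches + biases
  f <- activation_fun(layer$activation %||% "tanh")
  a <- f(z)
  dim(a) <- c(n_filters, geom$P, d[4])
  out <- aperm(a, c(2L, 1L, 3L))
  dim(out) <- c(geom$out[1], geom$out[2], n_filters, d[4])
  if (had_batch) out else array(out, dim(out)[1:3])
}

# coerce (T,C), (T,C,D) or (T,C,D,N) to (T,C,D,N)
as_plane_array <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  else if (length(dim(x)) == 3L) x <- array(x, c(dim(x), 1L))
  else if (length(dim(x)) != 4L) fail_field("input", "must have 2-4 dimensions")
  x
}

# im2col geometry for a (T, C, D) input and (kt, kc) kernel over full depth
conv_geometry <- function(in_shape, kernel) {
  T_ <- in_shape[1]; C_ <- in_shape[2]; D_ <- in_shape[3]
  kt <- kernel[1]; kc <- kernel[2]
  To <- T_ - kt + 1L; Co <- C_ - kc + 1L
  off <- as.vector(outer(0:(kt - 1L),
                         as.vector(outer((0:(kc - 1L)) * T_, (0:(D_ - 1L)) * T_ * C_, "+")),
                         "+"))
  pos <- as.vector(outer(0:(To - 1L), (0:(Co - 1L)) * T_, "+"))
  idx <- outer(off, pos, "+") + 1L
  list(idx = idx, K = length(off), P = length(pos), out = c(To, Co))
}

#' Pool feature-map regions along the time axis
#'
#' `mode = "max"` takes the maximum of each region. `mode = "stochastic"`
#' shifts each region to be non-negative and, during training, samples one
#' activation with probability proportional to the shifted values (uniform
#' when the region is constant); at inference (`expectation = TRUE`) it
#' returns the probability-weighted mean, which is deterministic.
#'
#' @param x Numeric vector, or `(time, channel, depth[, batch])` array.
#' @param pool_size Region length along the time axis.
#' @param stride Step between regions (>= 1).
#' @param mode `"max"` or `"stochastic"`.
#' @param seed Optional seed for reproducible stochastic sampling.
#' @param expectation If `TRUE`, stochastic mode returns the expected value
#'   instead of sampling.
#' @return Pooled vector or array with `floor((time - pool_size) / stride) + 1`
#'   time steps.
#' @examples
#' pool(c(1, 3, 2), pool_size = 3, stride = 3, mode = "max")  # 3
#' @export
pool <- function(x, pool_size = 2L, stride = 2L, mode = c("max", "stochastic"),
                 seed = NULL, expectation = FALSE) {
  mode <- match.arg(mode)
  was_vector <- is.null(dim(x))
  if (was_vector) x <- array(x, c(length(x), 1L, 1L, 1L))
  x <- as_plane_array(x)
  if (pool_size < 1L || stride < 1L || pool_size > dim(x)[1]) {
    abort("invalid pooling region geometry", class = "eegseize_shape_error")
  }
  res <- with_rng(seed, pool_fwd(x, pool_size, stride, mode, expectation))
  if (was_vector) as.vector(res$out) else res$out
}

# internal pooling core; also returns the selection needed for backprop
pool_fwd <- function(x, pt, st, mode, expectation) {
  d <- dim(x)
  To <- (d[1] - pt) %/% st + 1L
  starts <- seq.int(1L, by = st, length.out = To)
  slabs <- lapply(seq_len(pt), function(j) {
    x[starts + j - 1L, , , , drop = FALSE]
  })
  if (mode == "max") {
    # first-argmax tie-break
    sel <- array(1L, dim(slabs[[1]]))
    best <- slabs[[1]]
    for (j in seq_len(pt)[-1]) {
      better <- slabs[[j]] > best
      sel[better] <- j
      best[better] <- slabs[[j]][better]
    }
    return(list(out = best, sel = sel, starts = starts))
  }
  minv <- Reduce(pmin, slabs)
  wts <- lapply(slabs, function(s) s - minv)
  tot <- Reduce(`+`, wts)
  zero <- tot == 0
  probs <- lapply(wts, function(w) {
    p <- w / ifelse(zero, 1, tot)
    p[zero] <- 1 / pt
    p
  })
  if (expectation) {
    out <- Reduce(`+`, Map(`*`, probs, slabs))
    return(list(out = out, sel = NULL, starts = starts))
  }
  u <- array(runif(length(slabs[[1]])), dim(slabs[[1]]))
  cum <- array(0, dim(u))
  sel <- array(pt, dim(u))
  assigned <- array(FALSE, dim(u))
  for (j in seq_len(pt)) {
    cum <- cum + probs[[j]]
    take <- !assigned & u < cum
    sel[take] <- j
    assigned <- assigned | take
  }
  out <- slabs[[1]]
  for (j in seq_len(pt)[-1]) {
    pick <- sel == j
    out[pick] <- slabs[[j]][pick]
  }
  list(out = out, sel = sel, starts = starts)
}

#' Decision head: class scores from flattened features
#'
#' Default is a softmax over affine logits; for two classes a single-logit
#' logistic unit `1 / (1 + exp(-theta' x))` is available. Scores sum to 1
#' across classes.
#'
#' @param features Numeric vector (one sample) or features-by-samples matrix.
#' @param theta List with `W` (n_classes x n_features logits matrix, or a
#'   single row for the logistic head) and `b` (per-class bias).
#' @param type `"softmax"` or `"logistic"`.
#' @return Samples-by-classes score matrix.
#' @examples
#' decision_head(0, list(W = matrix(1), b = 0), type = "logistic")  # 0.5, 0.5
#' @export
decision_head <- function(features, theta, type = c("softmax", "logistic")) {
  type <- match.arg(type)
  if (is.vector(features)) features <- matrix(features, ncol = 1L)
  if (ncol(theta$W) != nrow(features)) {
    abort(sprintf("feature length %d does not match theta width %d",
                  nrow(features), ncol(theta$W)), class = "eegseize_shape_error")
  }
  z <- theta$W %*% features + theta$b
  if (type == "logistic") {
    if (nrow(z) != 1L) {
      abort("the logistic head uses a single logit", class = "eegseize_shape_error")
    }
    p <- 1 / (1 + exp(-z))
    return(t(rbind(1 - p, p)))
  }
  t(softmax_cols(z))
}

softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

#' Squared-error cost between scores and one-hot targets
#'
#' `0.5 * sum((targets - scores)^2)` over all samples and classes; zero iff
#' the prediction matches the target exactly, and invariant to sample order.
#'
#' @param scores Samples-by-classes score matrix (or vector for one sample).
#' @param targets One-hot matrix of the same shape.
#' @return Non-negative scalar.
#' @examples
#' sef_loss(c(0, 1), c(1, 0))  # 1
#' @export
sef_loss <- function(scores, targets) {
  if (is.vector(scores)) scores <- matrix(scores, nrow = 1L)
  if (is.vector(targets)) targets <- matrix(targets, nrow = 1L)
  if (!identical(dim(scores), dim(targets))) {
    abort("scores and targets must have identical shapes", class = "eegseize_shape_error")
  }
  if (any(!targets %in% c(0, 1)) || any(rowSums(targets) != 1)) {
    abort("targets must be one-hot", class = "eegseize_shape_error")
  }
  0.5 * sum((targets - scores)^2)
}
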