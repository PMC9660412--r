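# Forward/backward engine and RMSprop training loop. Feature maps are carried
# as flattened (prod(shape) x batch) matrices; convolutions run as im2col
# patch-matrix products so the heavy lifting is BLAS, and the conv backward
# scatter reuses a cached sparse accumulation matrix per layer.

# geometry + scatter operators resolved once per (arch, input shape).
# Conv layers that collapse the channel axis (kernel width == input width)
# use a "stacked shift" formulation: all time offsets of the kernel are
# stacked into one weight matrix so forward, weight-gradient and
# input-gradient are each a single large BLAS product. Other conv layers
# (small kernels) use im2col with a cached sparse scatter for the backward.
build_plan <- function(arch) {
  plan <- vector("list", length(arch$layers))
  for (i in seq_along(arch$layers)) {
    ly <- arch$layers[[i]]
    shp <- arch$shapes[[i]]
    p <- list(layer = ly, input = shp$input, output = shp$output)
    if (ly$kind == "conv") {
      p$kernel <- shp$kernel
      p$shift_path <- shp$kernel[2] == shp$input[2]
      if (p$shift_path) {
        p$kt <- shp$kernel[1]
        p$cd <- shp$input[2] * shp$input[3]
        p$To <- shp$output[1]
      } else {
        g <- conv_geometry(shp$input, shp$kernel)
        p$geom <- g
        p$scatter <- Matrix::sparseMatrix(
          i = as.vector(g$idx), j = seq_len(g$K * g$P), x = 1,
          dims = c(prod(shp$input), g$K * g$P))
      }
    } else if (ly$kind == "pool") {
      p$To <- shp$output[1]
      p$starts <- seq.int(1L, by = ly$stride, length.out = shp$output[1])
    }
    plan[[i]] <- p
  }
  plan
}

init_params <- function(plan, seed) {
  with_rng(seed, lapply(plan, function(p) {
    ly <- p$layer
    if (ly$kind == "conv") {
      K <- prod(p$kernel) * p$input[3]; f <- ly$n_filters
      lim <- sqrt(6 / (K + f))
      list(W = matrix(runif(f * K, -lim, lim), f, K), b = numeric(f))
    } else if (ly$kind == "dense") {
      fin <- prod(p$input); f <- ly$units
      lim <- sqrt(6 / (fin + f))
      list(W = matrix(runif(f * fin, -lim, lim), f, fin), b = numeric(f))
    } else if (ly$kind == "softmax") {
      fin <- prod(p$input); f <- ly$n_classes
      lim <- sqrt(6 / (fin + f))
      list(W = matrix(runif(f * fin, -lim, lim), f, fin), b = numeric(f))
    } else {
      NULL
    }
  }))
}

# x: (prod(input_shape) x N) matrix. Returns scores (N x K) and, if collect,
# the per-layer caches needed for the backward pass. Stochastic pooling
# samples in "train" mode (uses the current RNG stream) and takes the
# expectation in "infer" mode.
net_forward <- function(plan, params, x, mode = "infer", collect = FALSE) {
  n <- ncol(x)
  caches <- if (collect) vector("list", length(plan))
  for (i in seq_along(plan)) {
    p <- plan[[i]]
    ly <- p$layer
    if (ly$kind == "conv") {
      f <- ly$n_filters
      if (p$shift_path) {
        T_ <- p$input[1]; kt <- p$kt; cd <- p$cd; To <- p$To
        xr <- aperm(array(x, c(T_, cd, n)), c(2L, 1L, 3L))
        dim(xr) <- c(cd, T_ * n)
        wst <- matrix(params[[i]]$W, f * kt, cd)   # rows (filter, offset)
        y <- wst %*% xr
        dim(y) <- c(f, kt, T_, n)
        z <- array(0, c(f, To, n))
        for (dt in seq_len(kt)) {
          ys <- y[, dt, dt:(dt + To - 1L), , drop = FALSE]
          dim(ys) <- c(f, To, n)
          z <- z + ys
        }
        z <- z + params[[i]]$b
        a <- activation_fun(ly$activation)(z)
        if (collect) caches[[i]] <- list(xr = xr, act = a)
        x <- aperm(a, c(2L, 1L, 3L))               # (To, f, n)
        dim(x) <- c(To * f, n)
      } else {
        g <- p$geom
        patches <- x[as.vector(g$idx), , drop = FALSE]
        dim(patches) <- c(g$K, g$P * n)
        z <- params[[i]]$W %*% patches + params[[i]]$b
        a <- activation_fun(ly$activation)(z)
        if (collect) caches[[i]] <- list(patches = patches, act = a)
        dim(a) <- c(f, g$P, n)
        x <- aperm(a, c(2L, 1L, 3L))
        dim(x) <- c(g$P * f, n)
      }
    } else if (ly$kind == "pool") {
      xa <- x
      dim(xa) <- c(p$input, n)
      res <- pool_fwd(xa, ly$pool_size, ly$stride, ly$pool_mode,
                      expectation = ly$pool_mode == "stochastic" && mode == "infer")
      if (collect) caches[[i]] <- list(sel = res$sel, starts = res$starts)
      x <- matrix(res$out, ncol = n)
    } else if (ly$kind == "dense") {
      z <- params[[i]]$W %*% x + params[[i]]$b
      a <- activation_fun(ly$activation)(z)
      if (collect) caches[[i]] <- list(input = x, act = a)
      x <- a
    } else {
      z <- params[[i]]$W %*% x + params[[i]]$b
      y <- softmax_cols(z)
      if (collect) caches[[i]] <- list(input = x, scores = y)
      x <- y
    }
  }
  list(scores = t(x), caches = caches)
}

# squared-error loss and its gradients w.r.t. every parameter, for one batch.
# tmat: one-hot targets (N x K). Pooling selections are those drawn in the
# forward pass (mode "train") or the max mask.
net_loss_grad <- function(plan, params, x, tmat, mode = "train") {
  n <- ncol(x)
  fw <- net_forward(plan, params, x, mode = mode, collect = TRUE)
  y <- fw$scores
  loss <- 0.5 * sum((tmat - y)^2)
  grads <- vector("list", length(plan))
  # softmax + SEF: dz_i = y_i * (g_i - sum_j y_j g_j), g = y - t (per sample)
  i <- length(plan)
  yt <- t(y); gt <- t(y - tmat)
  s <- yt * gt
  dz <- s - yt * matrix(colSums(s), nrow(yt), n, byrow = TRUE)
  feat <- fw$caches[[i]]$input
  grads[[i]] <- list(W = dz %*% t(feat), b = rowSums(dz))
  dx <- t(params[[i]]$W) %*% dz
  for (i in rev(seq_len(length(plan) - 1L))) {
    p <- plan[[i]]
    ly <- p$layer
    if (ly$kind == "dense") {
      a <- fw$caches[[i]]$act
      dz <- dx * activation_dfun(ly$activation)(a)
      grads[[i]] <- list(W = dz %*% t(fw$caches[[i]]$input), b = rowSums(dz))
      dx <- t(params[[i]]$W) %*% dz
    } else if (ly$kind == "pool") {
      cache <- fw$caches[[i]]
      din <- array(0, c(p$input, n))
      dout <- array(dx, c(p$output, n))
      for (j in seq_len(ly$pool_size)) {
        mask <- cache$sel == j
        if (any(mask)) {
          rows <- cache$starts + j - 1L
          slab <- din[rows, , , , drop = FALSE]
          slab[mask] <- slab[mask] + dout[mask]
          din[rows, , , ] <- slab
        }
      }
      dx <- matrix(din, ncol = n)
    } else if (ly$kind == "conv") {
      f <- ly$n_filters
      if (p$shift_path) {
        T_ <- p$input[1]; kt <- p$kt; cd <- p$cd; To <- p$To
        a <- fw$caches[[i]]$act               # (f, To, n)
        dz <- aperm(array(dx, c(To, f, n)), c(2L, 1L, 3L))
        dz <- dz * activation_dfun(ly$activation)(a)
        dzpad <- array(0, c(f, kt, T_, n))
        for (dt in seq_len(kt)) dzpad[, dt, dt:(dt + To - 1L), ] <- dz
        dim(dzpad) <- c(f * kt, T_ * n)
        xr <- fw$caches[[i]]$xr               # (cd, T*n)
        dwst <- tcrossprod(dzpad, xr)         # (f*kt) x cd
        grads[[i]] <- list(W = matrix(dwst, f, kt * cd), b = rowSums(dz))
        dxr <- crossprod(matrix(params[[i]]$W, f * kt, cd), dzpad)  # cd x T*n
        dxa <- aperm(array(dxr, c(cd, T_, n)), c(2L, 1L, 3L))
        dx <- matrix(dxa, ncol = n)
      } else {
        g <- p$geom
        a <- fw$caches[[i]]$act               # (F x P*N)
        dout <- array(dx, c(g$P, f, n))
        dz <- aperm(dout, c(2L, 1L, 3L))
        dim(dz) <- c(f, g$P * n)
        dz <- dz * activation_dfun(ly$activation)(a)
        patches <- fw$caches[[i]]$patches
        grads[[i]] <- list(W = tcrossprod(dz, patches), b = rowSums(dz))
        dpatch <- crossprod(params[[i]]$W, dz)  # (K x P*N)
        dim(dpatch) <- c(g$K * g$P, n)
        dx <- as.matrix(p$scatter %*% dpatch)
      }
    }
  }
  list(loss = loss, grads = grads, scores = y)
}

#' Training configuration
#'
#' @param learning_rate RMSprop step size (default 1e-3).
#' @param decay RMSprop moving-average coefficient for squared gradients
#'   (default 0.9).
#' @param epsilon RMSprop denominator floor (default 1e-8).
#' @param batch_size Minibatch size (default 64).
#' @param max_epochs Training epoch cap (default 100).
#' @param tol Early-stop tolerance: training stops once the mean per-sample
#'   loss of an epoch drops below `tol` (default 1e-4; set 0 to disable).
#' @param seed Seed controlling initialization, shuffling and stochastic
#'   pooling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, decay = 0.9, epsilon = 1e-8,
                         batch_size = 64L, max_epochs = 100L, tol = 1e-4,
                         seed = 1L) {
  check_scalar_num(learning_rate, "learning_rate", lower = 0, strict = TRUE)
  check_scalar_num(decay, "decay", lower = 0, upper = 1)
  check_scalar_num(max_epochs, "max_epochs", lower = 1)
  check_scalar_num(batch_size, "batch_size", lower = 1)
  structure(list(learning_rate = learning_rate, decay = decay, epsilon = epsilon,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), tol = tol,
                 seed = as.integer(seed)),
            class = "train_config")
}

one_hot <- function(labels) {
  k <- nlevels(labels)
  m <- matrix(0, length(labels), k, dimnames = list(NULL, levels(labels)))
  m[cbind(seq_along(labels), as.integer(labels))] <- 1
  m
}

#' Train a convolutional network on a labeled window set
#'
#' Minimizes the squared-error cost by minibatch gradient descent with
#' RMSprop updates. Inputs are globally rescaled by the training-set standard
#' deviation (amplitude differences between classes are preserved). The run
#' is deterministic given `cfg$seed` and returns the full per-epoch trace of
#' the mean per-sample training loss.
#'
#' @param arch An [build_architecture()] spec whose `input_shape` matches the
#'   window geometry.
#' @param ws A labeled `window_set` with at least two classes present.
#' @param cfg A [train_config()].
#' @return An object of class `dcnn_model`; its `$loss_trace` is a
#'   `loss_trace` vector, one value per epoch.
#' @seealso [predict.dcnn_model()]
#' @export
train_dcnn <- function(arch, ws, cfg = train_config()) {
  stopifnot(inherits(arch, "architecture_spec"), inherits(ws, "window_set"))
  labs <- droplevels(ws$labels)
  if (nlevels(labs) < 2L) {
    abort("training data contain a single class", class = "eegseize_train_error")
  }
  if (nlevels(labs) != arch$n_classes) {
    abort(sprintf("architecture expects %d classes, data have %d",
                  arch$n_classes, nlevels(labs)), class = "eegseize_train_error")
  }
  spw <- samples_per_window(ws)
  if (!identical(c(spw, dim(ws$windows)[2]), as.integer(arch$input_shape))) {
    abort(sprintf("window shape %dx%d does not match architecture input %dx%d",
                  spw, dim(ws$windows)[2], arch$input_shape[1], arch$input_shape[2]),
          class = "eegseize_shape_error")
  }
  n <- n_windows(ws)
  scale <- sd(ws$windows)
  if (!is.finite(scale) || scale == 0) scale <- 1
  x_all <- matrix(ws$windows, ncol = n) / scale
  t_all <- one_hot(labs)
  plan <- build_plan(arch)
  params <- init_params(plan, cfg$seed)
  vsq <- lapply(params, function(p) if (is.null(p)) NULL else lapply(p, function(w) w * 0))
  trace <- numeric(0)
  with_rng(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      epoch_loss <- 0
      for (b0 in seq.int(1L, n, by = cfg$batch_size)) {
        take <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
        res <- net_loss_grad(plan, params, x_all[, take, drop = FALSE],
                             t_all[take, , drop = FALSE], mode = "train")
        if (!is.finite(res$loss)) {
          abort(sprintf("training diverged (non-finite loss at epoch %d)", epoch),
                class = "eegseize_train_error")
        }
        epoch_loss <- epoch_loss + res$loss
        for (i in seq_along(params)) {
          if (is.null(params[[i]])) next
          for (nm in c("W", "b")) {
            gr <- res$grads[[i]][[nm]] / length(take)
            vsq[[i]][[nm]] <- cfg$decay * vsq[[i]][[nm]] + (1 - cfg$decay) * gr^2
            params[[i]][[nm]] <- params[[i]][[nm]] -
              cfg$learning_rate * gr / (sqrt(vsq[[i]][[nm]]) + cfg$epsilon)
          }
        }
      }
      trace <- c(trace, epoch_loss / n)
      if (cfg$tol > 0 && epoch_loss / n < cfg$tol) break
    }
  })
  structure(list(arch = arch, plan = plan, params = params, input_scale = scale,
                 class_levels = levels(labs),
                 loss_trace = structure(trace, class = "loss_trace"),
                 cfg = cfg, epochs_run = length(trace)),
            class = "dcnn_model")
}

#' @export
print.dcnn_model <- function(x, ...) {
  cat(sprintf("<dcnn_model> %s, %d classes (%s), %d epoch(s), final loss %.4g\n",
              x$arch$weight_class, x$arch$n_classes,
              paste(x$class_levels, collapse = "/"),
              x$epochs_run, utils::tail(x$loss_trace, 1)))
  invisible(x)
}

#' Predict class labels and scores for windows
#'
#' Runs the network in inference mode: stochastic pooling layers return their
#' expectation, so repeated calls give identical output.
#'
#' @param object A trained `dcnn_model`.
#' @param newdata A `window_set` or a `(samples, channels, n)` array matching
#'   the model's input shape.
#' @param ... Ignored.
#' @return A tibble with the predicted `label` and one score column per class
#'   (scores sum to 1 per window).
#' @export
predict.dcnn_model <- function(object, newdata, ...) {
  windows <- if (inherits(newdata, "window_set")) newdata$windows else newdata
  if (is.matrix(windows)) windows <- array(windows, c(dim(windows), 1L))
  d <- dim(windows)
  if (!identical(d[1:2], as.integer(object$arch$input_shape))) {
    abort(sprintf("window shape %dx%d does not match model input %dx%d",
                  d[1], d[2], object$arch$input_shape[1], object$arch$input_shape[2]),
          class = "eegseize_shape_error")
  }
  x <- matrix(windows, ncol = d[3]) / object$input_scale
  scores <- net_forward(object$plan, object$params, x, mode = "infer")$scores
  colnames(scores) <- object$class_levels
  lab <- factor(object$class_levels[max.col(scores, ties.method = "first")],
                levels = object$class_levels)
  out <- tibble::as_tibble(as.data.frame(scores, optional = TRUE))
  names(out) <- paste0("score_", object$class_levels)
  dplyr::bind_cols(tibble::tibble(label = lab), out)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Per-layer summary of a fitted network
#' @param x A `dcnn_model`.
#' @param ... Ignored.
#' @return A tibble with one row per layer: kind, geometry and parameter count.
#' @exportS3Method generics::tidy
tidy.dcnn_model <- function(x, ...) {
  purrr::map_dfr(seq_along(x$arch$layers), function(i) {
    ly <- x$arch$layers[[i]]
    s <- x$arch$shapes[[i]]
    tibble::tibble(
      layer = i, kind = ly$kind,
      detail = switch(ly$kind,
        conv = sprintf("%dx%d x%d", s$kernel[1], s$kernel[2], ly$n_filters),
        pool = sprintf("%dx1 s%d %s", ly$pool_size, ly$stride, ly$pool_mode),
        dense = sprintf("%d units", ly$units),
        softmax = sprintf("%d classes", ly$n_classes)),
      output = paste(s$output, collapse = "x"),
      n_parameters = if (is.null(x$params[[i]])) 0L else
        length(x$params[[i]]$W) + length(x$params[[i]]$b))
  })
}

#' One-row summary of a fitted network
#' @param x A `dcnn_model`.
#' @param ... Ignored.
#' @return A tibble: weight class, classes, epochs, initial/final loss,
#'   parameter count.
#' @exportS3Method generics::glance
glance.dcnn_model <- function(x, ...) {
  tibble::tibble(weight_class = x$arch$weight_class,
                 n_classes = x$arch$n_classes,
                 epochs = x$epochs_run,
                 initial_loss = x$loss_trace[1],
                 final_loss = utils::tail(as.numeric(x$loss_trace), 1),
                 n_parameters = sum(tidy(x)$n_parameters))
}

#' Plot a training-loss trace
#' @param object A `loss_trace` (see [train_dcnn()]).
#' @param ... Ignored.
#' @return A ggplot of mean per-sample loss against epoch.
#' @exportS3Method ggplot2::autoplot
autoplot.loss_trace <- function(object, ...) {
  df <- tibble::tibble(epoch = seq_along(object), loss = as.numeric(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean squared-error loss per window") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
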