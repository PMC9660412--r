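test_that("architecture builders respect layer-count ranges and heads", {
  mw <- suppressWarnings(build_architecture("mw", 2))
  expect_identical(n_layers(mw), 7L)
  convs <- Filter(function(l) l$kind == "conv", mw$layers)
  expect_identical(vapply(convs, `[[`, integer(1), "n_filters"),
                   c(20L, 20L, 40L, 80L))
  expect_identical(mw$layers[[n_layers(mw)]]$n_classes, 2L)
  mw3 <- suppressWarnings(build_architecture("mw", 3))
  expect_identical(mw3$layers[[n_layers(mw3)]]$n_classes, 3L)
  expect_identical(lapply(mw3$layers[-7], `[`, c("kind", "kernel", "n_filters")),
                   lapply(mw$layers[-7], `[`, c("kind", "kernel", "n_filters")))
  lw <- build_architecture("lw", 2)
  expect_true(n_layers(lw) >= 3 && n_layers(lw) <= 5)
  hw <- suppressWarnings(build_architecture("hw", 2))
  expect_true(n_layers(hw) >= 8 && n_layers(hw) <= 12)
  # an oversized kernel is clipped, with a warning
  expect_warning(build_architecture("mw", 2), class = "eegseize_kernel_clip")
  suppressWarnings(
    expect_error(build_architecture("lw", 2, input_shape = c(5L, 1L)),
                 class = "eegseize_shape_error")
  )
})

test_that("conv_forward matches identity and closed-form cases", {
  x <- matrix(rnorm(20), 5, 4)
  ly <- list(kind = "conv", kernel = c(1L, 1L), n_filters = 1L,
             activation = "identity")
  out <- conv_forward(x, ly, matrix(1, 1, 1), 0)
  expect_equal(array(x, c(5, 4, 1)), out, tolerance = 1e-15)
  # zero weights, bias b, sigmoid -> 1 / (1 + exp(-b))
  ly$activation <- "sigmoid"
  b <- 0.7
  out <- conv_forward(x, ly, matrix(0, 1, 1), b)
  expect_equal(as.numeric(out), rep(1 / (1 + exp(-b)), 20), tolerance = 1e-12)
  expect_error(conv_forward(x, ly, array(1, c(2, 2, 3, 1)), 0),
               class = "eegseize_shape_error")
})

test_that("conv_forward equals the brute-force oracle on random geometries", {
  set.seed(14)
  for (i in 1:50) {
    d <- c(sample(3:9, 1), sample(1:5, 1), sample(1:3, 1))
    k <- c(sample(seq_len(d[1]), 1), sample(seq_len(d[2]), 1), d[3],
           sample(1:4, 1))
    x <- array(rnorm(prod(d)), d)
    w <- array(rnorm(prod(k)), k)
    b <- rnorm(k[4])
    ly <- list(kind = "conv", kernel = k[1:2], n_filters = k[4],
               activation = "identity")
    got <- conv_forward(x, ly, w, b)
    want <- conv_oracle(x, w, b)
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("max pooling implements the region maximum", {
  expect_equal(pool(c(1, 3, 2), pool_size = 3, stride = 3, mode = "max"), 3)
  expect_equal(pool(c(5, 5), pool_size = 2, stride = 2, mode = "max"), 5)
  expect_equal(pool(c(5, 5), pool_size = 2, stride = 2, mode = "stochastic",
                    seed = 1), 5)
  expect_equal(pool(c(4, 1, 7, 2), pool_size = 2, stride = 2, mode = "max"),
               c(4, 7))
  expect_error(pool(c(1, 2), pool_size = 3, stride = 1), "geometry")
})

test_that("stochastic pooling samples proportionally to shifted activations", {
  # region (0, 10): after the non-negative shift only 10 has mass
  picks <- vapply(1:2000, function(i) {
    pool(c(0, 10), pool_size = 2, stride = 2, mode = "stochastic", seed = i)
  }, numeric(1))
  expect_gt(mean(picks == 10), 0.98)
  # region (1, 3): shifted weights (0, 2) -> always the larger value
  # region (2, 6) vs uniform: shifted (0, 4) -> larger; use (4, 8, 12):
  # shifted (0, 4, 8), p = (0, 1/3, 2/3)
  picks <- vapply(1:6000, function(i) {
    pool(c(4, 8, 12), pool_size = 3, stride = 3, mode = "stochastic", seed = i)
  }, numeric(1))
  expect_equal(mean(picks == 12), 2 / 3, tolerance = 0.02)
  expect_equal(mean(picks == 8), 1 / 3, tolerance = 0.02)
  expect_equal(mean(picks == 4), 0, tolerance = 0.005)
  # expectation mode is the probability-weighted mean and is deterministic
  e1 <- pool(c(4, 8, 12), 3, 3, "stochastic", expectation = TRUE)
  expect_equal(e1, 8 * 1 / 3 + 12 * 2 / 3, tolerance = 1e-12)
  expect_identical(e1, pool(c(4, 8, 12), 3, 3, "stochastic", expectation = TRUE))
})

test_that("decision head produces normalized scores", {
  expect_equal(decision_head(0, list(W = matrix(1), b = 0), type = "logistic")[1, 2],
               0.5)
  sc <- decision_head(c(1, 2), list(W = matrix(0, 3, 2), b = c(0, 0, 0)))
  expect_equal(as.numeric(sc), rep(1 / 3, 3), tolerance = 1e-12)
  set.seed(2)
  sc <- decision_head(matrix(rnorm(40), 4, 10),
                      list(W = matrix(rnorm(12), 3, 4), b = rnorm(3)))
  expect_equal(rowSums(sc), rep(1, 10), tolerance = 1e-12)
  expect_error(decision_head(1:3, list(W = matrix(1, 1, 2), b = 0)),
               class = "eegseize_shape_error")
})

test_that("the squared-error cost matches hand arithmetic", {
  expect_equal(sef_loss(matrix(c(1, 0), 1), matrix(c(1, 0), 1)), 0)
  expect_equal(sef_loss(matrix(c(0, 1), 1), matrix(c(1, 0), 1)), 1)
  y <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, byrow = TRUE)
  tt <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  expect_equal(sef_loss(y, tt), 0.5 * (0.04 + 0.04 + 0.09 + 0.09))
  # invariant to sample order
  expect_equal(sef_loss(y[2:1, ], tt[2:1, ]), sef_loss(y, tt))
  expect_error(sef_loss(y, tt[1, , drop = FALSE]), class = "eegseize_shape_error")
  expect_error(sef_loss(y, y), "one-hot")
})

test_that("analytic gradients match finite differences on a toy network", {
  toy <- build_architecture("lw", 2, input_shape = c(31L, 2L), pool_mode = "max")
  plan <- eegseize:::build_plan(toy)
  params <- eegseize:::init_params(plan, 2L)
  set.seed(33)
  x <- matrix(rnorm(62 * 6), ncol = 6)
  tmat <- eegseize:::one_hot(factor(c("a", "b", "a", "b", "a", "b")))
  res <- eegseize:::net_loss_grad(plan, params, x, tmat, mode = "train")
  eps <- 1e-6
  worst <- 0
  for (i in seq_along(params)) {
    if (is.null(params[[i]])) next
    for (nm in c("W", "b")) {
      w <- params[[i]][[nm]]
      for (j in sample(length(w), min(25, length(w)))) {
        p2 <- params
        p2[[i]][[nm]][j] <- w[j] + eps
        lp <- eegseize:::net_loss_grad(plan, p2, x, tmat, mode = "train")$loss
        p2[[i]][[nm]][j] <- w[j] - eps
        lm <- eegseize:::net_loss_grad(plan, p2, x, tmat, mode = "train")$loss
        fd <- (lp - lm) / (2 * eps)
        an <- res$grads[[i]][[nm]][j]
        worst <- max(worst, abs(fd - an) / max(1e-8, abs(fd) + abs(an)))
      }
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("training on separable data converges, deterministically", {
  ws <- small_windowset(classes = 2L, seed = 23)
  arch <- small_arch(2L, pool_mode = "stochastic")
  cfg <- train_config(max_epochs = 40, batch_size = 20, seed = 9, tol = 0)
  m <- train_dcnn(arch, ws, cfg)
  expect_lt(tail(as.numeric(m$loss_trace), 1), 0.01 * m$loss_trace[1])
  expect_true(all(is.finite(m$loss_trace)))
  # the 5-epoch moving average of the trace is non-increasing on this run
  ma <- stats::filter(as.numeric(m$loss_trace), rep(1 / 5, 5), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_true(all(diff(ma) <= 1e-6))
  # training accuracy on the converged model
  pr <- predict(m, ws)
  expect_gte(mean(pr$label == ws$labels), 0.99)
  expect_equal(rowSums(as.matrix(pr[, -1])), rep(1, nrow(pr)), tolerance = 1e-12)
  # identical reruns
  m2 <- train_dcnn(arch, ws, cfg)
  expect_identical(m$loss_trace, m2$loss_trace)
  expect_identical(m$params, m2$params)
  # inference is deterministic even with stochastic pooling layers
  expect_identical(predict(m, ws), predict(m, ws))
})

test_that("training rejects degenerate inputs", {
  ws <- small_windowset(classes = 2L)
  only_one <- ws[ws$labels == "seizure"]
  arch <- small_arch(2L)
  expect_error(train_dcnn(arch, only_one, train_config(max_epochs = 1)),
               "single class", class = "eegseize_train_error")
  expect_error(predict(train_dcnn(arch, ws, train_config(max_epochs = 1, seed = 1)),
                       array(0, c(10, 2, 1))),
               class = "eegseize_shape_error")
})

test_that("model summaries expose layers and fit statistics", {
  ws <- small_windowset(classes = 2L)
  m <- train_dcnn(small_arch(2L), ws, train_config(max_epochs = 2, seed = 4))
  td <- generics::tidy(m)
  expect_identical(nrow(td), 4L)
  expect_true(all(td$n_parameters[td$kind == "conv"] > 0))
  gl <- generics::glance(m)
  expect_identical(gl$epochs, 2L)
  expect_identical(gl$n_parameters, sum(td$n_parameters))
  p <- ggplot2::autoplot(m$loss_trace)
  expect_s3_class(p, "ggplot")
})
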