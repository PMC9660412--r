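test_that("band amplitude picks out pure tones and scales linearly", {
  t <- (0:255) / 256
  x <- sin(2 * pi * 10 * t)
  amps <- vapply(c("delta", "theta", "alpha", "beta", "gamma"),
                 function(b) band_amplitude(x, b, 256), numeric(1))
  expect_identical(names(which.max(amps)), "alpha")
  expect_equal(band_amplitude(numeric(256), "beta", 256), 0)
  expect_equal(band_amplitude(2 * x, "alpha", 256),
               2 * band_amplitude(x, "alpha", 256), tolerance = 1e-12)
  expect_error(band_amplitude(x, "gamma", fs_hz = 32), "Nyquist")
})

make_tone_windows <- function(n = 60, seed = 2) {
  # windows with random per-window amplitudes of tones in every band
  withr::with_seed(seed, {
    t <- (0:76) / 256
    w <- array(0, c(77, 2, n))
    amp <- matrix(runif(n * 5, 0.2, 2), n, 5)
    freqs <- c(2, 6, 11, 22, 45)
    for (i in seq_len(n)) {
      sig <- rowSums(vapply(1:5, function(b) amp[i, b] * sin(2 * pi * freqs[b] * t),
                            numeric(77)))
      w[, , i] <- cbind(sig, sig) + matrix(rnorm(77 * 2, sd = 0.01), 77, 2)
    }
    list(w = w, amp = amp)
  })
}

test_that("a planted band probe is recovered with correlation one", {
  tw <- make_tone_windows()
  probe <- probe_model(function(win) band_amplitude(win, "alpha", 256))
  cm <- correlation_map(probe, 1L, tw$w, fs_hz = 256)
  expect_s3_class(cm, "correlation_map")
  expect_true(all(cm$correlation >= -1 & cm$correlation <= 1))
  expect_equal(cm$correlation[cm$band == "alpha"], 1, tolerance = 1e-9)
  expect_identical(cm$band[which.max(cm$correlation)], "alpha")
})

test_that("the planted band is the arg-max for every band", {
  tw <- make_tone_windows(n = 80, seed = 6)
  for (b in c("delta", "theta", "alpha", "beta", "gamma")) {
    probe <- probe_model(function(win) band_amplitude(win, b, 256))
    cm <- correlation_map(probe, 1L, tw$w, fs_hz = 256)
    expect_identical(cm$band[which.max(cm$correlation)], b)
  }
})

test_that("independent noise units correlate weakly; flat units are flagged", {
  tw <- make_tone_windows(n = 100, seed = 9)
  noise_state <- new.env()
  noise_state$i <- 0
  noise <- probe_model(function(win) {
    noise_state$i <- noise_state$i + 1
    withr::with_seed(noise_state$i, rnorm(1))
  })
  cm <- correlation_map(noise, 1L, tw$w, fs_hz = 256)
  expect_true(all(abs(cm$correlation) < 0.3))
  flat <- probe_model(function(win) c(1.0, sum(win^2)))
  cm2 <- correlation_map(flat, 1L, tw$w, fs_hz = 256)
  expect_true(all(cm2$undefined[cm2$unit == 1]))
  expect_true(all(is.na(cm2$correlation[cm2$unit == 1])))
  expect_false(any(cm2$undefined[cm2$unit == 2]))
  expect_error(correlation_map(flat, 1L, tw$w[, , 1:2, drop = FALSE], fs_hz = 256),
               "at least 3")
})

test_that("correlation maps work on trained networks and plot", {
  ws <- small_windowset(classes = 2L, seed = 12)
  m <- train_dcnn(small_arch(2L), ws, train_config(max_epochs = 3, seed = 2))
  cm <- correlation_map(m, 1L, ws)
  expect_identical(max(cm$unit), 20L)   # 20 filters in the first layer
  expect_true(all(cm$correlation[!cm$undefined] >= -1 &
                    cm$correlation[!cm$undefined] <= 1))
  expect_s3_class(ggplot2::autoplot(cm), "ggplot")
})

test_that("perturbation response is exactly zero at gain one", {
  ws <- small_windowset(classes = 2L, seed = 15)
  m <- train_dcnn(small_arch(2L), ws, train_config(max_epochs = 5, seed = 3))
  resp <- perturbation_response(m, ws, band = "beta", gain = 1)
  expect_identical(resp$mean_shift, c(0, 0))
  expect_identical(resp$class, c("nonseizure", "seizure"))
})

test_that("amplifying the seizure band raises the seizure score", {
  # seizures live in the beta range here, so more beta means more seizure-like
  ws <- small_windowset(classes = 2L, seed = 19,
                        class_params = list(freq_lo_hz = 16, freq_hi_hz = 30))
  m <- train_dcnn(small_arch(2L, pool_mode = "stochastic"), ws,
                  train_config(max_epochs = 30, batch_size = 20, seed = 6))
  resp <- perturbation_response(m, ws, band = "beta", gain = 2)
  expect_true(all(is.finite(resp$mean_shift)))
  expect_gt(resp$mean_shift[resp$class == "seizure"], 0)
  expect_lt(resp$mean_shift[resp$class == "nonseizure"], 0)
})
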