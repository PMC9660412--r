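test_that("window counts follow both conventions", {
  expect_identical(count_windows(30000, 300, 180, "floor"), 165L)
  expect_identical(count_windows(30000, 300, 180, "inclusive"), 166L)
  expect_identical(count_windows(300, 300, 180, "inclusive"), 1L)
  expect_identical(count_windows(300, 300, 180, "floor"), 0L)
  expect_warning(count_windows(200, 300, 180), "shorter")
})

test_that("floor and inclusive counts differ by exactly one everywhere", {
  set.seed(1)
  for (i in 1:50) {
    w <- runif(1, 50, 1000)
    tot <- w + runif(1, 0, 60000)
    step <- runif(1, 10, 500)
    expect_identical(count_windows(tot, w, step, "floor") + 1L,
                     count_windows(tot, w, step, "inclusive"))
  }
})

test_that("segmentation geometry matches the defaults", {
  rec <- generate_background(signal_spec(duration_s = 30, fs_hz = 256,
                                         n_channels = 3L, seed = 2))
  ws <- segment(rec, windowing_config())
  expect_identical(dim(ws$windows), c(77L, 3L, 165L))     # round(0.3 * 256) = 77
  # window 0 is the verbatim head of the record
  expect_identical(ws$windows[, , 1], t(rec$data[, 1:77]))
  # consecutive windows share round(overlap * spw) samples
  step_samp <- round(0.6 * 300 * 256 / 1000)
  shared <- 77L - step_samp
  expect_identical(ws$windows[(step_samp + 1):77, , 1], ws$windows[1:shared, , 2])
  # slicing is lossless: non-overlapping windows reproduce the source
  k <- c(1L, 4L)   # starts 0 and 3*46 = 138 >= 77
  expect_identical(ws$windows[, , 4],
                   t(rec$data[, (round(3 * step_samp) + 1):(round(3 * step_samp) + 77)]))
})

test_that("increment step mode applies the fixed slide", {
  cfg <- windowing_config(step_mode = "increment_ms", increment_ms = 20)
  rec <- generate_background(signal_spec(duration_s = 2, fs_hz = 256,
                                         n_channels = 1L, seed = 2))
  ws <- segment(rec, cfg)
  expect_identical(dim(ws$windows)[3], count_windows(2000, 300, 20, "floor"))
  expect_equal(diff(ws$offsets_s)[1], round(0.020 * 256) / 256, tolerance = 1e-9)
})

test_that("center-rule labeling respects interval membership and precedence", {
  rec <- generate_background(signal_spec(duration_s = 30, fs_hz = 256,
                                         n_channels = 1L, seed = 6))
  ws <- segment(rec, windowing_config())
  expect_true(all(ws$labels == "nonseizure"))
  ann <- tibble::tibble(label = "seizure", start_s = 10, end_s = 20)
  ws3 <- label_windows(ws, ann, n_classes = 3L)
  centers <- ws3$offsets_s + 77 / 256 / 2
  expect_true(all(ws3$labels[centers >= 10 & centers < 20] == "seizure"))
  expect_true(all(ws3$labels[centers >= 0 & centers < 10] == "onset"))   # lead 10 s
  expect_true(all(ws3$labels[centers >= 20] == "nonseizure"))
  # a window straddling the boundary with its center outside stays nonseizure
  straddle <- which(ws3$offsets_s < 20 & ws3$offsets_s + 77 / 256 > 20 &
                      centers >= 20)
  expect_true(all(ws3$labels[straddle] == "nonseizure"))
  # 2-class collapses onset into nonseizure
  ws2 <- label_windows(ws, ann, n_classes = 2L)
  expect_identical(levels(ws2$labels), c("nonseizure", "seizure"))
  expect_identical(sum(ws2$labels == "seizure"), sum(ws3$labels == "seizure"))
})

test_that("every window receives exactly one label under either rule", {
  rec <- generate_background(signal_spec(duration_s = 20, fs_hz = 128,
                                         n_channels = 1L, seed = 8))
  ann <- tibble::tibble(label = c("seizure", "seizure"),
                        start_s = c(4, 12), end_s = c(6, 15))
  for (rule in c("center", "majority")) {
    ws <- segment(rec, windowing_config(label_rule = rule))
    ws <- label_windows(ws, ann, n_classes = 3L)
    expect_false(anyNA(ws$labels))
    expect_identical(length(ws$labels), dim(ws$windows)[3])
  }
})

test_that("degenerate inputs error clearly", {
  rec <- generate_background(signal_spec(duration_s = 0.1, fs_hz = 256,
                                         n_channels = 1L, seed = 1))
  expect_error(segment(rec, windowing_config()), "shorter")
  expect_error(windowing_config(overlap_fraction = 1), "overlap_fraction")
  expect_error(windowing_config(window_ms = 0), "window_ms")
})
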