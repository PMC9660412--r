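test_that("background generator honours the spec shape and seed", {
  spec <- signal_spec(duration_s = 30, fs_hz = 256, n_channels = 23, seed = 7)
  rec <- generate_background(spec)
  expect_s3_class(rec, "eeg_record")
  expect_identical(dim(rec$data), c(23L, 30L * 256L))
  expect_identical(nrow(rec$annotations), 0L)
  rec2 <- generate_background(spec)
  expect_identical(rec$data, rec2$data)
  spec2 <- spec; spec2$seed <- 8L
  expect_false(identical(generate_background(spec2)$data, rec$data))
})

test_that("spec validation names the offending field", {
  expect_error(signal_spec(duration_s = 0), "duration_s")
  expect_error(signal_spec(duration_s = 1, fs_hz = -1), "fs_hz")
  expect_error(signal_spec(duration_s = 1, n_channels = 0), "n_channels")
  expect_error(event_spec("seizure", start_s = 5, end_s = 5), "end_s")
  expect_error(event_spec("seizure", 0, 1, freq_lo_hz = 10, freq_hi_hz = 5),
               "freq_hi_hz")
  expect_error(event_spec("seizure", 0, 1, amplitude_gain = 0.5), "amplitude_gain")
})

test_that("alpha=1 background has a pink-like log-log spectral slope", {
  spec <- signal_spec(duration_s = 60, fs_hz = 256, n_channels = 1L,
                      background_exponent = 1, seed = 21)
  x <- generate_background(spec)$data[1, ]
  sp <- stats::spec.pgram(stats::ts(x, frequency = 256), spans = 31,
                          plot = FALSE, taper = 0)
  keep <- sp$freq >= 1 & sp$freq <= 40
  fit <- stats::lm(log(sp$spec[keep]) ~ log(sp$freq[keep]))
  slope <- unname(stats::coef(fit)[2])   # power-spectrum slope ~ -alpha
  expect_gt(slope, -1.5)
  expect_lt(slope, -0.5)
})

test_that("event injection shifts band energy upward inside the event", {
  spec <- signal_spec(duration_s = 20, fs_hz = 256, n_channels = 2L, seed = 5)
  rec <- generate_background(spec)
  expect_identical(inject_events(rec, list(), seed = 1)$data, rec$data)
  ev <- event_spec("seizure", start_s = 8, end_s = 16, freq_lo_hz = 13,
                   freq_hi_hz = 29, amplitude_gain = 4)
  out <- inject_events(rec, list(ev), seed = 9)
  fs <- 256
  inside <- out$data[1, (9 * fs):(15 * fs)]
  outside <- out$data[1, 1:(7 * fs)]
  ratio <- function(x) band_power(x, fs, 13, 30) / band_power(x, fs, 0.5, 4)
  expect_gt(ratio(inside), ratio(outside))
  # untouched outside the event
  expect_identical(out$data[, 1:(8 * fs - 1)], rec$data[, 1:(8 * fs - 1)])
  expect_identical(out$annotations$label, "seizure")
})

test_that("onset in-band power sits between background and seizure", {
  spec <- signal_spec(duration_s = 24, fs_hz = 256, n_channels = 1L, seed = 13)
  rec <- generate_background(spec)
  evs <- list(event_spec("onset", 2, 8, amplitude_gain = 2),
              event_spec("seizure", 14, 20, amplitude_gain = 4))
  out <- inject_events(rec, evs, seed = 2)
  fs <- 256
  inband <- function(seg) band_power(seg, fs, 3, 29)
  p_bg <- inband(rec$data[1, (9 * fs):(13 * fs)])
  p_on <- inband(out$data[1, (3 * fs):(7 * fs)])
  p_sz <- inband(out$data[1, (15 * fs):(19 * fs)])
  expect_gt(p_on, p_bg)
  expect_gt(p_sz, p_on)
})

test_that("overlapping or out-of-range events are rejected", {
  rec <- generate_background(signal_spec(duration_s = 10, n_channels = 1L, seed = 1))
  expect_error(inject_events(rec, list(event_spec("seizure", 2, 6),
                                       event_spec("onset", 5, 8)), seed = 1),
               "overlap")
  expect_error(inject_events(rec, list(event_spec("seizure", 8, 12)), seed = 1),
               "beyond")
})

test_that("labeled datasets are balanced, class-complete and reproducible", {
  ws2 <- small_windowset(classes = 2L)
  expect_identical(sort(unique(as.character(ws2$labels))),
                   c("nonseizure", "seizure"))
  expect_length(unique(table(ws2$labels)), 1L)   # balanced by design
  ws3 <- small_windowset(classes = 3L)
  expect_identical(nlevels(ws3$labels), 3L)
  expect_identical(sort(unique(as.character(ws3$labels))),
                   c("nonseizure", "onset", "seizure"))
  again <- small_windowset(classes = 3L)
  expect_identical(ws3$windows, again$windows)
  expect_identical(ws3$labels, again$labels)
  expect_error(make_labeled_dataset(1, classes = 4L,
                                    spec = signal_spec(duration_s = 2, seed = 1)),
               "classes")
})

test_that("band-power separation is monotone in the amplitude gain", {
  # a fixed band-power threshold discriminant must not get worse as the
  # seizure gain grows
  acc_at_gain <- function(gain) {
    ws <- small_windowset(classes = 2L, n_records = 2L, duration_s = 5.0,
                          class_params = list(seizure_gain = gain), seed = 17)
    pow <- apply(ws$windows, 3, function(w) band_power(w[, 1], ws$fs_hz, 3, 29))
    thr <- stats::median(pow)
    pred <- ifelse(pow > thr, "seizure", "nonseizure")
    mean(pred == as.character(ws$labels))
  }
  accs <- vapply(c(1.5, 2, 4), acc_at_gain, numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_gt(accs[3], 0.9)
})
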