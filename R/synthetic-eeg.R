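# Seeded synthetic EEG: spectrally shaped 1/f^alpha Gaussian background with
# rhythmic seizure/onset events injected in a configurable frequency band.
# The generator emulates the energy shift toward higher-frequency subbands
# observed during seizures, not physiologically realistic EEG.

#' Specification of a synthetic multichannel EEG recording
#'
#' @param duration_s Recording length in seconds (> 0).
#' @param fs_hz Sampling rate in samples/second (default 256, the CHB-MIT rate).
#' @param n_channels Number of channels (default 23, the CHB-MIT montage width).
#' @param background_exponent Spectral slope alpha of the `1/f^alpha`
#'   background (default 1, classic pink-like EEG background).
#' @param noise_scale Background standard deviation in arbitrary microvolt-like
#'   units (default 1).
#' @param seed Integer seed; identical spec + seed gives bit-identical signals.
#' @return An object of class `signal_spec`.
#' @examples
#' signal_spec(duration_s = 30, seed = 7)
#' @export
signal_spec <- function(duration_s, fs_hz = 256, n_channels = 23L,
                        background_exponent = 1, noise_scale = 1, seed = 1L) {
  check_scalar_num(duration_s, "duration_s", lower = 0, strict = TRUE)
  check_scalar_num(fs_hz, "fs_hz", lower = 0, strict = TRUE)
  check_scalar_num(n_channels, "n_channels", lower = 1)
  check_scalar_num(background_exponent, "background_exponent", lower = 0)
  check_scalar_num(noise_scale, "noise_scale", lower = 0, strict = TRUE)
  check_scalar_num(seed, "seed")
  structure(list(duration_s = duration_s, fs_hz = fs_hz,
                 n_channels = as.integer(n_channels),
                 background_exponent = background_exponent,
                 noise_scale = noise_scale, seed = as.integer(seed)),
            class = "signal_spec")
}

#' @export
print.signal_spec <- function(x, ...) {
  cat(sprintf("<signal_spec> %g s @ %g Hz, %d channels, 1/f^%g background (seed %d)\n",
              x$duration_s, x$fs_hz, x$n_channels, x$background_exponent, x$seed))
  invisible(x)
}

#' Specification of an injected rhythmic event
#'
#' Describes a seizure-like (or onset, or explicitly nonseizure) interval in
#' which rhythmic activity confined to `[freq_lo_hz, freq_hi_hz]` is added on
#' top of the background. `amplitude_gain` is the target multiplicative factor
#' on in-band amplitude relative to the background; onset events conventionally
#' use a lower gain than full seizures.
#'
#' @param label `"nonseizure"`, `"onset"` or `"seizure"`.
#' @param start_s,end_s Event interval in seconds, `0 <= start_s < end_s`.
#' @param freq_lo_hz,freq_hi_hz Band of the injected rhythm (defaults 3 and
#'   29 Hz, the span in which seizure activity concentrates).
#' @param amplitude_gain Multiplicative amplitude factor vs background
#'   (>= 1; a gain of 1 adds nothing).
#' @param ramp_s Seconds of linear amplitude ramp-in at event start (default 0).
#' @return An object of class `event_spec`.
#' @export
event_spec <- function(label = c("seizure", "onset", "nonseizure"), start_s, end_s,
                       freq_lo_hz = 3, freq_hi_hz = 29, amplitude_gain = 4,
                       ramp_s = 0) {
  label <- match.arg(label)
  check_scalar_num(start_s, "start_s", lower = 0)
  check_scalar_num(end_s, "end_s")
  if (start_s >= end_s) fail_field("end_s", "must be greater than start_s")
  check_scalar_num(freq_lo_hz, "freq_lo_hz", lower = 0, strict = TRUE)
  if (freq_hi_hz <= freq_lo_hz) fail_field("freq_hi_hz", "must exceed freq_lo_hz")
  check_scalar_num(amplitude_gain, "amplitude_gain", lower = 1)
  check_scalar_num(ramp_s, "ramp_s", lower = 0)
  structure(list(label = label, start_s = start_s, end_s = end_s,
                 freq_lo_hz = freq_lo_hz, freq_hi_hz = freq_hi_hz,
                 amplitude_gain = amplitude_gain, ramp_s = ramp_s),
            class = "event_spec")
}

# one channel of 1/f^alpha noise via frequency-domain shaping of white noise
shaped_noise <- function(n, alpha, fs_hz) {
  w <- rnorm(n)
  if (alpha == 0) return(w)
  spec <- fft(w)
  freq <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs_hz / n
  shape <- c(0, freq[-1]^(-alpha / 2))   # kill DC, scale amplitude by f^(-a/2)
  x <- Re(fft(spec * shape, inverse = TRUE)) / n
  x / sd(x)
}

#' Generate 1/f-like multichannel background EEG
#'
#' Each channel is independent Gaussian noise whose amplitude spectrum is
#' shaped to decay as `1/f^alpha`, rescaled to `noise_scale` standard
#' deviation. The result carries no annotations.
#'
#' @param spec A [signal_spec()].
#' @return An [eeg_record()] of `n_channels` x `duration_s * fs_hz` samples.
#' @examples
#' rec <- generate_background(signal_spec(duration_s = 2, n_channels = 2, seed = 1))
#' dim(rec$data)
#' @export
generate_background <- function(spec) {
  if (!inherits(spec, "signal_spec")) fail_field("spec", "must be a signal_spec")
  n <- round(spec$duration_s * spec$fs_hz)
  with_rng(spec$seed, {
    data <- matrix(0, spec$n_channels, n)
    for (ch in seq_len(spec$n_channels)) {
      data[ch, ] <- spec$noise_scale *
        shaped_noise(n, spec$background_exponent, spec$fs_hz)
    }
    eeg_record(data, fs_hz = spec$fs_hz,
               channel_labels = sprintf("SYN%02d", seq_len(spec$n_channels)),
               subject_id = sprintf("synthetic-seed%d", spec$seed))
  })
}

# rhythmic burst: sum of `n_sin` sinusoids with random frequencies in the band,
# random phases, unit RMS before scaling
rhythm_burst <- function(n, fs_hz, freq_lo, freq_hi, n_sin = 5L) {
  t <- (seq_len(n) - 1L) / fs_hz
  fr <- runif(n_sin, freq_lo, freq_hi)
  ph <- runif(n_sin, 0, 2 * pi)
  x <- rowSums(vapply(seq_len(n_sin), function(i) sin(2 * pi * fr[i] * t + ph[i]),
                      numeric(n)))
  x / sqrt(mean(x^2))
}

#' Inject rhythmic seizure/onset events into a recording
#'
#' Within each event interval a burst of 5 random sinusoids confined to the
#' event's frequency band is added to every channel, with per-channel +/-20%
#' amplitude jitter and an optional linear ramp-in. The added rhythm has RMS
#' `(amplitude_gain - 1)` times the channel's background RMS, so total in-band
#' energy grows with the gain while a gain of 1 leaves the signal untouched.
#' Annotation intervals are appended accordingly; samples outside all events
#' are unchanged.
#'
#' @param record An [eeg_record()].
#' @param events List of [event_spec()]s; must be non-overlapping and lie
#'   within the record duration.
#' @param seed Integer seed for the randomized burst content.
#' @return A new `eeg_record` with events added and annotated.
#' @export
inject_events <- function(record, events, seed = 1L) {
  stopifnot(inherits(record, "eeg_record"))
  if (length(events) == 0L) return(record)
  if (inherits(events, "event_spec")) events <- list(events)
  ok <- vapply(events, inherits, logical(1), "event_spec")
  if (!all(ok)) fail_field("events", "must be a list of event_spec objects")
  dur <- record_duration(record)
  ord <- order(vapply(events, `[[`, numeric(1), "start_s"))
  events <- events[ord]
  starts <- vapply(events, `[[`, numeric(1), "start_s")
  ends <- vapply(events, `[[`, numeric(1), "end_s")
  if (any(ends > dur + 1e-9)) {
    abort("event extends beyond the record duration", class = "eegseize_validation_error")
  }
  if (length(events) > 1L && any(starts[-1] < ends[-length(ends)] - 1e-9)) {
    abort("events overlap after sorting by start time", class = "eegseize_validation_error")
  }
  fs <- record$fs_hz
  nch <- nrow(record$data)
  data <- record$data
  ann <- record$annotations
  with_rng(seed, {
    for (ev in events) {
      i0 <- floor(ev$start_s * fs) + 1L
      i1 <- min(ncol(data), ceiling(ev$end_s * fs))
      n <- i1 - i0 + 1L
      if (n < 2L) next
      burst <- rhythm_burst(n, fs, ev$freq_lo_hz, ev$freq_hi_hz)
      ramp <- rep(1, n)
      if (ev$ramp_s > 0) {
        nr <- min(n, round(ev$ramp_s * fs))
        if (nr > 1L) ramp[seq_len(nr)] <- seq(0, 1, length.out = nr)
      }
      jitter <- runif(nch, 0.8, 1.2)
      for (ch in seq_len(nch)) {
        amp <- (ev$amplitude_gain - 1) * sd(record$data[ch, ])
        data[ch, i0:i1] <- data[ch, i0:i1] + amp * jitter[ch] * ramp * burst
      }
      ann <- rbind(ann, tibble::tibble(label = ev$label, start_s = ev$start_s,
                                       end_s = ev$end_s))
    }
  })
  out <- record
  out$data <- data
  out$annotations <- ann[order(ann$start_s), , drop = FALSE]
  out
}

#' Balanced labeled window set from synthetic recordings
#'
#' Fixture factory for the two- and three-class experiments: generates
#' `n_records` background recordings per class, injects a class-defining
#' rhythmic event spanning each non-background recording, windows every
#' recording with the supplied configuration and labels all of its windows
#' with the record's class. Classes are balanced by construction; windows per
#' class = `n_records * count_windows(...)` for the record duration.
#'
#' @param n_records Recordings generated per class.
#' @param classes 2 (nonseizure/seizure) or 3 (nonseizure/onset/seizure).
#' @param spec A [signal_spec()] describing each recording; its `seed` anchors
#'   the whole dataset.
#' @param class_params List with elements `onset_gain` (default 2),
#'   `seizure_gain` (default 4), `freq_lo_hz` (3), `freq_hi_hz` (29) and
#'   `onset_ramp_s` (default 1).
#' @param config A [windowing_config()] (default: 300 ms windows, 40% overlap).
#' @param seed Integer seed; two equal-argument calls return identical window
#'   sets.
#' @return A `window_set` (see [segment()]) with balanced class labels and
#'   generator provenance in `$provenance`.
#' @examples
#' ws <- make_labeled_dataset(1, classes = 2,
#'   spec = signal_spec(duration_s = 3, n_channels = 2, seed = 1), seed = 1)
#' table(ws$labels)
#' @export
make_labeled_dataset <- function(n_records, classes = 3L, spec = signal_spec(30),
                                 class_params = list(), config = windowing_config(),
                                 seed = 1L) {
  if (!classes %in% c(2L, 3L)) fail_field("classes", "must be 2 or 3")
  check_scalar_num(n_records, "n_records", lower = 1)
  p <- utils::modifyList(list(onset_gain = 2, seizure_gain = 4, freq_lo_hz = 3,
                              freq_hi_hz = 29, onset_ramp_s = 1), class_params)
  lv <- seizure_class_levels(classes)
  gains <- c(nonseizure = 1, onset = p$onset_gain, seizure = p$seizure_gain)[lv]
  sets <- list()
  idx <- 0L
  for (cl in lv) {
    for (r in seq_len(n_records)) {
      idx <- idx + 1L
      rec_spec <- spec
      rec_spec$seed <- spec$seed + 1000L * idx + seed
      rec <- generate_background(rec_spec)
      if (cl != "nonseizure") {
        ev <- event_spec(cl, start_s = 0, end_s = record_duration(rec),
                         freq_lo_hz = p$freq_lo_hz, freq_hi_hz = p$freq_hi_hz,
                         amplitude_gain = gains[[cl]],
                         ramp_s = if (cl == "onset") p$onset_ramp_s else 0)
        rec <- inject_events(rec, list(ev), seed = rec_spec$seed + 1L)
      }
      ws <- segment(rec, config)
      ws$labels <- factor(rep(cl, n_windows(ws)), levels = lv)
      sets[[idx]] <- ws
    }
  }
  out <- bind_window_sets(sets)
  out$provenance <- list(generator = "make_labeled_dataset", classes = classes,
                         n_records = n_records, seed = seed, spec = unclass(spec),
                         class_params = p)
  out
}
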