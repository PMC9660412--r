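# Fixed-length overlapping windows over multichannel recordings, plus label
# assignment from annotation intervals.

#' Windowing configuration
#'
#' The window length defaults to 300 ms. Two step conventions are supported:
#' `overlap_fraction` (default, 40% overlap, i.e. a 180 ms step) and
#' `increment_ms` (a fixed slide, default 20 ms); both appear in practice and
#' they disagree, so the one whose window count is externally checkable (165
#' windows over 30 s) is the default. `count_convention` "floor" counts
#' `floor((total - window) / step)` windows; "inclusive" adds the final
#' aligned window.
#'
#' @param window_ms Window length in milliseconds (> 0, default 300).
#' @param step_mode `"overlap_fraction"` or `"increment_ms"`.
#' @param overlap_fraction Fractional overlap in `[0, 1)` (default 0.40).
#' @param increment_ms Slide in milliseconds when `step_mode = "increment_ms"`
#'   (default 20).
#' @param count_convention `"floor"` (default) or `"inclusive"`.
#' @param onset_lead_s Seconds before an annotated seizure start treated as
#'   "onset" in 3-class labeling (default 10).
#' @param label_rule `"center"` (label by the window's center point, default)
#'   or `"majority"` (label by the majority of its samples).
#' @return An object of class `windowing_config`.
#' @export
windowing_config <- function(window_ms = 300, step_mode = c("overlap_fraction", "increment_ms"),
                             overlap_fraction = 0.40, increment_ms = 20,
                             count_convention = c("floor", "inclusive"),
                             onset_lead_s = 10, label_rule = c("center", "majority")) {
  step_mode <- match.arg(step_mode)
  count_convention <- match.arg(count_convention)
  label_rule <- match.arg(label_rule)
  check_scalar_num(window_ms, "window_ms", lower = 0, strict = TRUE)
  check_scalar_num(overlap_fraction, "overlap_fraction", lower = 0, upper = 1)
  if (overlap_fraction >= 1) fail_field("overlap_fraction", "must be < 1")
  check_scalar_num(increment_ms, "increment_ms", lower = 0, strict = TRUE)
  check_scalar_num(onset_lead_s, "onset_lead_s", lower = 0)
  structure(list(window_ms = window_ms, step_mode = step_mode,
                 overlap_fraction = overlap_fraction, increment_ms = increment_ms,
                 count_convention = count_convention, onset_lead_s = onset_lead_s,
                 label_rule = label_rule),
            class = "windowing_config")
}

step_ms_of <- function(config) {
  if (config$step_mode == "overlap_fraction") {
    config$window_ms * (1 - config$overlap_fraction)
  } else {
    config$increment_ms
  }
}

#' Number of windows over a signal
#'
#' Under the `"floor"` convention, `floor((total_ms - window_ms) / step_ms)`;
#' `"inclusive"` adds one for the final aligned window. A 30 s signal with
#' 300 ms windows and a 180 ms step (40% overlap) gives 165 windows under the
#' floor convention.
#'
#' @param total_ms Signal length in milliseconds.
#' @param window_ms Window length in milliseconds.
#' @param step_ms Step between window starts in milliseconds.
#' @param convention `"floor"` or `"inclusive"`.
#' @return Integer window count (0, with a warning, if the signal is shorter
#'   than one window).
#' @examples
#' count_windows(30000, 300, 180)              # 165
#' count_windows(30000, 300, 180, "inclusive") # 166
#' @export
count_windows <- function(total_ms, window_ms, step_ms,
                          convention = c("floor", "inclusive")) {
  convention <- match.arg(convention)
  check_scalar_num(window_ms, "window_ms", lower = 0, strict = TRUE)
  check_scalar_num(step_ms, "step_ms", lower = 0, strict = TRUE)
  check_scalar_num(total_ms, "total_ms", lower = 0)
  if (total_ms < window_ms) {
    warn("signal is shorter than one window; 0 windows")
    return(0L)
  }
  n <- floor((total_ms - window_ms) / step_ms + 1e-9)
  as.integer(if (convention == "inclusive") n + 1L else n)
}

# internal constructor shared by segment()/load_windowset()/subsetting
new_window_set <- function(windows, labels, offsets_s, fs_hz, config,
                           provenance = list()) {
  structure(list(windows = windows, labels = labels, offsets_s = offsets_s,
                 fs_hz = fs_hz, config = config, provenance = provenance),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("<window_set> %d windows x %d channels x %d samples @ %g Hz\n",
              d[3], d[2], d[1], x$fs_hz))
  if (nlevels(x$labels) > 0) print(table(x$labels))
  invisible(x)
}

n_windows <- function(ws) dim(ws$windows)[3]
samples_per_window <- function(ws) dim(ws$windows)[1]

#' Cut a recording into overlapping labeled windows
#'
#' Windows start at `k * step` for `k = 0 .. N-1` with `N` from
#' [count_windows()]; each window is the contiguous half-open sample slice
#' `[start, start + window)` across all channels. Each window holds
#' `round(window_ms * fs_hz / 1000)` samples. Labels are assigned from the
#' record's annotations via [label_windows()] (2-class by default when
#' annotations are present; all-nonseizure otherwise).
#'
#' @param record An [eeg_record()].
#' @param config A [windowing_config()].
#' @param n_classes Classes for the initial labeling (2 or 3).
#' @return A `window_set`: `$windows` is a samples x channels x n array,
#'   `$labels` a factor, `$offsets_s` the window start times.
#' @examples
#' rec <- generate_background(signal_spec(duration_s = 2, n_channels = 2, seed = 1))
#' segment(rec, windowing_config())
#' @export
segment <- function(record, config = windowing_config(), n_classes = 2L) {
  stopifnot(inherits(record, "eeg_record"), inherits(config, "windowing_config"))
  if (ncol(record$data) == 0L) {
    abort("cannot segment an empty record", class = "eegseize_validation_error")
  }
  fs <- record$fs_hz
  total_ms <- 1000 * ncol(record$data) / fs
  if (total_ms < config$window_ms) {
    abort("record is shorter than one window", class = "eegseize_validation_error")
  }
  step_ms <- step_ms_of(config)
  n <- count_windows(total_ms, config$window_ms, step_ms, config$count_convention)
  spw <- round(config$window_ms * fs / 1000)
  step_samp <- step_ms * fs / 1000
  starts <- round((seq_len(n) - 1L) * step_samp)         # 0-based start samples
  # the floor count can leave the last start slightly past the usable range
  starts <- starts[starts + spw <= ncol(record$data)]
  n <- length(starts)
  nch <- nrow(record$data)
  windows <- array(0, dim = c(spw, nch, n))
  for (i in seq_len(n)) {
    windows[, , i] <- t(record$data[, (starts[i] + 1L):(starts[i] + spw), drop = FALSE])
  }
  ws <- new_window_set(windows,
                       labels = factor(rep("nonseizure", n),
                                       levels = seizure_class_levels(n_classes)),
                       offsets_s = starts / fs, fs_hz = fs, config = config,
                       provenance = list(subject_id = record$subject_id))
  if (nrow(record$annotations) > 0) {
    ws <- label_windows(ws, record$annotations, n_classes = n_classes)
  }
  ws
}

#' Assign class labels to windows from annotation intervals
#'
#' Two-class: a window is `"seizure"` iff its label point (center rule) or the
#' majority of its extent (majority rule) lies inside a seizure interval.
#' Three-class: additionally `"onset"` iff it lies inside
#' `[start - onset_lead_s, start)` of a seizure interval or inside an
#' explicitly annotated onset interval. Precedence is seizure > onset >
#' nonseizure; every window gets exactly one label.
#'
#' @param ws A `window_set`.
#' @param annotations Tibble with `label`, `start_s`, `end_s`.
#' @param n_classes 2 or 3.
#' @return The window set with `$labels` replaced.
#' @export
label_windows <- function(ws, annotations, n_classes = 2L) {
  stopifnot(inherits(ws, "window_set"))
  if (!n_classes %in% c(2L, 3L)) fail_field("n_classes", "must be 2 or 3")
  lv <- seizure_class_levels(n_classes)
  window_s <- samples_per_window(ws) / ws$fs_hz
  lead <- ws$config$onset_lead_s
  inside_frac <- function(lo, hi) {
    # fraction of each window inside [lo, hi)
    a <- pmax(ws$offsets_s, lo)
    b <- pmin(ws$offsets_s + window_s, hi)
    pmax(0, b - a) / window_s
  }
  hit <- function(lo, hi) {
    if (ws$config$label_rule == "center") {
      ctr <- ws$offsets_s + window_s / 2
      ctr >= lo & ctr < hi
    } else {
      inside_frac(lo, hi) > 0.5
    }
  }
  seiz <- rep(FALSE, n_windows(ws))
  onset <- rep(FALSE, n_windows(ws))
  for (i in seq_len(nrow(annotations))) {
    lab <- annotations$label[i]
    lo <- annotations$start_s[i]; hi <- annotations$end_s[i]
    if (lab == "seizure") {
      seiz <- seiz | hit(lo, hi)
      if (n_classes == 3L && lead > 0) onset <- onset | hit(lo - lead, lo)
    } else if (lab == "onset" && n_classes == 3L) {
      onset <- onset | hit(lo, hi)
    }
  }
  labels <- rep("nonseizure", n_windows(ws))
  labels[onset] <- "onset"
  labels[seiz] <- "seizure"      # seizure takes precedence over onset
  ws$labels <- factor(labels, levels = lv)
  ws
}

#' Subset a window set
#'
#' @param x A `window_set`.
#' @param i Window indices (integer or logical).
#' @param ... Ignored.
#' @return A `window_set` with the selected windows.
#' @export
`[.window_set` <- function(x, i, ...) {
  new_window_set(x$windows[, , i, drop = FALSE], labels = x$labels[i],
                 offsets_s = x$offsets_s[i], fs_hz = x$fs_hz, config = x$config,
                 provenance = x$provenance)
}

# concatenate window sets with identical geometry
bind_window_sets <- function(sets) {
  stopifnot(length(sets) >= 1L)
  d1 <- dim(sets[[1]]$windows)[1:2]
  for (s in sets) stopifnot(identical(dim(s$windows)[1:2], d1))
  windows <- array(unlist(lapply(sets, function(s) s$windows), use.names = FALSE),
                   dim = c(d1, sum(vapply(sets, n_windows, integer(1)))))
  lv <- levels(sets[[1]]$labels)
  new_window_set(windows,
                 labels = factor(unlist(lapply(sets, function(s) as.character(s$labels))),
                                 levels = lv),
                 offsets_s = unlist(lapply(sets, `[[`, "offsets_s")),
                 fs_hz = sets[[1]]$fs_hz, config = sets[[1]]$config,
                 provenance = sets[[1]]$provenance)
}

#' Per-band window sets from a wavelet decomposition
#'
#' Decomposes every window with the multilevel filter bank and returns, for
#' each requested band, a window set whose windows are the band-reconstructed
#' time signals (same shape as the input windows). This feeds the per-subband
#' classification experiments; the raw set itself is the
#' "without decomposition" arm.
#'
#' @param ws A `window_set`.
#' @param bands Character vector of band names (default all five).
#' @param filters,extension,levels,gamma_merge_d1 Decomposition settings, see
#'   [decompose()].
#' @return Named list of `window_set`s, one per band.
#' @export
decompose_windowset <- function(ws, bands = c("delta", "theta", "alpha", "beta", "gamma"),
                                filters = wavelet_filters(), extension = "symmetric",
                                levels = 5L, gamma_merge_d1 = FALSE) {
  stopifnot(inherits(ws, "window_set"))
  spw <- samples_per_window(ws)
  flat <- matrix(ws$windows, nrow = spw)   # samples x (channels * windows)
  out <- list()
  for (b in bands) {
    m <- band_transfer_matrix(spw, b, ws$fs_hz, levels, filters, extension,
                              gamma_merge_d1)
    bw <- ws
    bw$windows <- array(m %*% flat, dim = dim(ws$windows))
    bw$provenance <- c(ws$provenance,
                       list(band = b, wavelet = filters$family, extension = extension))
    out[[b]] <- bw
  }
  out
}
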