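# Correlation-map interpretability: relate the mean activation of each
# network unit (filter) to the mean spectral amplitude of each EEG band over
# a set of windows, and probe a trained model by rescaling one band.

#' Mean spectral amplitude of a window in one band
#'
#' Magnitude spectrum (FFT) per channel, averaged over the frequency bins
#' inside the band's nominal Hz range, then averaged over channels. The band
#' edges are the nominal EEG rhythm boundaries (the dyadic edges at the
#' 256 Hz reference rate: delta 0-4, theta 4-8, alpha 8-16, beta 16-32,
#' gamma 32-64 Hz), independent of the data sampling rate; a band entirely
#' above the Nyquist frequency of the data is an error. With
#' `method = "dwt"`, the root-mean-square of the band's wavelet coefficients
#' is used instead.
#'
#' @param window Numeric vector or samples-by-channels matrix.
#' @param band Band name (`"delta"` ... `"gamma"`).
#' @param fs_hz Sampling rate of the data in Hz.
#' @param method `"spectrum"` (default) or `"dwt"`.
#' @param gamma_merge_d1 Passed to [band_map()].
#' @return Non-negative scalar; linear in the window amplitude.
#' @examples
#' t <- (0:255) / 256
#' band_amplitude(sin(2 * pi * 10 * t), "alpha", 256)
#' @export
band_amplitude <- function(window, band, fs_hz, method = c("spectrum", "dwt"),
                           gamma_merge_d1 = FALSE) {
  method <- match.arg(method)
  bm <- band_map(256, gamma_merge_d1 = gamma_merge_d1)
  if (!band %in% names(bm)) {
    fail_field("band", paste("must be one of:", paste(names(bm), collapse = ", ")))
  }
  if (bm[[band]]$lo_hz >= fs_hz / 2) {
    abort(sprintf("band %s lies outside the Nyquist range of %g Hz", band, fs_hz / 2),
          class = "eegseize_validation_error")
  }
  if (is.vector(window)) window <- matrix(window, ncol = 1L)
  if (method == "dwt") {
    sb <- decompose(window, fs_hz, gamma_merge_d1 = gamma_merge_d1)
    co <- unlist(sb$coeffs[bm[[band]]$coefs])
    return(sqrt(mean(co^2)))
  }
  n <- nrow(window)
  freq <- (seq_len(n) - 1L) * fs_hz / n
  pick <- freq >= bm[[band]]$lo_hz & freq < min(bm[[band]]$hi_hz, fs_hz / 2)
  if (!any(pick)) return(0)
  amp <- abs(stats::mvfft(window))[pick, , drop = FALSE] / n
  mean(colMeans(amp))
}

#' Mean unit activations of a model layer over windows
#'
#' Generic used by [correlation_map()]: returns a windows-by-units matrix of
#' per-filter activations averaged over the unit's spatial extent. A method
#' is provided for trained networks and for probe models (see
#' [probe_model()]), which makes the correlation machinery testable against
#' analytically known responses.
#'
#' @param model A `dcnn_model` or `probe_model`.
#' @param windows A `window_set` or `(samples, channels, n)` array.
#' @param layer_id Layer index (for networks).
#' @return Numeric matrix, `n_windows` rows, one column per unit/filter.
#' @export
layer_activations <- function(model, windows, layer_id) {
  UseMethod("layer_activations")
}

#' @export
layer_activations.dcnn_model <- function(model, windows, layer_id) {
  if (layer_id < 1L || layer_id > length(model$plan)) {
    abort(sprintf("layer_id must be in 1..%d", length(model$plan)),
          class = "eegseize_validation_error")
  }
  w <- if (inherits(windows, "window_set")) windows$windows else windows
  d <- dim(w)
  x <- matrix(w, ncol = d[3]) / model$input_scale
  sub <- model$plan[seq_len(layer_id)]
  par <- model$params[seq_len(layer_id)]
  out <- net_forward(sub, par, x, mode = "infer")$scores  # n x prod(output)
  shp <- model$plan[[layer_id]]$output                    # (T, C, D)
  n <- nrow(out)
  a <- array(t(out), c(shp, n))
  units <- shp[3]
  # mean over the spatial (time x channel) extent, per filter
  t(apply(a, c(3L, 4L), mean))                            # n x units
}

#' Probe model with a known analytic response
#'
#' Wraps a function `fn(window_matrix) -> numeric vector of unit outputs`
#' into an object usable by [correlation_map()]; useful to validate the
#' correlation machinery against planted responses.
#'
#' @param fn Function of one samples-by-channels matrix.
#' @return An object of class `probe_model`.
#' @export
probe_model <- function(fn) {
  stopifnot(is.function(fn))
  structure(list(fn = fn), class = "probe_model")
}

#' @export
layer_activations.probe_model <- function(model, windows, layer_id = 1L) {
  w <- if (inherits(windows, "window_set")) windows$windows else windows
  n <- dim(w)[3]
  k <- length(model$fn(w[, , 1]))
  res <- vapply(seq_len(n), function(i) as.numeric(model$fn(w[, , i])),
                numeric(k))
  if (k == 1L) matrix(res, ncol = 1L) else t(res)
}

#' Correlation map of layer units against subband amplitudes
#'
#' For every unit (filter) of a layer, the Pearson correlation across windows
#' between its mean activation and each band's [band_amplitude()]. Units with
#' zero activation variance are flagged `undefined` (correlation `NA`) rather
#' than propagating NaN.
#'
#' @param model A `dcnn_model` or [probe_model()].
#' @param layer_id Layer index.
#' @param windows A `window_set` (or array) with at least 3 windows.
#' @param fs_hz Sampling rate; taken from the window set when available.
#' @param method Spectral-amplitude method, see [band_amplitude()].
#' @return A tibble of class `correlation_map`: `layer`, `unit`, `band`,
#'   `correlation`, `undefined`, `n_windows`.
#' @export
correlation_map <- function(model, layer_id, windows, fs_hz = NULL,
                            method = "spectrum") {
  w <- if (inherits(windows, "window_set")) windows$windows else windows
  if (is.null(fs_hz)) {
    fs_hz <- if (inherits(windows, "window_set")) windows$fs_hz else
      fail_field("fs_hz", "must be given when windows are a bare array")
  }
  n <- dim(w)[3]
  if (is.na(n) || n < 3L) {
    abort("at least 3 windows are required", class = "eegseize_validation_error")
  }
  act <- layer_activations(model, windows, layer_id)
  bands <- names(band_map(fs_hz))
  amps <- vapply(bands, function(b) {
    vapply(seq_len(n), function(i) band_amplitude(w[, , i], b, fs_hz, method = method),
           numeric(1))
  }, numeric(n))
  res <- purrr::map_dfr(seq_len(ncol(act)), function(u) {
    a <- act[, u]
    flat <- sd(a) == 0
    purrr::map_dfr(bands, function(b) {
      r <- if (flat || sd(amps[, b]) == 0) NA_real_ else cor(a, amps[, b])
      tibble::tibble(layer = layer_id, unit = u, band = b, correlation = r,
                     undefined = is.na(r), n_windows = n)
    })
  })
  class(res) <- c("correlation_map", class(res))
  res
}

#' Plot a correlation map as a unit-by-band heat map
#' @param object A `correlation_map` tibble.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.correlation_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$band, y = factor(.data$unit),
                                       fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = "frequency band", y = "unit",
                  title = sprintf("Layer %d correlation map", object$layer[1])) +
    ggplot2::theme_minimal()
}

#' Response of a trained model to an artificial band rescaling
#'
#' Rescales one frequency band of every window (reconstruct the band, scale
#' it by `gain`, add it back), re-runs prediction and reports the mean change
#' of each class score. A gain of 1 leaves the windows untouched, so the
#' shift is exactly zero.
#'
#' @param model A trained `dcnn_model`.
#' @param windows A `window_set`.
#' @param band Band to rescale.
#' @param gain Positive multiplicative factor on the band component.
#' @param filters,extension Wavelet settings used for the band split.
#' @return A tibble: `class`, `mean_shift` (mean score change), `band`,
#'   `gain`.
#' @export
perturbation_response <- function(model, windows, band, gain,
                                  filters = wavelet_filters(),
                                  extension = "symmetric") {
  stopifnot(inherits(model, "dcnn_model"), inherits(windows, "window_set"))
  check_scalar_num(gain, "gain", lower = 0, strict = TRUE)
  base <- predict(model, windows)
  pw <- windows
  if (gain != 1) {
    spw <- samples_per_window(windows)
    m <- band_transfer_matrix(spw, band, windows$fs_hz, filters = filters,
                              extension = extension)
    flat <- matrix(windows$windows, nrow = spw)
    pw$windows <- array(flat + (gain - 1) * (m %*% flat), dim = dim(windows$windows))
  }
  pert <- predict(model, pw)
  score_cols <- grep("^score_", names(base), value = TRUE)
  tibble::tibble(class = sub("^score_", "", score_cols),
                 mean_shift = vapply(score_cols,
                                     function(cn) mean(pert[[cn]] - base[[cn]]),
                                     numeric(1), USE.NAMES = FALSE),
                 band = band, gain = gain)
}
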