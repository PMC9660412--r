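# Discrete wavelet filter bank: two-channel quadrature-mirror decomposition
# with downsampling by 2, applied recursively to the approximation branch.
# Analysis follows the standard half-sample symmetric (or periodic) extension;
# synthesis is the exact inverse, so decompose -> reconstruct is lossless.

# Low-pass (scaling) taps of the supported orthogonal families. These are the
# standard published Daubechies/Symlet coefficients.
.wavelet_dec_lo <- list(
  haar = c(7.0710678118654757e-01, 7.0710678118654757e-01),
  db1 = c(7.0710678118654757e-01, 7.0710678118654757e-01),
  db2 = c(-1.2940952255126037e-01, 2.2414386804201339e-01, 8.3651630373780794e-01,
          4.8296291314453416e-01),
  db3 = c(3.5226291885709533e-02, -8.5441273882026658e-02, -1.3501102001025458e-01,
          4.5987750211849154e-01, 8.0689150931109255e-01, 3.3267055295008263e-01),
  db4 = c(-1.0597401785069032e-02, 3.2883011666885197e-02, 3.0841381835560764e-02,
          -1.8703481171909309e-01, -2.7983769416859854e-02, 6.3088076792985892e-01,
          7.1484657055291567e-01, 2.3037781330889651e-01),
  db5 = c(3.3357252854737712e-03, -1.2580751999081999e-02, -6.2414902127982744e-03,
          7.7571493840045719e-02, -3.2244869584638375e-02, -2.4229488706638203e-01,
          1.3842814590132074e-01, 7.2430852843777294e-01, 6.0382926979718965e-01,
          1.6010239797419293e-01),
  db6 = c(-1.0773010853084796e-03, 4.7772575109455108e-03, 5.5384220116149613e-04,
          -3.1582039317486030e-02, 2.7522865530305727e-02, 9.7501605587323043e-02,
          -1.2976686756726194e-01, -2.2626469396543983e-01, 3.1525035170919763e-01,
          7.5113390802109536e-01, 4.9462389039845306e-01, 1.1154074335010947e-01),
  db8 = c(-1.1747678412476953e-04, 6.7544940645056933e-04, -3.9174037337694705e-04,
          -4.8703529934515741e-03, 8.7460940474057766e-03, 1.3981027917398282e-02,
          -4.4088253930794755e-02, -1.7369301001807547e-02, 1.2874742662047847e-01,
          4.7248457391328279e-04, -2.8401554296154691e-01, -1.5829105256349306e-02,
          5.8535468365420673e-01, 6.7563073629728976e-01, 3.1287159091429995e-01,
          5.4415842243104008e-02),
  sym4 = c(-7.5765714789273325e-02, -2.9635527645998510e-02, 4.9761866763201545e-01,
           8.0373875180591614e-01, 2.9785779560527736e-01, -9.9219543576847216e-02,
           -1.2603967262037833e-02, 3.2223100604042702e-02),
  sym8 = c(-3.3824159510061256e-03, -5.4213233179114812e-04, 3.1695087811492981e-02,
           7.6074873249176054e-03, -1.4329423835080971e-01, -6.1273359067658524e-02,
           4.8135965125837221e-01, 7.7718575170052351e-01, 3.6444189483533140e-01,
           -5.1945838107709037e-02, -2.7219029917056003e-02, 4.9137179673607506e-02,
           3.8087520138906151e-03, -1.4952258337048231e-02, -3.0292051472136680e-04,
           1.8899503327594609e-03)
)

#' Quadrature-mirror analysis filter pair
#'
#' Returns the low-pass taps `h` of the requested orthogonal wavelet family
#' together with the high-pass mirror `g`, defined by the quadrature-mirror
#' relation `g[n] = (-1)^n h[L-1-n]` (0-based indexing).
#'
#' @param family Wavelet family identifier; one of `"haar"`/`"db1"`, `"db2"`,
#'   `"db3"`, `"db4"` (default), `"db5"`, `"db6"`, `"db8"`, `"sym4"`, `"sym8"`.
#' @return An object of class `wavelet_filters`: a list with elements `h`
#'   (low-pass taps), `g` (high-pass taps) and `family`.
#' @examples
#' f <- wavelet_filters("db4")
#' length(f$h)
#' @export
wavelet_filters <- function(family = "db4") {
  if (!is.character(family) || length(family) != 1L || !family %in% names(.wavelet_dec_lo)) {
    fail_field("family", paste("must be one of:", paste(names(.wavelet_dec_lo), collapse = ", ")))
  }
  h <- .wavelet_dec_lo[[family]]
  g <- qmf_mirror(h)
  structure(list(h = h, g = g, family = family), class = "wavelet_filters")
}

# g[n] = (-1)^n h[L-1-n], written 1-based
qmf_mirror <- function(h) (-1)^(seq_along(h) - 1) * rev(h)

#' @export
print.wavelet_filters <- function(x, ...) {
  cat(sprintf("<wavelet_filters> family %s, %d taps\n", x$family, length(x$h)))
  invisible(x)
}

# half-sample symmetric reflection of out-of-range indices into 1..n
reflect_index <- function(i, n) {
  repeat {
    bad_lo <- i < 1L
    bad_hi <- i > n
    if (!any(bad_lo) && !any(bad_hi)) return(i)
    i[bad_lo] <- 1L - i[bad_lo]
    i[bad_hi] <- 2L * n + 1L - i[bad_hi]
  }
}

# full linear convolution of u with f (length: length(u) + length(f) - 1)
conv_full <- function(u, f) {
  L <- length(f)
  e <- c(rep(0, L - 1), u, rep(0, L - 1))
  as.vector(stats::embed(e, L) %*% f)
}

#' One analysis step of the two-channel filter bank
#'
#' Filters a signal with the low-pass `h` and high-pass `g` of a
#' quadrature-mirror pair and downsamples each branch by 2, yielding the
#' approximation and detail coefficients of one decomposition level.
#'
#' @param x Numeric vector, `length(x) >= length(filters$h)`.
#' @param filters A [wavelet_filters()] pair.
#' @param extension Boundary handling: `"symmetric"` (half-sample reflection,
#'   default) or `"periodic"` (circular; requires even length and gives exact
#'   energy partition for orthogonal families).
#' @return A list with numeric vectors `approx` and `detail`. Under symmetric
#'   extension both have length `floor((n + L - 1) / 2)`; under periodic
#'   extension, `n / 2`.
#' @seealso [idwt_step()] for the exact inverse.
#' @export
dwt_step <- function(x, filters, extension = c("symmetric", "periodic")) {
  extension <- match.arg(extension)
  stopifnot(inherits(filters, "wavelet_filters"))
  n <- length(x)
  L <- length(filters$h)
  if (n < L) {
    abort(sprintf("signal (%d samples) is shorter than the %d-tap filter", n, L),
          class = "eegseize_wavelet_error")
  }
  if (extension == "symmetric") {
    idx <- reflect_index(seq.int(2L - L, n + L - 1L), n)
    e <- x[idx]
    m <- stats::embed(e, L)           # row i = reversed segment e[i..i+L-1]
    keep <- seq.int(2L, n + L - 1L, by = 2L)
    # correlation with the reversed taps == convolution with the taps
    list(approx = as.vector(m %*% filters$h)[keep],
         detail = as.vector(m %*% filters$g)[keep])
  } else {
    if (n %% 2L != 0L) {
      abort("periodic extension requires an even-length signal (pad first)",
            class = "eegseize_wavelet_error")
    }
    e <- c(x, x[seq_len(L - 1L)])
    m <- stats::embed(e, L)
    keep <- seq.int(1L, n, by = 2L)
    # y[k] = sum_m f[m] x[(k + m - 2) mod n + 1]; rows of embed() are reversed
    list(approx = as.vector(m %*% rev(filters$h))[keep],
         detail = as.vector(m %*% rev(filters$g))[keep])
  }
}

#' One synthesis step of the two-channel filter bank
#'
#' Exact inverse of [dwt_step()]: upsamples the approximation and detail
#' branches, filters with the synthesis pair and recombines.
#'
#' @param approx,detail Coefficient vectors from [dwt_step()] (equal length).
#' @param filters,extension As in [dwt_step()]; must match the analysis call.
#' @param out_length Length of the signal to reconstruct.
#' @return Numeric vector of length `out_length`.
#' @export
idwt_step <- function(approx, detail, filters, extension = c("symmetric", "periodic"),
                      out_length) {
  extension <- match.arg(extension)
  stopifnot(inherits(filters, "wavelet_filters"), length(approx) == length(detail))
  la <- length(approx)
  L <- length(filters$h)
  if (extension == "symmetric") {
    up_a <- numeric(2L * la - 1L); up_a[seq.int(1L, 2L * la - 1L, 2L)] <- approx
    up_d <- numeric(2L * la - 1L); up_d[seq.int(1L, 2L * la - 1L, 2L)] <- detail
    z <- conv_full(up_a, rev(filters$h)) + conv_full(up_d, rev(filters$g))
    avail <- 2L * la - L + 2L
    if (out_length > avail) {
      abort(sprintf("cannot reconstruct %d samples from %d coefficients", out_length, la),
            class = "eegseize_wavelet_error")
    }
    z[seq.int(L - 1L, length.out = out_length)]
  } else {
    n <- 2L * la
    if (out_length > n) {
      abort(sprintf("cannot reconstruct %d samples from %d coefficients", out_length, la),
            class = "eegseize_wavelet_error")
    }
    x <- numeric(n)
    pos0 <- 2L * (seq_len(la) - 1L)      # 0-based start of each tap run
    for (m in seq_len(L)) {
      at <- (pos0 + m - 1L) %% n + 1L
      contrib <- approx * filters$h[m] + detail * filters$g[m]
      x[at] <- x[at] + contrib
    }
    x[seq_len(out_length)]
  }
}

#' Nominal dyadic subband map of a multilevel decomposition
#'
#' Maps the conventional EEG rhythms to the detail/approximation branches of a
#' `levels`-deep dyadic filter bank at sampling rate `fs_hz`. At 256 Hz with 5
#' levels: delta is A5 (0-4 Hz), theta D5 (4-8), alpha D4 (8-16), beta D3
#' (16-32) and gamma D2 (32-64; optionally merged with D1 up to Nyquist). The
#' Hz edges are the dyadic approximations of the textbook band limits and are
#' metadata only; the coefficients themselves define the split.
#'
#' @param fs_hz Sampling rate in Hz.
#' @param levels Decomposition depth (default 5).
#' @param gamma_merge_d1 If `TRUE`, gamma covers D1 and D2 (up to Nyquist).
#' @return Named list (delta, theta, alpha, beta, gamma); each element lists
#'   the coefficient branch names (`coefs`) and nominal `lo_hz`/`hi_hz` edges.
#' @export
band_map <- function(fs_hz = 256, levels = 5L, gamma_merge_d1 = FALSE) {
  check_scalar_num(fs_hz, "fs_hz", lower = 0, strict = TRUE)
  if (levels < 2L) fail_field("levels", "at least 2 levels are needed to name bands")
  edge <- function(k) fs_hz / 2^k                      # D_k spans fs/2^(k+1) .. fs/2^k
  gamma_coefs <- if (gamma_merge_d1) c("d1", "d2") else "d2"
  bm <- list(
    delta = list(coefs = paste0("a", levels), lo_hz = 0, hi_hz = edge(levels + 1)),
    theta = list(coefs = paste0("d", levels), lo_hz = edge(levels + 1), hi_hz = edge(levels)),
    alpha = list(coefs = "d4", lo_hz = edge(5), hi_hz = edge(4)),
    beta  = list(coefs = "d3", lo_hz = edge(4), hi_hz = edge(3)),
    gamma = list(coefs = gamma_coefs, lo_hz = edge(3),
                 hi_hz = if (gamma_merge_d1) edge(1) else edge(2))
  )
  bm
}

#' Multilevel wavelet decomposition of one window
#'
#' Recursively applies [dwt_step()] to the approximation branch, retaining the
#' detail coefficients D1..Dlevels and the final approximation, per channel.
#'
#' @param window Numeric vector or samples-by-channels matrix.
#' @param fs_hz Sampling rate in Hz (kept as metadata for the band map).
#' @param levels Decomposition depth (default 5).
#' @param filters A [wavelet_filters()] pair.
#' @param extension Boundary extension, see [dwt_step()].
#' @param pad If `TRUE` (default), odd-length levels under periodic extension
#'   are zero-padded on the right (recorded in the result); if `FALSE` such
#'   inputs are an error.
#' @param gamma_merge_d1 Passed to [band_map()].
#' @return An object of class `subband_set`: coefficient matrices
#'   (coefficients x channels) named `d1..d<levels>`, `a<levels>`, plus the
#'   per-level input lengths and decomposition metadata.
#' @examples
#' sb <- decompose(sin(2 * pi * 10 * (0:76) / 256), fs_hz = 256)
#' names(sb$coeffs)
#' @export
decompose <- function(window, fs_hz, levels = 5L, filters = wavelet_filters(),
                      extension = c("symmetric", "periodic"), pad = TRUE,
                      gamma_merge_d1 = FALSE) {
  extension <- match.arg(extension)
  if (is.vector(window)) window <- matrix(window, ncol = 1L)
  if (!is.matrix(window) || !is.numeric(window)) {
    fail_field("window", "must be a numeric vector or samples-by-channels matrix")
  }
  n <- nrow(window); nc <- ncol(window)
  L <- length(filters$h)
  lengths <- integer(levels)   # (possibly padded) input length at each level
  pads <- integer(levels)
  details <- vector("list", levels)
  a <- window
  for (l in seq_len(levels)) {
    need_pad <- 0L
    if (extension == "periodic" && nrow(a) %% 2L != 0L) need_pad <- 1L
    if (nrow(a) + need_pad < L) {
      if (!pad) {
        abort(sprintf("level %d input (%d samples) too short for %d-tap filter and padding is disabled",
                      l, nrow(a), L), class = "eegseize_wavelet_error")
      }
      need_pad <- L - nrow(a)
      if (extension == "periodic" && (nrow(a) + need_pad) %% 2L != 0L) need_pad <- need_pad + 1L
    }
    if (need_pad > 0L && !pad) {
      abort(sprintf("level %d input has odd length %d and padding is disabled", l, nrow(a)),
            class = "eegseize_wavelet_error")
    }
    if (need_pad > 0L) a <- rbind(a, matrix(0, need_pad, nc))
    pads[l] <- need_pad
    lengths[l] <- nrow(a)
    out_a <- NULL; out_d <- NULL
    for (ch in seq_len(nc)) {
      s <- dwt_step(a[, ch], filters, extension)
      if (is.null(out_a)) {
        out_a <- matrix(0, length(s$approx), nc)
        out_d <- matrix(0, length(s$detail), nc)
      }
      out_a[, ch] <- s$approx
      out_d[, ch] <- s$detail
    }
    details[[l]] <- out_d
    a <- out_a
  }
  coeffs <- c(stats::setNames(details, paste0("d", seq_len(levels))),
              stats::setNames(list(a), paste0("a", levels)))
  structure(list(coeffs = coeffs, lengths = lengths, pads = pads, levels = levels,
                 fs_hz = fs_hz, n_samples = n, n_channels = nc,
                 filters = filters, extension = extension,
                 band_map = band_map(fs_hz, levels, gamma_merge_d1)),
            class = "subband_set")
}

#' @export
print.subband_set <- function(x, ...) {
  cat(sprintf("<subband_set> %d-level %s decomposition (%s extension), %d samples x %d channels @ %g Hz\n",
              x$levels, x$filters$family, x$extension, x$n_samples, x$n_channels, x$fs_hz))
  invisible(x)
}

# inverse transform keeping only the named coefficient branches
inverse_keep <- function(sb, keep) {
  a <- if (paste0("a", sb$levels) %in% keep) {
    sb$coeffs[[paste0("a", sb$levels)]]
  } else {
    0 * sb$coeffs[[paste0("a", sb$levels)]]
  }
  for (l in rev(seq_len(sb$levels))) {
    dn <- paste0("d", l)
    d <- if (dn %in% keep) sb$coeffs[[dn]] else 0 * sb$coeffs[[dn]]
    out <- matrix(0, sb$lengths[l], sb$n_channels)
    for (ch in seq_len(sb$n_channels)) {
      out[, ch] <- idwt_step(a[, ch], d[, ch], sb$filters, sb$extension,
                             out_length = sb$lengths[l])
    }
    if (sb$pads[l] > 0L) out <- out[seq_len(sb$lengths[l] - sb$pads[l]), , drop = FALSE]
    a <- out
  }
  a
}

#' Reconstruct a single frequency band as a time-domain signal
#'
#' Inverts the decomposition with every coefficient branch outside the named
#' band zeroed. Summing the five reconstructed bands recovers the original
#' window (the inverse transform is linear).
#'
#' @param sb A `subband_set` from [decompose()].
#' @param band_name One of `"delta"`, `"theta"`, `"alpha"`, `"beta"`, `"gamma"`.
#' @return Samples-by-channels matrix, same shape as the decomposed window.
#' @export
reconstruct_band <- function(sb, band_name) {
  stopifnot(inherits(sb, "subband_set"))
  if (!is.character(band_name) || length(band_name) != 1L ||
      !band_name %in% names(sb$band_map)) {
    fail_field("band_name", paste("must be one of:", paste(names(sb$band_map), collapse = ", ")))
  }
  inverse_keep(sb, sb$band_map[[band_name]]$coefs)
}

#' Full inverse of a multilevel decomposition
#'
#' @param sb A `subband_set` from [decompose()].
#' @return Samples-by-channels matrix equal (to numerical precision) to the
#'   decomposed window.
#' @export
reconstruct_all <- function(sb) {
  stopifnot(inherits(sb, "subband_set"))
  inverse_keep(sb, names(sb$coeffs))
}

# --- cached linear band-transfer operators -------------------------------

.band_matrix_cache <- new.env(parent = emptyenv())

# n x n matrix mapping a length-n signal to its reconstructed band component;
# built once per (n, band, family, extension, levels) by pushing the identity
# through decompose()/reconstruct_band(), then reused for whole window sets.
band_transfer_matrix <- function(n, band_name, fs_hz, levels = 5L,
                                 filters = wavelet_filters(),
                                 extension = "symmetric", gamma_merge_d1 = FALSE) {
  key <- paste(n, band_name, fs_hz, levels, filters$family, extension, gamma_merge_d1,
               sep = "|")
  hit <- .band_matrix_cache[[key]]
  if (!is.null(hit)) return(hit)
  sb <- decompose(diag(n), fs_hz, levels, filters, extension,
                  gamma_merge_d1 = gamma_merge_d1)
  m <- reconstruct_band(sb, band_name)
  .band_matrix_cache[[key]] <- m
  m
}
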