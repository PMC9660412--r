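# Record container, EDF read/write, CHB-MIT-style annotation summaries and
# the on-disk window-set container.
#
# Window container layout (version 1), little-endian throughout:
#   bytes 1-8   magic "EEGWINS1"
#   bytes 9-12  int32 header length H
#   H bytes     JSON header: version, dim (samples, channels, windows),
#               labels, class levels, offsets_s, fs_hz, config, provenance
#   rest        float64 window tensor, column-major in `dim` order

#' Multichannel EEG recording
#'
#' @param data Channels-by-samples numeric matrix (microvolt-like units).
#' @param fs_hz Sampling rate in samples/second.
#' @param channel_labels Character vector, one label per row of `data`.
#' @param subject_id Free-form subject/recording identifier.
#' @param annotations Tibble with columns `label` (nonseizure/onset/seizure),
#'   `start_s`, `end_s`; may be empty.
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(data, fs_hz, channel_labels = NULL, subject_id = "unknown",
                       annotations = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) fail_field("data", "must be a numeric matrix")
  check_scalar_num(fs_hz, "fs_hz", lower = 0, strict = TRUE)
  if (is.null(channel_labels)) channel_labels <- sprintf("CH%02d", seq_len(nrow(data)))
  if (length(channel_labels) != nrow(data)) {
    fail_field("channel_labels", "length must equal the number of data rows")
  }
  if (is.null(annotations)) {
    annotations <- tibble::tibble(label = character(), start_s = numeric(),
                                  end_s = numeric())
  }
  dur <- ncol(data) / fs_hz
  if (nrow(annotations) > 0) {
    if (any(annotations$start_s >= annotations$end_s)) {
      fail_field("annotations", "start_s must be < end_s")
    }
    if (any(annotations$start_s < 0) || any(annotations$end_s > dur + 1e-9)) {
      fail_field("annotations", "intervals must lie within [0, duration]")
    }
  }
  structure(list(subject_id = subject_id, channel_labels = channel_labels,
                 data = data, fs_hz = fs_hz, annotations = annotations),
            class = "eeg_record")
}

record_duration <- function(record) ncol(record$data) / record$fs_hz

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %s: %d channels x %d samples @ %g Hz (%.1f s), %d annotation(s)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs_hz,
              record_duration(x), nrow(x$annotations)))
  invisible(x)
}

# --- EDF ------------------------------------------------------------------

pad_ascii <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a recording to European Data Format
#'
#' Minimal EDF writer: one 16-bit data record holding the full signal, equal
#' sampling rate on all channels, physical range set to the data range.
#' Annotations are not stored (plain EDF has no annotation channel); use the
#' summary-text format for seizure intervals.
#'
#' @param record An [eeg_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  nch <- nrow(record$data)
  ns <- ncol(record$data)
  # the scaling must use the value as written in the 8-char ASCII field,
  # or the reader would apply a slightly different gain
  phys_str <- formatC(signif(max(abs(record$data), 1e-6) * 1.000001, 6),
                      format = "g", width = 1)
  phys_max <- as.numeric(phys_str)
  dig_max <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * nch
  writeChar(paste0(
    pad_ascii("0", 8), pad_ascii(record$subject_id, 80), pad_ascii("eegseize", 80),
    pad_ascii("01.01.20", 8), pad_ascii("00.00.00", 8), pad_ascii(hdr_bytes, 8),
    pad_ascii("", 44), pad_ascii(1, 8),
    pad_ascii(format(record_duration(record), digits = 10), 8), pad_ascii(nch, 4)
  ), con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste(vapply(vals, pad_ascii, character(1), width = width), collapse = ""),
              con, eos = NULL)
  }
  field(record$channel_labels, 16)
  field(rep("", nch), 80)                       # transducer
  field(rep("uV", nch), 8)                      # physical dimension
  field(rep(paste0("-", phys_str), nch), 8)
  field(rep(phys_str, nch), 8)
  field(rep(-dig_max, nch), 8)   # symmetric range so gain is exactly p/32767
  field(rep(dig_max, nch), 8)
  field(rep("", nch), 80)                       # prefiltering
  field(rep(ns, nch), 8)                        # samples per data record
  field(rep("", nch), 32)
  scale <- dig_max / phys_max
  dig <- t(round(record$data * scale))          # channel-sequential within record
  dig <- pmax(pmin(dig, dig_max), -dig_max)
  writeBin(as.integer(dig), con, size = 2L, endian = "little")
  invisible(path)
}

read_ascii <- function(con, n) {
  s <- suppressWarnings(readChar(con, n, useBytes = TRUE))
  if (length(s) == 0L) "" else trimws(s)
}

#' Read a European Data Format recording
#'
#' Reads channel labels, sampling rate and the full signal of an EDF file.
#' All channels must share one sampling rate; EDF carries no seizure
#' annotations, so the result has none.
#'
#' @param path Path to an existing EDF file.
#' @return An [eeg_record()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("EDF file not found: %s", path), class = "eegseize_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  read_ascii(con, 8)                            # version
  subject_id <- read_ascii(con, 80)
  read_ascii(con, 80 + 8 + 8)                   # recording id, date, time
  read_ascii(con, 8)                            # header bytes
  read_ascii(con, 44)
  n_rec <- suppressWarnings(as.integer(read_ascii(con, 8)))
  dur_rec <- suppressWarnings(as.numeric(read_ascii(con, 8)))
  nch <- suppressWarnings(as.integer(read_ascii(con, 4)))
  if (is.na(nch) || nch < 1L || is.na(n_rec) || n_rec < 1L || is.na(dur_rec)) {
    abort(sprintf("corrupt EDF header in %s", path), class = "eegseize_io_error")
  }
  fields <- function(width) vapply(seq_len(nch), function(i) read_ascii(con, width),
                                   character(1))
  labels <- fields(16); fields(80); fields(8)
  phys_min <- as.numeric(fields(8)); phys_max <- as.numeric(fields(8))
  dig_min <- as.numeric(fields(8)); dig_max <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))
  fields(32)
  if (length(unique(spr)) != 1L) {
    abort("channels with unequal sampling rates are not supported",
          class = "eegseize_io_error")
  }
  fs <- spr[1] / dur_rec
  data <- matrix(0, nch, spr[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(nch)) {
      raw <- readBin(con, "integer", n = spr[ch], size = 2L, endian = "little",
                     signed = TRUE)
      if (length(raw) < spr[ch]) {
        abort(sprintf("truncated EDF data in %s", path), class = "eegseize_io_error")
      }
      gain <- (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
      data[ch, ((r - 1L) * spr[ch] + 1L):(r * spr[ch])] <-
        phys_min[ch] + (raw - dig_min[ch]) * gain
    }
  }
  eeg_record(data, fs_hz = fs, channel_labels = labels, subject_id = subject_id)
}

# --- CHB-MIT summary text -------------------------------------------------

#' Parse a CHB-MIT-style seizure annotation summary
#'
#' Parses the plain-text summary dialect used by the CHB-MIT corpus
#' (`File Name:`, `Number of Seizures in File:`, `Seizure Start Time: N
#' seconds`, `Seizure End Time: N seconds`, with the numbered variants
#' `Seizure 1 Start Time:` etc.). Every declared seizure becomes an interval
#' labeled `"seizure"`; files declaring zero seizures map to empty tibbles.
#'
#' @param text Summary text: a single string or a character vector of lines.
#' @return Named list, one tibble (`label`, `start_s`, `end_s`) per declared
#'   file.
#' @export
parse_chbmit_summary <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  file_at <- grep("^\\s*File Name\\s*:", lines)
  out <- list()
  bounds <- c(file_at, length(lines) + 1L)
  for (b in seq_along(file_at)) {
    block <- lines[bounds[b]:(bounds[b + 1L] - 1L)]
    fname <- trimws(sub("^\\s*File Name\\s*:", "", block[1]))
    n_line <- grep("^\\s*Number of Seizures in File\\s*:", block, value = TRUE)
    if (length(n_line) != 1L) {
      abort(sprintf("block for %s: missing seizure count", fname),
            class = "eegseize_parse_error")
    }
    n_seiz <- as.integer(trimws(sub(".*:", "", n_line)))
    grab <- function(what) {
      m <- grep(sprintf("^\\s*Seizure( \\d+)? %s Time\\s*:", what), block, value = TRUE)
      as.numeric(gsub("[^0-9.]", "", sub(".*:", "", m)))
    }
    starts <- grab("Start"); ends <- grab("End")
    if (length(starts) != n_seiz || length(ends) != n_seiz) {
      abort(sprintf("block for %s declares %d seizure(s) but lists %d start/%d end time(s)",
                    fname, n_seiz, length(starts), length(ends)),
            class = "eegseize_parse_error")
    }
    if (any(starts >= ends)) {
      abort(sprintf("block for %s: seizure start >= end", fname),
            class = "eegseize_parse_error")
    }
    out[[fname]] <- tibble::tibble(label = rep("seizure", n_seiz),
                                   start_s = starts, end_s = ends)
  }
  out
}

# --- window-set container -------------------------------------------------

.ws_magic <- "EEGWINS1"
.ws_version <- 1L

#' Save / load a window set
#'
#' Lossless round-trip of the window tensor, labels, offsets and provenance
#' metadata through a single self-describing file: an 8-byte magic, a JSON
#' header and a little-endian float64 payload (layout documented in the
#' source).
#'
#' @param ws A `window_set` (see [segment()]).
#' @param path File path.
#' @return `save_windowset()` returns `path` invisibly; `load_windowset()`
#'   returns the restored `window_set`.
#' @export
save_windowset <- function(ws, path) {
  stopifnot(inherits(ws, "window_set"))
  header <- list(version = .ws_version, dim = dim(ws$windows),
                 labels = as.character(ws$labels),
                 class_levels = levels(ws$labels),
                 offsets_s = ws$offsets_s, fs_hz = ws$fs_hz,
                 config = unclass(ws$config), provenance = ws$provenance)
  json <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA, null = "null")
  raw_json <- charToRaw(as.character(json))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(.ws_magic, con, eos = NULL)
  writeBin(length(raw_json), con, size = 4L, endian = "little")
  writeBin(raw_json, con)
  writeBin(as.vector(ws$windows), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname save_windowset
#' @export
load_windowset <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("window container not found: %s", path), class = "eegseize_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, nchar(.ws_magic), useBytes = TRUE)
  if (!identical(magic, .ws_magic)) {
    abort(sprintf("%s is not a window container (bad magic)", path),
          class = "eegseize_io_error")
  }
  hlen <- readBin(con, "integer", size = 4L, endian = "little")
  if (length(hlen) != 1L || is.na(hlen) || hlen <= 0L) {
    abort(sprintf("truncated window container: %s", path), class = "eegseize_io_error")
  }
  raw_json <- readBin(con, "raw", n = hlen)
  if (length(raw_json) < hlen) {
    abort(sprintf("truncated window container: %s", path), class = "eegseize_io_error")
  }
  header <- jsonlite::fromJSON(rawToChar(raw_json), simplifyVector = TRUE)
  if (!identical(as.integer(header$version), .ws_version)) {
    abort(sprintf("window container version %s not supported (expected %d)",
                  header$version, .ws_version), class = "eegseize_io_error")
  }
  n_vals <- prod(header$dim)
  payload <- readBin(con, "double", n = n_vals, size = 8L, endian = "little")
  if (length(payload) < n_vals) {
    abort(sprintf("truncated window container: %s", path), class = "eegseize_io_error")
  }
  cfg <- header$config
  config <- do.call(windowing_config, cfg[intersect(names(cfg), names(formals(windowing_config)))])
  new_window_set(array(payload, dim = header$dim),
                 labels = factor(header$labels, levels = header$class_levels),
                 offsets_s = as.numeric(header$offsets_s), fs_hz = header$fs_hz,
                 config = config, provenance = header$provenance)
}
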