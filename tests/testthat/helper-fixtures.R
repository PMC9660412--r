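# Shared fixtures: everything is generated in code at test time.

# small, fast labeled window set: 128 Hz, 4 channels, 38-sample windows
small_windowset <- function(classes = 2L, n_records = 2L, duration_s = 4.06,
                            fs_hz = 128, n_channels = 4L, seed = 3L,
                            class_params = list()) {
  make_labeled_dataset(
    n_records, classes = classes,
    spec = signal_spec(duration_s = duration_s, fs_hz = fs_hz,
                       n_channels = n_channels, seed = seed),
    class_params = class_params, seed = seed)
}

# light architecture matching small_windowset geometry (38 x 4 input)
small_arch <- function(n_classes = 2L, pool_mode = "max") {
  build_architecture("lw", n_classes, input_shape = c(38L, 4L),
                     pool_mode = pool_mode)
}

# mean band power of one channel over a frequency range, via periodogram
band_power <- function(x, fs_hz, lo, hi) {
  n <- length(x)
  freq <- (seq_len(n) - 1L) * fs_hz / n
  p <- Mod(stats::fft(x))^2 / n
  mean(p[freq >= lo & freq < hi])
}

# brute-force cross-correlation oracle for conv_forward
conv_oracle <- function(x, w, b, act = identity) {
  d <- dim(x)                       # (T, C, D)
  k <- dim(w)                       # (kt, kc, D, F)
  To <- d[1] - k[1] + 1L; Co <- d[2] - k[2] + 1L
  out <- array(0, c(To, Co, k[4]))
  for (f in seq_len(k[4])) for (to in seq_len(To)) for (co in seq_len(Co)) {
    acc <- 0
    for (dt in seq_len(k[1])) for (dc in seq_len(k[2])) for (dd in seq_len(d[3])) {
      acc <- acc + x[to + dt - 1L, co + dc - 1L, dd] * w[dt, dc, dd, f]
    }
    out[to, co, f] <- act(acc + b[f])
  }
  out
}
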