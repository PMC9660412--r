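# End-to-end orchestration behind the command-line interface: configuration
# handling, the simulate command (write synthetic EDF + annotations +
# window containers) and the full run command (segment -> label ->
# decompose -> cross-validated training -> correlation map), with a
# reproducibility manifest in every output directory.

#' Assemble (and validate) a pipeline run configuration
#'
#' All fields have working defaults so `run_config()` describes a reduced
#' synthetic experiment. The same structure is read from YAML by the command
#' line interface; unknown fields are rejected.
#'
#' @param input `"synthetic"` (default) or a directory of EDF files.
#' @param summary_file Optional CHB-MIT-style annotation summary (for EDF
#'   input).
#' @param output_dir Where artifacts are written.
#' @param seed Global seed for generation, fold splitting and training.
#' @param synthetic List: `n_records`, `classes`, `duration_s`, `fs_hz`,
#'   `n_channels`, `onset_gain`, `seizure_gain`.
#' @param windowing List of [windowing_config()] fields.
#' @param wavelet List: `family`, `extension`, `levels`, `gamma_merge_d1`.
#' @param arch List: `weight_class`, `n_classes`, `pool_mode`.
#' @param train List of [train_config()] fields.
#' @param evaluation List: `k`, `repeats`, `bands`, `decomposition` (one of
#'   `"both"`, `"with"`, `"without"`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = "synthetic", summary_file = NULL,
                       output_dir = tempfile("eegseize-run-"), seed = 1L,
                       synthetic = list(), windowing = list(), wavelet = list(),
                       arch = list(), train = list(), evaluation = list()) {
  syn <- utils::modifyList(list(n_records = 1L, classes = 2L, duration_s = 10,
                                fs_hz = 256, n_channels = 4L, onset_gain = 2,
                                seizure_gain = 4), synthetic)
  wav <- utils::modifyList(list(family = "db4", extension = "symmetric",
                                levels = 5L, gamma_merge_d1 = FALSE), wavelet)
  ar <- utils::modifyList(list(weight_class = "mw", n_classes = syn$classes,
                               pool_mode = "stochastic"), arch)
  ev <- utils::modifyList(list(k = 3L, repeats = 1L, bands = "beta",
                               decomposition = "both"), evaluation)
  cfg <- structure(list(input = input, summary_file = summary_file,
                        output_dir = output_dir, seed = as.integer(seed),
                        synthetic = syn,
                        windowing = do.call(windowing_config, windowing),
                        wavelet = wav, arch = ar,
                        train = do.call(train_config,
                                        utils::modifyList(list(seed = as.integer(seed)),
                                                          train)),
                        evaluation = ev),
                   class = "run_config")
  if (!ev$decomposition %in% c("both", "with", "without")) {
    fail_field("evaluation$decomposition", "must be both, with or without")
  }
  cfg
}

write_manifest <- function(cfg, dir, extra = list()) {
  manifest <- c(list(package_version = as.character(utils::packageVersion("eegseize")),
                     seed = cfg$seed, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                     config = rapply(unclass(cfg), unclass, how = "replace")),
                extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
}

#' Generate and write synthetic fixtures (simulate command)
#'
#' Writes one EDF per class record, a CHB-MIT-style annotation summary for
#' the seizure intervals, the labeled window container and a manifest
#' recording the seed and configuration.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the written paths and the window set.
#' @export
cmd_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  syn <- cfg$synthetic
  spec <- signal_spec(duration_s = syn$duration_s, fs_hz = syn$fs_hz,
                      n_channels = syn$n_channels, seed = cfg$seed)
  lv <- seizure_class_levels(syn$classes)
  gains <- c(nonseizure = 1, onset = syn$onset_gain, seizure = syn$seizure_gain)
  edf_paths <- character(0)
  summary_lines <- character(0)
  idx <- 0L
  for (cl in lv) {
    for (r in seq_len(syn$n_records)) {
      idx <- idx + 1L
      rec_spec <- spec; rec_spec$seed <- cfg$seed + 1000L * idx
      rec <- generate_background(rec_spec)
      if (cl != "nonseizure") {
        rec <- inject_events(rec,
                             list(event_spec(cl, 0, record_duration(rec),
                                             amplitude_gain = gains[[cl]])),
                             seed = rec_spec$seed + 1L)
      }
      fname <- sprintf("%s_%02d.edf", cl, r)
      write_edf(rec, file.path(cfg$output_dir, fname))
      edf_paths <- c(edf_paths, fname)
      n_seiz <- sum(rec$annotations$label == "seizure")
      summary_lines <- c(summary_lines,
                         sprintf("File Name: %s", fname),
                         sprintf("Number of Seizures in File: %d", n_seiz))
      si <- rec$annotations[rec$annotations$label == "seizure", , drop = FALSE]
      for (j in seq_len(nrow(si))) {
        summary_lines <- c(summary_lines,
                           sprintf("Seizure %d Start Time: %d seconds", j, round(si$start_s[j])),
                           sprintf("Seizure %d End Time: %d seconds", j, round(si$end_s[j])))
      }
      summary_lines <- c(summary_lines, "")
    }
  }
  writeLines(summary_lines, file.path(cfg$output_dir, "summary.txt"))
  ws <- make_labeled_dataset(syn$n_records, classes = syn$classes, spec = spec,
                             class_params = list(onset_gain = syn$onset_gain,
                                                 seizure_gain = syn$seizure_gain),
                             config = cfg$windowing, seed = cfg$seed)
  ws_path <- file.path(cfg$output_dir, "windows.eegwins")
  save_windowset(ws, ws_path)
  write_manifest(cfg, cfg$output_dir,
                 list(edf_files = edf_paths, summary_file = "summary.txt",
                      windowset = basename(ws_path)))
  invisible(list(edf = file.path(cfg$output_dir, edf_paths),
                 summary = file.path(cfg$output_dir, "summary.txt"),
                 windowset = ws_path, windows = ws))
}

load_input_windows <- function(cfg) {
  if (identical(cfg$input, "synthetic")) {
    syn <- cfg$synthetic
    spec <- signal_spec(duration_s = syn$duration_s, fs_hz = syn$fs_hz,
                        n_channels = syn$n_channels, seed = cfg$seed)
    make_labeled_dataset(syn$n_records, classes = syn$classes, spec = spec,
                         class_params = list(onset_gain = syn$onset_gain,
                                             seizure_gain = syn$seizure_gain),
                         config = cfg$windowing, seed = cfg$seed)
  } else {
    files <- list.files(cfg$input, pattern = "\\.edf$", full.names = TRUE)
    if (length(files) == 0L) {
      abort(sprintf("no EDF files under %s", cfg$input), class = "eegseize_io_error")
    }
    ann <- if (!is.null(cfg$summary_file)) {
      parse_chbmit_summary(readLines(cfg$summary_file))
    } else list()
    sets <- lapply(files, function(f) {
      rec <- read_edf(f)
      a <- ann[[basename(f)]]
      if (!is.null(a)) rec$annotations <- a
      segment(rec, cfg$windowing, n_classes = cfg$arch$n_classes)
    })
    bind_window_sets(sets)
  }
}

#' Execute the full pipeline (run command)
#'
#' Segments and labels the input (synthetic or EDF), optionally decomposes
#' windows into subbands, runs the repeated k-fold evaluation for the
#' with/without-decomposition arms, computes a correlation map of the first
#' convolution layer of the final model, and writes every artifact plus a
#' manifest under `cfg$output_dir`.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the `eval_report`, the final model and the
#'   correlation map.
#' @export
cmd_run <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  ws <- load_input_windows(cfg)
  filters <- wavelet_filters(cfg$wavelet$family)
  arms <- list()
  if (cfg$evaluation$decomposition %in% c("both", "without")) arms$raw <- ws
  if (cfg$evaluation$decomposition %in% c("both", "with")) {
    arms <- c(arms, decompose_windowset(ws, bands = cfg$evaluation$bands,
                                        filters = filters,
                                        extension = cfg$wavelet$extension,
                                        levels = cfg$wavelet$levels,
                                        gamma_merge_d1 = cfg$wavelet$gamma_merge_d1))
  }
  arch <- build_architecture(cfg$arch$weight_class, cfg$arch$n_classes,
                             input_shape = dim(ws$windows)[1:2],
                             pool_mode = cfg$arch$pool_mode)
  report <- run_cv(arch, arms, train_cfg = cfg$train, k = cfg$evaluation$k,
                   repeats = cfg$evaluation$repeats)
  write_eval_report(report, file.path(cfg$output_dir, "evaluation"))
  final_model <- train_dcnn(arch, ws, cfg$train)
  cmap <- correlation_map(final_model, 1L, ws)
  utils::write.table(cmap, file.path(cfg$output_dir, "correlation_map.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_manifest(cfg, cfg$output_dir,
                 list(n_windows = n_windows(ws),
                      arms = names(arms),
                      mean_accuracy = mean(report$summary$mean)))
  invisible(list(report = report, model = final_model, correlation_map = cmap))
}
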