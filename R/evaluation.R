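# Evaluation protocol: accuracy/sensitivity/specificity from confusion
# counts, repeated stratified k-fold cross-validation with best/mean/worst
# +/- SD reporting, ROC/AUC by cutoff sweep, and paired t-tests between
# configurations.

#' Confusion counts for a binary (or one-vs-rest) decision
#'
#' @param truth Logical or factor of true labels.
#' @param pred Predicted labels, same type.
#' @param positive The positive class (defaults to the last factor level).
#' @return A list of class `confusion_matrix` with counts `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion_matrix <- function(truth, pred, positive = NULL) {
  if (is.factor(truth) || is.character(truth)) {
    if (is.null(positive)) positive <- utils::tail(levels(factor(truth)), 1)
    truth <- truth == positive
    pred <- pred == positive
  }
  structure(list(TP = sum(truth & pred), TN = sum(!truth & !pred),
                 FP = sum(!truth & pred), FN = sum(truth & !pred)),
            class = "confusion_matrix")
}

#' Accuracy, sensitivity and specificity of a confusion matrix
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`. A metric with a zero denominator is returned as `NA` and
#' flagged in `undefined`, never silently as 0.
#'
#' @param cm A [confusion_matrix()] or a list with `TP`, `TN`, `FP`, `FN`.
#' @return A one-row tibble: `accuracy`, `sensitivity`, `specificity`,
#'   `undefined` (character vector of undefined metrics, empty string if
#'   none).
#' @examples
#' metrics(list(TP = 9, TN = 8, FP = 1, FN = 2))
#' @export
metrics <- function(cm) {
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  acc <- safe_div(cm$TP + cm$TN, cm$TP + cm$TN + cm$FP + cm$FN)
  sens <- safe_div(cm$TP, cm$TP + cm$FN)
  spec <- safe_div(cm$TN, cm$TN + cm$FP)
  und <- c(if (is.na(acc)) "accuracy", if (is.na(sens)) "sensitivity",
           if (is.na(spec)) "specificity")
  tibble::tibble(accuracy = acc, sensitivity = sens, specificity = spec,
                 undefined = paste(und, collapse = ","))
}

#' Repeated stratified k-fold assignments
#'
#' Partitions `n` indices into `k` folds per repeat, stratified by class:
#' within every class the indices are shuffled and dealt round-robin, so fold
#' sizes differ by at most one and per-fold class proportions stay within one
#' sample of the global proportions.
#'
#' @param labels Class labels (factor/character), or a bare integer `n` for
#'   unstratified splitting.
#' @param k Number of folds (default 10).
#' @param repeats Number of repeated shufflings (default 5).
#' @param seed Seed; repeats differ by construction.
#' @return A tibble: `repeat_id`, `fold`, `index`.
#' @export
kfold_splits <- function(labels, k = 10L, repeats = 5L, seed = 1L) {
  if (length(labels) == 1L && is.numeric(labels)) labels <- rep("all", labels)
  n <- length(labels)
  if (n < k) {
    abort(sprintf("cannot make %d folds from %d observations", k, n),
          class = "eegseize_validation_error")
  }
  labels <- factor(labels)
  with_rng(seed, purrr::map_dfr(seq_len(repeats), function(r) {
    fold <- integer(n)
    offset <- 0L
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      # continue dealing across classes so overall fold sizes stay balanced
      fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- offset + length(idx)
    }
    tibble::tibble(repeat_id = r, fold = fold, index = seq_len(n))
  }))
}

#' ROC curve and AUC by cutoff sweep
#'
#' Sweeps the decision cutoff over the unique scores (ties cross the
#' threshold simultaneously) and accumulates the true- and false-positive
#' fractions; the area is the trapezoid rule over the resulting polyline.
#'
#' @param scores Numeric scores, larger meaning more positive.
#' @param labels Binary labels (logical, 0/1, or 2-level factor where the
#'   last level is positive).
#' @param positive Positive class for factor labels.
#' @return A list of class `roc_curve`: `points` (tibble `cutoff`, `fpr`,
#'   `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  if (is.factor(labels) || is.character(labels)) {
    if (is.null(positive)) positive <- utils::tail(levels(factor(labels)), 1)
    labels <- labels == positive
  }
  labels <- as.logical(labels)
  if (any(!is.finite(scores))) fail_field("scores", "must be finite")
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L) {
    abort("ROC needs both classes present", class = "eegseize_validation_error")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))            # tied scores collapse to one step
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)
  pts <- tibble::tibble(cutoff = c(Inf, s[last]),
                        fpr = c(0, fp[last] / nn),
                        tpr = c(0, tp[last] / np))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.4f (%d cutoffs)\n", x$auc, nrow(x$points)))
  invisible(x)
}

#' Plot an ROC curve
#' @param object A `roc_curve`.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false-positive fraction", y = "true-positive fraction",
                  subtitle = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Paired t-test between two fold-matched metric vectors
#'
#' Standard paired t statistic with a two-sided p-value. When the paired
#' differences have zero variance the result is degenerate (flagged, with
#' `NA` statistics) rather than an error or an infinite statistic.
#'
#' @param a,b Equal-length numeric vectors, paired by fold.
#' @return A one-row tibble: `t`, `df`, `p_value`, `mean_diff`, `degenerate`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L) {
    fail_field("a", "needs two equal-length vectors with >= 2 pairs")
  }
  d <- a - b
  if (sd(d) <= .Machine$double.eps^0.5 * (abs(mean(d)) + 1)) {
    return(tibble::tibble(t = NA_real_, df = length(d) - 1L, p_value = NA_real_,
                          mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, mean_diff = unname(tt$estimate),
                 degenerate = FALSE)
}

# one-vs-rest metrics for every class + macro accuracy, as a wide one-row df
multiclass_metrics <- function(truth, pred) {
  lv <- levels(factor(truth))
  per <- purrr::map_dfr(lv, function(cl) {
    dplyr::mutate(metrics(confusion_matrix(truth, pred, positive = cl)), class = cl)
  })
  tibble::tibble(accuracy = mean(truth == pred),
                 macro_accuracy = mean(vapply(lv, function(cl) {
                   mean(pred[truth == cl] == cl)
                 }, numeric(1))),
                 sensitivity = mean(per$sensitivity, na.rm = TRUE),
                 specificity = mean(per$specificity, na.rm = TRUE))
}

#' Repeated k-fold evaluation of architectures over subband window sets
#'
#' Runs the full protocol: for each arm (a named window set: the raw windows
#' and/or band-reconstructed sets from [decompose_windowset()]), each repeat
#' and each fold, trains a fresh network on the out-of-fold windows and
#' evaluates on the held-out fold. Fold metrics are aggregated per
#' (arm, repeat) into best/mean/worst with the SD over folds, and a ROC/AUC
#' is computed per arm and repeat from the pooled held-out scores of the
#' positive (last) class.
#'
#' @param arch An [build_architecture()] spec.
#' @param windowsets Named list of labeled `window_set`s (e.g. `raw` plus
#'   band sets); names become the `arm` column.
#' @param train_cfg A [train_config()].
#' @param k Folds per repeat (default 10).
#' @param repeats Repeats (default 5).
#' @return An object of class `eval_report`: tibbles `$folds` (per-fold
#'   metrics), `$summary` (best/mean/worst +/- SD per arm and repeat) and
#'   `$roc` (one `roc_curve` per arm/repeat), plus the run settings.
#' @export
run_cv <- function(arch, windowsets, train_cfg = train_config(), k = 10L,
                   repeats = 5L) {
  if (inherits(windowsets, "window_set")) windowsets <- list(raw = windowsets)
  if (is.null(names(windowsets)) || any(names(windowsets) == "")) {
    fail_field("windowsets", "must be a named list of window sets")
  }
  folds_out <- list()
  rocs <- list()
  for (arm in names(windowsets)) {
    ws <- windowsets[[arm]]
    splits <- kfold_splits(ws$labels, k = k, repeats = repeats,
                           seed = train_cfg$seed)
    for (r in seq_len(repeats)) {
      sp <- splits[splits$repeat_id == r, ]
      pooled_scores <- numeric(0)
      pooled_truth <- character(0)
      for (f in seq_len(k)) {
        hold <- sp$index[sp$fold == f]
        cfg_f <- train_cfg
        cfg_f$seed <- train_cfg$seed + 97L * r + f
        model <- train_dcnn(arch, ws[-hold], cfg_f)
        pr <- predict(model, ws[hold])
        truth <- ws$labels[hold]
        mm <- multiclass_metrics(truth, pr$label)
        folds_out[[length(folds_out) + 1L]] <-
          dplyr::bind_cols(tibble::tibble(arm = arm, repeat_id = r, fold = f),
                           mm)
        pos <- utils::tail(levels(truth), 1)
        pooled_scores <- c(pooled_scores, pr[[paste0("score_", pos)]])
        pooled_truth <- c(pooled_truth, as.character(truth))
      }
      rocs[[paste(arm, r, sep = ".")]] <-
        roc_auc(pooled_scores, pooled_truth == utils::tail(levels(ws$labels), 1))
    }
  }
  folds <- dplyr::bind_rows(folds_out)
  summary <- folds |>
    dplyr::group_by(.data$arm, .data$repeat_id) |>
    dplyr::summarise(best = max(.data$accuracy), mean = mean(.data$accuracy),
                     worst = min(.data$accuracy), sd = sd(.data$accuracy),
                     .groups = "drop") |>
    dplyr::mutate(auc = vapply(paste(.data$arm, .data$repeat_id, sep = "."),
                               function(key) rocs[[key]]$auc, numeric(1)))
  structure(list(folds = folds, summary = summary, roc = rocs,
                 k = k, repeats = repeats, arch = arch$weight_class,
                 n_classes = arch$n_classes),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s architecture, %d classes, %d-fold x %d repeat(s)\n",
              x$arch, x$n_classes, x$k, x$repeats))
  print(x$summary)
  invisible(x)
}

#' Per-fold results of an evaluation report
#' @param x An `eval_report`.
#' @param ... Ignored.
#' @return The per-fold metrics tibble.
#' @exportS3Method generics::tidy
tidy.eval_report <- function(x, ...) x$folds

#' One-row-per-arm summary of an evaluation report
#' @param x An `eval_report`.
#' @param ... Ignored.
#' @return Tibble with overall mean/best/worst accuracy and mean AUC per arm.
#' @exportS3Method generics::glance
glance.eval_report <- function(x, ...) {
  x$summary |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(mean_accuracy = mean(.data$mean), best = max(.data$best),
                     worst = min(.data$worst), mean_auc = mean(.data$auc),
                     .groups = "drop")
}

#' Write an evaluation report to tab-separated files
#'
#' Emits `summary.tsv` (best/mean/worst +/- SD per arm and repeat),
#' `folds.tsv`, `roc_points.csv` and a machine-readable `report.json` under
#' `dir`.
#'
#' @param report An `eval_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$summary, file.path(dir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$folds, file.path(dir, "folds.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  pts <- purrr::imap_dfr(report$roc, function(rc, key) {
    dplyr::mutate(rc$points, run = key)
  })
  utils::write.csv(pts, file.path(dir, "roc_points.csv"), row.names = FALSE)
  jsonlite::write_json(list(summary = report$summary, folds = report$folds,
                            auc = purrr::map_dbl(report$roc, "auc"),
                            k = report$k, repeats = report$repeats),
                       file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
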