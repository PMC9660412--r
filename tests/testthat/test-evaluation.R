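test_that("metrics follow the confusion-count formulas exactly", {
  m <- metrics(list(TP = 9, TN = 8, FP = 1, FN = 2))
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$sensitivity, 9 / 11)
  expect_equal(m$specificity, 8 / 9)
  perfect <- metrics(list(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_equal(unlist(perfect[1, 1:3]), c(accuracy = 1, sensitivity = 1,
                                          specificity = 1))
  expect_equal(metrics(list(TP = 0, TN = 3, FP = 0, FN = 4))$sensitivity, 0)
  undef <- metrics(list(TP = 0, TN = 3, FP = 1, FN = 0))
  expect_true(is.na(undef$sensitivity))
  expect_match(undef$undefined, "sensitivity")
})

test_that("confusion_matrix counts one-vs-rest decisions", {
  truth <- factor(c("a", "a", "b", "b", "b"))
  pred <- factor(c("a", "b", "b", "b", "a"))
  cm <- confusion_matrix(truth, pred, positive = "b")
  expect_identical(unclass(cm)[c("TP", "TN", "FP", "FN")],
                   list(TP = 2L, TN = 1L, FP = 1L, FN = 1L))
})

test_that("k-fold splits partition, balance and stratify", {
  sp <- kfold_splits(rep("x", 100), k = 10, repeats = 2, seed = 4)
  for (r in 1:2) {
    spr <- sp[sp$repeat_id == r, ]
    expect_identical(sort(spr$index), 1:100)
    expect_true(all(table(spr$fold) == 10))
  }
  expect_false(identical(sp$fold[sp$repeat_id == 1], sp$fold[sp$repeat_id == 2]))
  # stratification on a 70/30 labeled set
  labels <- rep(c("neg", "pos"), c(70, 30))
  sp <- kfold_splits(labels, k = 10, repeats = 1, seed = 1)
  per_fold <- table(sp$fold, labels[sp$index])
  expect_true(all(abs(per_fold[, "pos"] - 3) <= 1))
  expect_true(all(abs(per_fold[, "neg"] - 7) <= 1))
  expect_true(all(abs(rowSums(per_fold) - 10) <= 1))
  expect_error(kfold_splits(rep("x", 5), k = 10), "folds")
})

test_that("ROC handles separation, reversal and ties", {
  sep <- roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(sep$auc, 1)
  rev <- roc_auc(-c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(rev$auc, 0)
  set.seed(8)
  s <- rnorm(300)
  expect_equal(roc_auc(-s, rep(c(0, 1), 150))$auc,
               1 - roc_auc(s, rep(c(0, 1), 150))$auc, tolerance = 1e-12)
  # all-tied scores give chance area
  expect_equal(roc_auc(rep(1, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC on label-independent scores is near one half", {
  set.seed(77)
  scores <- rnorm(2000)
  labels <- sample(c(0, 1), 2000, replace = TRUE)
  auc <- roc_auc(scores, labels)$auc
  expect_gt(auc, 0.45)
  expect_lt(auc, 0.55)
})

test_that("the ROC sweep agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  scores <- rnorm(500)
  labels <- as.integer(scores + rnorm(500) > 0)
  ours <- roc_auc(scores, labels)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("paired t-test matches hand arithmetic and flags degeneracy", {
  # five paired measurements, worked by hand:
  # d = a - b = (0.02, 0.05, -0.01, 0.03, 0.01); mean 0.02; sd 0.02236068
  # t = 0.02 / (0.02236068 / sqrt(5)) = 2.0; df 4; p = 0.1161165
  a <- c(0.95, 0.97, 0.91, 0.96, 0.93)
  b <- c(0.93, 0.92, 0.92, 0.93, 0.92)
  res <- paired_ttest(a, b)
  expect_equal(res$t, 2, tolerance = 1e-9)
  expect_identical(res$df, 4)
  expect_equal(res$p_value, 2 * stats::pt(-2, df = 4), tolerance = 1e-9)
  same <- paired_ttest(a, a)
  expect_true(same$degenerate)
  expect_equal(same$mean_diff, 0)
  shifted <- paired_ttest(a, a + 0.1)
  expect_true(shifted$degenerate)   # constant shift, zero-variance differences
  expect_error(paired_ttest(1:3, 1:4), "equal-length")
})

test_that("repeated k-fold evaluation fills a coherent report", {
  ws <- small_windowset(classes = 2L, duration_s = 13.86, seed = 27)
  arms <- c(list(raw = ws), decompose_windowset(ws, bands = "beta"))
  arch <- small_arch(2L, pool_mode = "stochastic")
  rep_ <- run_cv(arch, arms, train_config(max_epochs = 30, batch_size = 32,
                                          seed = 10),
                 k = 5, repeats = 2)
  expect_s3_class(rep_, "eval_report")
  expect_identical(nrow(rep_$folds), 2L * 5L * 2L)   # arms x folds x repeats
  expect_identical(nrow(rep_$summary), 4L)           # arms x repeats
  expect_true(all(rep_$summary$best >= rep_$summary$mean))
  expect_true(all(rep_$summary$mean >= rep_$summary$worst))
  expect_true(all(rep_$folds$accuracy >= 0 & rep_$folds$accuracy <= 1))
  expect_true(all(rep_$summary$auc >= 0 & rep_$summary$auc <= 1))
  # strongly separable data classify well in the with-decomposition arm
  beta_mean <- rep_$summary$mean[rep_$summary$arm == "beta"]
  expect_gte(mean(beta_mean), 0.95)
  # tidy/glance accessors
  expect_identical(generics::tidy(rep_), rep_$folds)
  gl <- generics::glance(rep_)
  expect_identical(sort(gl$arm), c("beta", "raw"))
  # report files
  dir <- withr::local_tempdir()
  write_eval_report(rep_, dir)
  expect_true(all(file.exists(file.path(dir, c("summary.tsv", "folds.tsv",
                                               "roc_points.csv", "report.json")))))
  expect_s3_class(ggplot2::autoplot(rep_$roc[[1]]), "ggplot")
})
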