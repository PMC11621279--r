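test_that("balanced accuracy averages per-class recalls", {
  # the printed participant-4 confusion matrix: 19/3 over 11/5
  y_true <- c(rep(0, 22), rep(1, 16))
  y_pred <- c(rep(0, 19), rep(1, 3), rep(0, 11), rep(1, 5))
  expect_equal(balanced_accuracy(y_true, y_pred), (19 / 22 + 5 / 16) / 2)
  expect_equal(round(balanced_accuracy(y_true, y_pred), 3), 0.588)

  expect_equal(balanced_accuracy(c(0, 1, 1), c(0, 1, 1)), 1)
  expect_equal(balanced_accuracy(c(rep(0, 90), rep(1, 10)), rep(0, 100)), 0.5)
  expect_error(balanced_accuracy(integer(0), integer(0)), "empty")
})

test_that("confusion-matrix accuracy reproduces printed percentages", {
  expect_equal(accuracy_from_confusion(matrix(c(19, 11, 3, 5), 2)), 63.2)
  expect_equal(accuracy_from_confusion(matrix(c(22, 16, 0, 0), 2)), 57.9)
  expect_equal(accuracy_from_confusion(diag(2)), 100)
  expect_error(accuracy_from_confusion(matrix(0, 2, 2)), "empty")
})

test_that("stratified folds keep class ratios within one sample and are reproducible", {
  y <- c(rep(0, 73), rep(1, 27))
  cv <- cv_config(folds = 10, repeats = 3, seed = 4)
  folds <- stratified_folds(y, cv)
  expect_length(folds, 3)
  for (f in folds) {
    for (cl in c(0, 1)) {
      per_fold <- table(factor(f[y == cl], levels = 1:10))
      expect_lte(diff(range(per_fold)), 1)
    }
  }
  expect_identical(folds, stratified_folds(y, cv))
  expect_error(stratified_folds(c(rep(0, 50), rep(1, 5)), cv_config(10, 1, 1)),
               "fewer than")
})

test_that("SMOTE balances classes with convex minority interpolations", {
  set.seed(8)
  X <- matrix(rnorm(60), ncol = 2)
  y <- c(rep("0", 22), rep("1", 8))
  out <- smote_resample(X, y, k = 5)
  expect_identical(unname(table(out$y)["1"]), unname(table(out$y)["0"]))
  synth <- out$X[-(1:30), , drop = FALSE]
  rng <- apply(X[y == "1", ], 2, range)
  expect_true(all(synth[, 1] >= rng[1, 1] & synth[, 1] <= rng[2, 1]))
  expect_true(all(synth[, 2] >= rng[1, 2] & synth[, 2] <= rng[2, 2]))

  single <- smote_resample(X, c(rep("0", 29), "1"), k = 5)
  expect_identical(sum(single$y == "1"), 29L)
  expect_true(all(single$X[single$y == "1", 1] == X[30, 1]))
})

test_that("every classifier learns a shifted-mean signal under every setting", {
  fs <- shifted_features()
  cv <- cv_config(folds = 5, repeats = 1, seed = 9)
  for (clf in six_classifiers()) {
    for (setting in four_settings()) {
      r <- run_setting(fs, setting, clf, cv)
      expect_length(r$test_acc, 5)
      expect_gt(r$mean_bal, 0.65)
      expect_gte(r$mean_train, r$mean_test - 0.05)
    }
  }
})

test_that("cross-validation is reproducible under a fixed seed", {
  fs <- shifted_features()
  cv <- cv_config(folds = 5, repeats = 2, seed = 10)
  r1 <- run_setting(fs, setting_spec("smote", "pca"), classifier_spec("svm_rbf"), cv)
  r2 <- run_setting(fs, setting_spec("smote", "pca"), classifier_spec("svm_rbf"), cv)
  expect_identical(r1$test_acc, r2$test_acc)
  expect_identical(r1$bal_acc, r2$bal_acc)
})

test_that("gradient boosting is invariant to duplicated feature columns", {
  fs <- shifted_features()
  fs_dup <- fs
  fs_dup$X <- cbind(fs$X, fs$X)
  cv <- cv_config(folds = 5, repeats = 1, seed = 11)
  r1 <- run_setting(fs, setting_spec("bcw"), classifier_spec("gradient_boosting"), cv)
  r2 <- run_setting(fs_dup, setting_spec("bcw"), classifier_spec("gradient_boosting"), cv)
  expect_equal(r1$test_acc, r2$test_acc)
})

test_that("label-independent features score at chance balanced accuracy", {
  set.seed(20)
  n <- 90
  fs <- structure(list(X = matrix(rnorm(n * 10), n),
                       labels = rbinom(n, 1, 0.3), modality = "org"),
                  class = "feature_set")
  cv <- cv_config(folds = 10, repeats = 5, seed = 21)
  r <- run_setting(fs, setting_spec("bcw"), classifier_spec("logistic_regression"), cv)
  expect_lt(abs(r$mean_bal - 0.5), 3 * corrected_se(r$bal_acc, folds = 10))
})

test_that("the grid covers every combination and flags the best setting per block", {
  dt <- small_day_tbl()
  fs_list <- list(org = build_features(dt, "org"), fft = build_features(dt, "fft"))
  cv <- cv_config(folds = 3, repeats = 2, seed = 12)
  cls <- six_classifiers()[c("logistic_regression", "svm_linear")]
  sets <- four_settings()[c("bcw", "smote")]
  # the deliberately tiny fixture triggers glmnet's small-class caution
  grid <- suppressWarnings(run_grid(fs_list, cv, settings = sets, classifiers = cls))
  expect_identical(nrow(grid), 2L * 2L * 2L)
  expect_true(all(vapply(grid$result, function(r) length(r$test_acc), integer(1)) == 6L))
  expect_identical(sum(grid$best_in_block), 4L)  # one flag per (modality, classifier)
  gs <- grid_summary(grid)
  expect_identical(nrow(gs), 4L)
})

test_that("best_configuration maximizes test accuracy with balanced-accuracy tie-break", {
  mock_row <- function(modality, clf, setting, test, bal) {
    tibble::tibble(modality = modality, classifier = clf, setting = setting,
                   mean_test = test, mean_bal = bal,
                   result = list(list(test_acc = rep(test, 4))))
  }
  grid <- dplyr::bind_rows(
    mock_row("org", "a", "BCW", 0.70, 0.60),
    mock_row("org", "b", "BCW", 0.80, 0.61),
    mock_row("org", "c", "BCW", 0.80, 0.70),
    mock_row("fft", "a", "BCW", 0.65, 0.55)
  )
  best <- best_configuration(grid, "org")
  expect_identical(best$classifier, "c")   # tie on test, higher balanced wins
  expect_identical(best_configuration(grid, "fft")$classifier, "a")
  expect_error(best_configuration(grid, "wave50"), "no configurations")
})

test_that("transfer evaluation reproduces the printed all-negative-predictor arithmetic", {
  set.seed(30)
  # training participant: clearly separated classes
  Xtr <- rbind(matrix(rnorm(40 * 4, 0), 40), matrix(rnorm(20 * 4, 4), 20))
  train_fs <- structure(list(X = Xtr, labels = c(rep(0, 40), rep(1, 20)),
                             modality = "org"), class = "feature_set")
  clf <- classifier_spec("svm_linear")
  setting <- setting_spec("bcw")

  # 9 all-negative days in the negative region: accuracy 100
  test9 <- structure(list(X = matrix(rnorm(9 * 4, 0), 9), labels = rep(0, 9),
                          modality = "org"), class = "feature_set")
  r9 <- transfer_evaluate(train_fs, test9, setting, clf)
  expect_equal(r9$test_accuracy, 100)

  # 22 negative / 16 positive days, all presenting as negative:
  # confusion [[22, 0], [16, 0]] and accuracy 57.9
  test38 <- structure(list(X = matrix(rnorm(38 * 4, 0), 38),
                           labels = c(rep(0, 22), rep(1, 16)),
                           modality = "org"), class = "feature_set")
  r38 <- transfer_evaluate(train_fs, test38, setting, clf)
  expect_equal(unname(r38$confusion), matrix(c(22L, 16L, 0L, 0L), 2))
  expect_equal(r38$test_accuracy, 57.9)

  # train = test smoke case
  rt <- transfer_evaluate(train_fs, train_fs, setting, clf)
  expect_equal(rt$train_accuracy, rt$test_accuracy)

  bad <- structure(list(X = matrix(0, 3, 7), labels = rep(0, 3), modality = "org"),
                   class = "feature_set")
  expect_error(transfer_evaluate(train_fs, bad, setting, clf), "width mismatch")
})
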