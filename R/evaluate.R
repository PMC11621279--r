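#' Imbalance / dimensionality setting
#'
#' Encodes the four experimental settings: balanced class weights (BCW) or
#' SMOTE for class imbalance, each with or without PCA dimensionality
#' reduction. With SMOTE + PCA, SMOTE is applied first and PCA fitted on
#' the resampled training data. Both resampler and reducer are fitted
#' strictly inside each training fold.
#'
#' @param imbalance `"bcw"` (balanced class weights) or `"smote"`.
#' @param reduce `"none"` or `"pca"`.
#' @param pca_variance_target Cumulative explained-variance fraction the
#'   retained components must reach (default 0.95).
#' @param smote_neighbors Number of minority-class nearest neighbours
#'   SMOTE interpolates between (default 5).
#' @return A `setting_spec` object.
#' @export
setting_spec <- function(imbalance = c("bcw", "smote"), reduce = c("none", "pca"),
                         pca_variance_target = 0.95, smote_neighbors = 5) {
  imbalance <- match.arg(imbalance)
  reduce <- match.arg(reduce)
  structure(list(imbalance = imbalance, reduce = reduce,
                 pca_variance_target = pca_variance_target,
                 smote_neighbors = smote_neighbors,
                 name = paste0(toupper(imbalance),
                               if (reduce == "pca") "+PCA" else "")),
            class = "setting_spec")
}

#' The four standard settings
#'
#' @return Named list of the four [setting_spec()] combinations: BCW,
#'   BCW+PCA, SMOTE, SMOTE+PCA.
#' @export
four_settings <- function() {
  list(
    bcw = setting_spec("bcw", "none"),
    bcw_pca = setting_spec("bcw", "pca"),
    smote = setting_spec("smote", "none"),
    smote_pca = setting_spec("smote", "pca")
  )
}

#' Classifier specification
#'
#' Families: ridge logistic regression, SVMs with linear / degree-3
#' polynomial / RBF kernels, random forest (100 trees), gradient boosting
#' (100 depth-3 trees, learning rate 0.1). Features are standardized with
#' training-fold mean/sd before logistic regression, SVMs and PCA;
#' tree ensembles see the unscaled features unless PCA is in play. The
#' polynomial kernel is inhomogeneous (`coef0 = 1`): with the
#' inverse-width default `gamma = 1/p` on standardized features, the
#' homogeneous cubic kernel is vanishingly small off-diagonal and the
#' machine degenerates toward memorization, whereas `coef0 = 1` retains
#' the linear and quadratic terms.
#'
#' @param family One of `"logistic_regression"`, `"svm_linear"`,
#'   `"svm_poly"`, `"svm_rbf"`, `"random_forest"`,
#'   `"gradient_boosting"`.
#' @param ... Hyperparameter overrides (`cost`, `degree`, `n_trees`,
#'   `eta`, `max_depth`, `lambda`).
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(family = c("logistic_regression", "svm_linear", "svm_poly",
                                       "svm_rbf", "random_forest", "gradient_boosting"),
                            ...) {
  family <- match.arg(family)
  hp <- utils::modifyList(
    list(cost = 1, degree = 3, coef0 = 1, n_trees = 100, eta = 0.1,
         max_depth = 3, lambda = NULL),
    list(...)
  )
  structure(list(family = family, hp = hp), class = "classifier_spec")
}

#' The six standard classifiers
#'
#' @return Named list of [classifier_spec()]s for all six families.
#' @export
six_classifiers <- function() {
  fams <- c("logistic_regression", "svm_linear", "svm_poly", "svm_rbf",
            "random_forest", "gradient_boosting")
  stats::setNames(lapply(fams, classifier_spec), fams)
}

#' Cross-validation configuration
#'
#' @param folds Number of folds (default 10).
#' @param repeats Number of random repetitions (default 10), giving
#'   `folds * repeats` held-out evaluations per configuration.
#' @param seed Seed for the fold assignment and any stochastic fitting.
#' @return A `cv_config` object.
#' @export
cv_config <- function(folds = 10, repeats = 10, seed = 1L) {
  stopifnot(folds >= 2, repeats >= 1)
  structure(list(folds = folds, repeats = repeats, seed = as.integer(seed)),
            class = "cv_config")
}

#' Balanced accuracy
#'
#' The mean of per-class recalls over the classes present in `y_true`;
#' insensitive to class imbalance (an always-majority predictor scores
#' 0.5 on two-class data).
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @return Fraction in \[0, 1\].
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("empty input", call. = FALSE)
  stopifnot(length(y_true) == length(y_pred))
  classes <- unique(y_true)
  recalls <- vapply(classes, function(cl) {
    mean(y_pred[y_true == cl] == cl)
  }, numeric(1))
  mean(recalls)
}

#' Accuracy (percent) from a 2x2 confusion matrix
#'
#' The matrix is oriented `[[TN, FP], [FN, TP]]` with the non-stressful
#' class first (rows = truth, columns = prediction).
#'
#' @param cm 2x2 numeric matrix of counts.
#' @return Percentage, rounded to one decimal.
#' @export
accuracy_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  round(100 * sum(diag(cm)) / total, 1)
}

#' Stratified repeated k-fold assignments
#'
#' Within every class, indices are shuffled and dealt into folds whose
#' per-class sizes differ by at most one, so each fold's class ratio stays
#' within one sample of the global ratio.
#'
#' @param y Label vector.
#' @param cv A [cv_config()]; `cv$seed` fixes the assignments.
#' @return List of `repeats` integer vectors of fold ids (1..folds).
#' @export
stratified_folds <- function(y, cv) {
  counts <- table(y)
  if (any(counts < cv$folds)) {
    stop("class `", names(counts)[which.min(counts)], "` has ", min(counts),
         " members, fewer than ", cv$folds, " folds", call. = FALSE)
  }
  set.seed(cv$seed)
  lapply(seq_len(cv$repeats), function(r) {
    fold <- integer(length(y))
    for (cl in names(counts)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(cv$folds), length(idx)))
    }
    fold
  })
}

#' SMOTE oversampling of the minority class
#'
#' Adds interpolated minority samples until both classes have equal
#' counts: each synthetic sample sits uniformly at random on the segment
#' between a random minority sample and one of its `k` nearest minority
#' neighbours (Euclidean distance). `k` shrinks automatically when the
#' minority class has fewer than `k + 1` members.
#'
#' @param X Numeric feature matrix.
#' @param y Binary label vector.
#' @param k Neighbour count (default 5).
#' @return List with the augmented `X` and `y`.
#' @export
smote_resample <- function(X, y, k = 5) {
  counts <- table(y)
  if (length(counts) < 2 || min(counts) == max(counts)) return(list(X = X, y = y))
  min_cl <- names(counts)[which.min(counts)]
  n_new <- max(counts) - min(counts)
  Xmin <- X[y == min_cl, , drop = FALSE]
  n_min <- nrow(Xmin)
  if (n_min == 1) {
    synth <- Xmin[rep(1, n_new), , drop = FALSE]
  } else {
    k_eff <- min(k, n_min - 1)
    d <- as.matrix(stats::dist(Xmin))
    nn <- apply(d, 1, function(row) order(row)[2:(k_eff + 1)])
    nn <- matrix(nn, ncol = n_min)  # k_eff x n_min
    base <- sample.int(n_min, n_new, replace = TRUE)
    pick <- nn[cbind(sample.int(k_eff, n_new, replace = TRUE), base)]
    gap <- stats::runif(n_new)
    synth <- Xmin[base, , drop = FALSE] +
      gap * (Xmin[pick, , drop = FALSE] - Xmin[base, , drop = FALSE])
  }
  list(X = rbind(X, synth),
       y = c(y, rep(min_cl, n_new)))
}

fit_scaler <- function(X) {
  center <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  sds[!is.finite(sds) | sds == 0] <- 1
  list(center = center, scale = sds)
}

apply_scaler <- function(scaler, X) {
  sweep(sweep(X, 2, scaler$center), 2, scaler$scale, "/")
}

fit_pca_reducer <- function(X, variance_target) {
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  cum <- cumsum(pr$sdev^2) / sum(pr$sdev^2)
  ncomp <- max(1L, which(cum >= variance_target)[1])
  list(center = pr$center, rotation = pr$rotation[, seq_len(ncomp), drop = FALSE],
       ncomp = ncomp)
}

apply_pca_reducer <- function(red, X) {
  sweep(X, 2, red$center) %*% red$rotation
}

needs_scaling <- function(clf, setting) {
  clf$family %in% c("logistic_regression", "svm_linear", "svm_poly", "svm_rbf") ||
    setting$reduce == "pca"
}

fit_classifier <- function(clf, X, y, balanced) {
  yf <- factor(y, levels = c("0", "1"))
  n <- length(y)
  cw <- NULL
  w <- rep(1, n)
  if (balanced) {
    tab <- table(yf)
    cw <- n / (length(tab) * as.numeric(tab))
    names(cw) <- names(tab)
    w <- cw[as.character(yf)]
  }
  hp <- clf$hp
  model <- switch(
    clf$family,
    logistic_regression = {
      lambda <- if (is.null(hp$lambda)) 1 / n else hp$lambda
      glmnet::glmnet(X, yf, family = "binomial", alpha = 0, lambda = lambda,
                     weights = as.numeric(w), standardize = FALSE)
    },
    svm_linear = e1071::svm(X, yf, kernel = "linear", cost = hp$cost,
                            class.weights = cw, scale = FALSE),
    svm_poly = e1071::svm(X, yf, kernel = "polynomial", degree = hp$degree,
                          coef0 = hp$coef0, cost = hp$cost, class.weights = cw,
                          scale = FALSE),
    svm_rbf = e1071::svm(X, yf, kernel = "radial", cost = hp$cost,
                         class.weights = cw, scale = FALSE),
    random_forest = {
      colnames(X) <- paste0("f", seq_len(ncol(X)))
      ranger::ranger(x = X, y = yf, num.trees = hp$n_trees,
                     case.weights = as.numeric(w), num.threads = 1)
    },
    gradient_boosting = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = hp$max_depth,
                    eta = hp$eta, nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = as.integer(y == "1"),
                                  weight = as.numeric(w)),
      nrounds = hp$n_trees, verbose = 0
    )
  )
  list(family = clf$family, model = model)
}

predict_classifier <- function(fit, X) {
  out <- switch(
    fit$family,
    logistic_regression = as.character(stats::predict(fit$model, X, type = "class")),
    svm_linear = ,
    svm_poly = ,
    svm_rbf = as.character(stats::predict(fit$model, X)),
    random_forest = {
      colnames(X) <- paste0("f", seq_len(ncol(X)))
      as.character(stats::predict(fit$model, data = X)$predictions)
    },
    gradient_boosting = ifelse(
      stats::predict(fit$model, xgboost::xgb.DMatrix(X)) > 0.5, "1", "0")
  )
  out
}

# Fit one fold's full pipeline (scaler -> SMOTE -> PCA -> classifier) on
# the training rows only. Returns the fitted parts, a predict closure and
# a hash of the fitted preprocessing state (used by the leakage audit).
fit_fold <- function(X, y, train_idx, setting, clf) {
  y <- as.character(y)
  Xtr <- X[train_idx, , drop = FALSE]
  ytr <- y[train_idx]
  scaler <- NULL
  if (needs_scaling(clf, setting)) {
    scaler <- fit_scaler(Xtr)
    Xtr <- apply_scaler(scaler, Xtr)
  }
  if (setting$imbalance == "smote") {
    sm <- smote_resample(Xtr, ytr, k = setting$smote_neighbors)
    Xtr <- sm$X
    ytr <- sm$y
  }
  reducer <- NULL
  if (setting$reduce == "pca") {
    reducer <- fit_pca_reducer(Xtr, setting$pca_variance_target)
    Xtr <- apply_pca_reducer(reducer, Xtr)
  }
  fit <- fit_classifier(clf, Xtr, ytr, balanced = setting$imbalance == "bcw")
  transform <- function(newX) {
    if (!is.null(scaler)) newX <- apply_scaler(scaler, newX)
    if (!is.null(reducer)) newX <- apply_pca_reducer(reducer, newX)
    newX
  }
  list(
    predict = function(newX) predict_classifier(fit, transform(newX)),
    train_X = Xtr, train_y = ytr,
    state_hash = rlang::hash(list(scaler, Xtr, ytr,
                                  if (!is.null(reducer)) reducer$rotation))
  )
}

#' Evaluate one classifier under one setting with repeated stratified CV
#'
#' For each of `folds * repeats` splits, the scaler, SMOTE resampler, PCA
#' reducer and classifier are fitted on the training part only; training
#' accuracy is measured on that training part and (balanced) accuracy on
#' the held-out part.
#'
#' @param fs A `feature_set` from [build_features()].
#' @param setting A [setting_spec()].
#' @param clf A [classifier_spec()].
#' @param cv A [cv_config()].
#' @return A `cv_result`: list of fold-level `train_acc`, `test_acc`,
#'   `bal_acc` vectors (length `folds * repeats`), their means/sds, and the
#'   configuration identifiers.
#' @export
run_setting <- function(fs, setting, clf, cv = cv_config()) {
  X <- fs$X
  y <- as.character(fs$labels)
  assignments <- stratified_folds(y, cv)
  n_eval <- cv$folds * cv$repeats
  train_acc <- test_acc <- bal_acc <- numeric(n_eval)
  i <- 0L
  for (fold_of in assignments) {
    for (f in seq_len(cv$folds)) {
      i <- i + 1L
      test_idx <- which(fold_of == f)
      train_idx <- which(fold_of != f)
      fit <- fit_fold(X, y, train_idx, setting, clf)
      pred_tr <- fit$predict(X[train_idx, , drop = FALSE])
      pred_te <- fit$predict(X[test_idx, , drop = FALSE])
      train_acc[i] <- mean(pred_tr == y[train_idx])
      test_acc[i] <- mean(pred_te == y[test_idx])
      bal_acc[i] <- balanced_accuracy(y[test_idx], pred_te)
    }
  }
  structure(
    list(modality = fs$modality, setting = setting$name, classifier = clf$family,
         train_acc = train_acc, test_acc = test_acc, bal_acc = bal_acc,
         mean_train = mean(train_acc), mean_test = mean(test_acc),
         sd_test = stats::sd(test_acc), mean_bal = mean(bal_acc),
         sd_bal = stats::sd(bal_acc)),
    class = "cv_result"
  )
}

#' @exportS3Method base::print
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s | %s | %s: train %.1f%%, test %.1f +/- %.1f%%, balanced %.1f +/- %.1f%%\n",
              x$modality, x$setting, x$classifier, 100 * x$mean_train,
              100 * x$mean_test, 100 * x$sd_test, 100 * x$mean_bal, 100 * x$sd_bal))
  invisible(x)
}

#' Run the full modality x setting x classifier grid
#'
#' Evaluates every combination of the supplied feature sets, settings and
#' classifiers under a common CV configuration (the default grid is
#' 5 x 4 x 6 = 120 configurations, each with `folds * repeats` fold
#' accuracies). Per (modality, classifier), the setting with the highest
#' mean test accuracy is flagged, mirroring the bold marks of a results
#' table.
#'
#' @param fs_list Named list of `feature_set`s (one per modality), all
#'   built on the same day index.
#' @param cv A [cv_config()].
#' @param settings List of [setting_spec()]s (default [four_settings()]).
#' @param classifiers List of [classifier_spec()]s (default
#'   [six_classifiers()]).
#' @return Tibble with one row per configuration: identifiers, summary
#'   accuracies, `best_in_block` flag, and a `result` list-column of
#'   `cv_result`s.
#' @export
run_grid <- function(fs_list, cv = cv_config(), settings = four_settings(),
                     classifiers = six_classifiers()) {
  lab0 <- fs_list[[1]]$labels
  for (fs in fs_list) {
    if (!identical(fs$labels, lab0)) {
      stop("all feature sets must be built on the same day index", call. = FALSE)
    }
  }
  rows <- list()
  i <- 0L
  for (fs in fs_list) {
    for (clf in classifiers) {
      for (setting in settings) {
        i <- i + 1L
        res <- run_setting(fs, setting, clf, cv)
        rows[[i]] <- tibble::tibble(
          modality = fs$modality, classifier = clf$family, setting = setting$name,
          mean_train = res$mean_train, mean_test = res$mean_test,
          sd_test = res$sd_test, mean_bal = res$mean_bal, sd_bal = res$sd_bal,
          result = list(res)
        )
      }
    }
  }
  grid <- dplyr::bind_rows(rows)
  grid |>
    dplyr::group_by(.data$modality, .data$classifier) |>
    dplyr::mutate(best_in_block = seq_along(.data$mean_test) ==
                    order(-.data$mean_test, -.data$mean_bal)[1]) |>
    dplyr::ungroup()
}

#' Summarize a grid as a modality-by-setting table of averages
#'
#' @param grid Output of [run_grid()].
#' @return Tibble of mean train/test/balanced accuracies per
#'   (modality, setting), averaged over classifiers.
#' @export
grid_summary <- function(grid) {
  grid |>
    dplyr::group_by(.data$modality, .data$setting) |>
    dplyr::summarise(mean_train = mean(.data$mean_train),
                     mean_test = mean(.data$mean_test),
                     mean_bal = mean(.data$mean_bal), .groups = "drop")
}

#' Best configuration within one modality
#'
#' The configuration with the highest mean test accuracy; ties broken by
#' higher mean balanced accuracy, then by grid order.
#'
#' @param grid Output of [run_grid()].
#' @param modality Modality name to search within.
#' @return The winning grid row (with its `cv_result` in `result`).
#' @export
best_configuration <- function(grid, modality) {
  sub <- grid[grid$modality == modality, , drop = FALSE]
  if (nrow(sub) == 0) stop("no configurations for modality ", modality, call. = FALSE)
  ord <- order(-sub$mean_test, -sub$mean_bal)
  sub[ord[1], , drop = FALSE]
}

#' Cross-participant transfer evaluation
#'
#' Fits the chosen setting + classifier once on all training days (one
#' participant) and evaluates on another participant's days, reporting the
#' confusion matrix with the non-stressful class first.
#'
#' @param train_fs,test_fs `feature_set`s of identical modality and width
#'   from disjoint participants.
#' @param setting A [setting_spec()].
#' @param clf A [classifier_spec()].
#' @return List with `train_accuracy` and `test_accuracy` (percent, one
#'   decimal) and `confusion` (`[[TN, FP], [FN, TP]]`).
#' @export
transfer_evaluate <- function(train_fs, test_fs, setting, clf) {
  if (ncol(train_fs$X) != ncol(test_fs$X)) {
    stop("feature width mismatch: ", ncol(train_fs$X), " vs ", ncol(test_fs$X),
         call. = FALSE)
  }
  y_tr <- as.character(train_fs$labels)
  fit <- fit_fold(train_fs$X, y_tr, seq_len(nrow(train_fs$X)), setting, clf)
  pred_tr <- fit$predict(train_fs$X)
  pred_te <- fit$predict(test_fs$X)
  y_te <- as.character(test_fs$labels)
  cm <- matrix(0L, 2, 2, dimnames = list(truth = c("0", "1"), pred = c("0", "1")))
  for (cl_t in c("0", "1")) for (cl_p in c("0", "1")) {
    cm[cl_t, cl_p] <- sum(y_te == cl_t & pred_te == cl_p)
  }
  list(
    train_accuracy = round(100 * mean(pred_tr == y_tr), 1),
    test_accuracy = accuracy_from_confusion(cm),
    confusion = cm
  )
}
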