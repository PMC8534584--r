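# Classifier configurations, grid-search tuning, and the performance
# metrics (sensitivity, specificity, balanced accuracy, confusion matrix).

#' RBF-SVM configuration
#'
#' Radial-basis-function support vector machine with per-feature linear
#' scaling to \[-1, 1\] fit on training data only. The penalty grid runs
#' 2^-5..2^15 and the kernel-bandwidth grid 2^-15..2^3, both in steps of
#' 2^2.
#'
#' @param C_grid Penalty-parameter grid.
#' @param w_grid Kernel-bandwidth (gamma) grid.
#' @return An object of class `classifier_config`.
#' @export
svm_config <- function(C_grid = 2^seq(-5, 15, by = 2),
                       w_grid = 2^seq(-15, 3, by = 2)) {
  stopifnot(length(C_grid) > 0, length(w_grid) > 0)
  structure(list(type = "svm", C_grid = C_grid, w_grid = w_grid),
            class = "classifier_config")
}

#' Random-forest configuration
#'
#' Forests with 500 and 1000 trees and the per-node feature sample set to
#' half, one, and two times the classification default `sqrt(p)`.
#'
#' @param n_trees Tree-count grid.
#' @param mtry_multiplier Multipliers of the default `sqrt(p)`.
#' @return An object of class `classifier_config`.
#' @export
forest_config <- function(n_trees = c(500, 1000),
                          mtry_multiplier = c(0.5, 1, 2)) {
  stopifnot(all(n_trees > 0))
  structure(list(type = "rf", n_trees = n_trees,
                 mtry_multiplier = mtry_multiplier),
            class = "classifier_config")
}

#' AdaBoost configuration
#'
#' Discrete AdaBoost over shallow (depth-2) decision trees with 1000 weak
#' learners; the learning rate is searched over 0.01-0.5.
#'
#' @param learning_rate_grid Learning-rate (shrinkage) grid in (0, 1\].
#' @param n_estimators Number of weak learners.
#' @param max_depth Depth of the weak trees.
#' @return An object of class `classifier_config`.
#' @export
boost_config <- function(learning_rate_grid = c(0.01, 0.03, 0.05, 0.1, 0.3, 0.5),
                         n_estimators = 1000, max_depth = 2) {
  stopifnot(all(learning_rate_grid > 0), all(learning_rate_grid <= 1))
  structure(list(type = "adaboost", learning_rate_grid = learning_rate_grid,
                 n_estimators = n_estimators, max_depth = max_depth),
            class = "classifier_config")
}

# [-1, 1] per-feature scaling fit on the training data only.
fit_scaling <- function(X) {
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  rng <- hi - lo
  rng[rng < 1e-12] <- 1
  list(lo = lo, rng = rng)
}

apply_scaling <- function(X, sc) {
  stopifnot(!is.null(sc$lo), !is.null(sc$rng))
  sweep(sweep(X, 2, sc$lo), 2, sc$rng, "/") * 2 - 1
}

# Grid rows ordered so the first best row realizes the documented
# tie-break (smaller C, then larger w; fewer trees; smaller rate).
config_grid <- function(config) {
  switch(config$type,
    svm = {
      g <- expand.grid(C = config$C_grid, w = config$w_grid)
      g[base::order(g$C, -g$w), , drop = FALSE]
    },
    rf = {
      g <- expand.grid(ntree = config$n_trees,
                       mult = config$mtry_multiplier)
      g[base::order(g$ntree, g$mult), , drop = FALSE]
    },
    adaboost = data.frame(rate = sort(config$learning_rate_grid))
  )
}

fit_one <- function(config, row, X, y, seed) {
  y_f <- factor(y, levels = c(0, 1))
  switch(config$type,
    svm = e1071::svm(X, y_f, kernel = "radial", cost = row$C,
                     gamma = row$w, scale = FALSE),
    rf = with_local_seed(seed, {
      mtry <- max(1, min(ncol(X), round(row$mult * sqrt(ncol(X)))))
      randomForest::randomForest(X, y_f, ntree = row$ntree, mtry = mtry)
    }),
    adaboost = with_local_seed(seed,
      adaboost_fit(X, y, n_estimators = config$n_estimators,
                   learning_rate = row$rate, max_depth = config$max_depth))
  )
}

predict_fit <- function(config, fit, X) {
  pred <- switch(config$type,
    svm = stats::predict(fit, X),
    rf = stats::predict(fit, X),
    adaboost = adaboost_predict(fit, X))
  as.integer(as.character(pred))
}

# Discrete AdaBoost (SAMME for two classes) over rpart stumps with
# shrinkage; labels in {0, 1}.
adaboost_fit <- function(X, y, n_estimators, learning_rate, max_depth) {
  n <- nrow(X)
  yy <- ifelse(y == 1, 1, -1)
  w <- rep(1 / n, n)
  df <- data.frame(.y = factor(yy), X)
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0, xval = 0,
                               minsplit = 5, minbucket = 2)
  fm <- stats::as.formula(".y ~ .", env = environment())
  learners <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    tr <- rpart::rpart(fm, data = df, weights = w,
                       method = "class", control = ctrl)
    h <- ifelse(stats::predict(tr, df, type = "class") == "1", 1, -1)
    err <- sum(w * (h != yy))
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- learning_rate * 0.5 * log((1 - err) / err)
    learners[[length(learners) + 1]] <- tr
    alphas <- c(alphas, alpha)
    w <- w * exp(-alpha * yy * h)
    w <- w / sum(w)
    if (err < 1e-9) break
  }
  list(learners = learners, alphas = alphas,
       feature_names = colnames(X))
}

adaboost_predict <- function(fit, X) {
  df <- data.frame(X)
  score <- numeric(nrow(X))
  for (m in seq_along(fit$learners)) {
    h <- ifelse(stats::predict(fit$learners[[m]], df, type = "class") == "1",
                1, -1)
    score <- score + fit$alphas[m] * h
  }
  factor(ifelse(score >= 0, 1, 0), levels = c(0, 1))
}

#' Tune hyper-parameters by inner cross-validation and train a final model
#'
#' Exhaustively evaluates the configuration's grid with stratified
#' `inner_cv_folds`-fold cross-validation on the training data only,
#' selecting the hyper-parameters with the highest mean balanced accuracy
#' (ties: smaller penalty, then larger bandwidth / fewer trees / smaller
#' rate). The final model is refit on all training data; the \[-1, 1\]
#' scaling parameters (fit on training data) are stored with the model and
#' applied at prediction time.
#'
#' @param X_train Training feature matrix with column names.
#' @param y_train Labels in `{0, 1}` (both classes present).
#' @param config A `classifier_config`.
#' @param inner_cv_folds Inner folds (default 5); skipped when the grid has
#'   one row.
#' @param seed Seed controlling fold assignment and stochastic learners.
#' @return An object of class `trained_model`.
#' @export
tune_and_train <- function(X_train, y_train, config = svm_config(),
                           inner_cv_folds = 5, seed = 1L) {
  X_train <- as.matrix(X_train)
  y_train <- as.integer(y_train)
  if (length(unique(y_train)) < 2) stop("single-class training data")
  if (is.null(colnames(X_train)))
    colnames(X_train) <- sprintf("x%03d", seq_len(ncol(X_train)))
  sc <- fit_scaling(X_train)
  Z <- apply_scaling(X_train, sc)
  grid <- config_grid(config)

  if (nrow(grid) > 1) {
    folds <- with_local_seed(seed, stratified_folds(y_train, inner_cv_folds))
    ba <- vapply(seq_len(nrow(grid)), function(gi) {
      bas <- vapply(seq_len(inner_cv_folds), function(fi) {
        tr <- folds != fi
        if (length(unique(y_train[tr])) < 2) return(NA_real_)
        fit <- fit_one(config, grid[gi, , drop = FALSE],
                       Z[tr, , drop = FALSE], y_train[tr], seed)
        pr <- predict_fit(config, fit, Z[!tr, , drop = FALSE])
        evaluate_predictions(y_train[!tr], pr)$balanced_accuracy
      }, numeric(1))
      mean(bas, na.rm = TRUE)
    }, numeric(1))
    best <- which.max(ba)            # first max = documented tie-break
  } else best <- 1L

  fit <- fit_one(config, grid[best, , drop = FALSE], Z, y_train, seed)
  structure(list(type = config$type, fit = fit, config = config,
                 hyper = as.list(grid[best, , drop = FALSE]),
                 scaling = sc, feature_names = colnames(X_train)),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s (%s) on %d features\n", x$type,
              paste(names(x$hyper), signif(unlist(x$hyper), 3),
                    sep = "=", collapse = ", "),
              length(x$feature_names)))
  invisible(x)
}

#' Predict class labels with a trained model
#'
#' Applies the stored training-data scaling; refuses to predict when the
#' feature names do not match the training manifest.
#'
#' @param object A `trained_model`.
#' @param newdata Feature matrix with the training feature names.
#' @param ... Unused.
#' @return Integer vector of labels in `{0, 1}`.
#' @export
predict.trained_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata)))
    colnames(newdata) <- sprintf("x%03d", seq_len(ncol(newdata)))
  if (!identical(colnames(newdata), object$feature_names))
    stop("feature-name manifest mismatch: refusing to predict")
  Z <- apply_scaling(newdata, object$scaling)
  predict_fit(object$config, object$fit, Z)
}

stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Confusion-matrix metrics from prediction vectors
#'
#' Sensitivity = TP / (TP + FN) with PD (label 1) positive, specificity =
#' TN / (TN + FP), balanced accuracy = their mean, all in percent; plus
#' the full confusion counts. A class absent from `y_true` leaves its rate
#' `NA` (reported as undefined).
#'
#' @param y_true,y_pred Label vectors in `{0, 1}`.
#' @return An object of class `eval_report`.
#' @export
evaluate_predictions <- function(y_true, y_pred) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  stopifnot(length(y_true) == length(y_pred))
  tp <- sum(y_true == 1 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  eval_report(sens, spec, confusion = c(TP = tp, FN = fn, FP = fp, TN = tn))
}

#' Construct an evaluation report
#'
#' Enforces the balanced-accuracy identity
#' `balanced_accuracy = (sensitivity + specificity) / 2`.
#'
#' @param sensitivity,specificity Rates in percent (may be `NA` when a
#'   class is absent).
#' @param confusion Named counts `c(TP, FN, FP, TN)` or `NULL`.
#' @param dispersion Optional SD of the balanced accuracy over CV
#'   iterations.
#' @return An object of class `eval_report`.
#' @export
eval_report <- function(sensitivity, specificity, confusion = NULL,
                        dispersion = NULL) {
  ba <- mean(c(sensitivity, specificity))
  structure(list(sensitivity = sensitivity, specificity = specificity,
                 balanced_accuracy = ba, confusion = confusion,
                 dispersion = dispersion),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> sensitivity %.2f%%, specificity %.2f%%, balanced accuracy %.2f%%\n",
              x$sensitivity, x$specificity, x$balanced_accuracy))
  if (!is.null(x$confusion)) {
    cm <- x$confusion
    cat(sprintf("  confusion: TP=%d FN=%d FP=%d TN=%d\n",
                cm["TP"], cm["FN"], cm["FP"], cm["TN"]))
  }
  invisible(x)
}

#' Evaluate a trained model on a disjoint test set
#'
#' Applies the model (with its stored training-data scaling) to the test
#' features and reports sensitivity, specificity, balanced accuracy and
#' the full confusion matrix. Test/training disjointness is the caller's
#' contract (enforced end-to-end by the split plan).
#'
#' @param model A `trained_model`.
#' @param X_test Test feature matrix.
#' @param y_test Test labels in `{0, 1}`.
#' @return An `eval_report`.
#' @export
evaluate <- function(model, X_test, y_test) {
  stopifnot(inherits(model, "trained_model"))
  evaluate_predictions(y_test, predict(model, X_test))
}
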