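# Classifier tuning, evaluation metrics, and their contracts.

sep_data <- function(n = 200, d = 5, p = 4, seed = 3) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n / 2 * p), ncol = p),
             matrix(rnorm(n / 2 * p, mean = d / 2), ncol = p))
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = rep(c(0L, 1L), each = n / 2))
}

test_that("hyper-parameter grids have the documented shape", {
  g <- pdvoice:::config_grid(svm_config())
  expect_equal(nrow(g), 11 * 10)
  expect_equal(sort(unique(g$C)), 2^seq(-5, 15, by = 2))
  expect_equal(sort(unique(g$w)), 2^seq(-15, 3, by = 2))
  expect_equal(nrow(pdvoice:::config_grid(forest_config())), 6)
  expect_equal(nrow(pdvoice:::config_grid(boost_config())), 6)
})

test_that("all three classifiers separate well-separated Gaussians", {
  d <- sep_data()
  for (cfg in list(svm_config(C_grid = 2^seq(-5, 15, 4),
                              w_grid = 2^seq(-15, 3, 4)),
                   forest_config(n_trees = 100, mtry_multiplier = 1),
                   boost_config(learning_rate_grid = c(0.1, 0.5),
                                n_estimators = 50))) {
    m <- tune_and_train(d$X, d$y, cfg, inner_cv_folds = 3, seed = 1)
    r <- evaluate(m, d$X, d$y)
    expect_gte(r$balanced_accuracy, 99)
  }
})

test_that("permuted labels give chance-level held-out accuracy", {
  set.seed(4)
  X <- matrix(rnorm(500 * 10), 500)
  colnames(X) <- paste0("f", 1:10)
  y <- sample(rep(0:1, 250))
  m <- tune_and_train(X[1:400, ], y[1:400],
                      svm_config(C_grid = 1, w_grid = 0.1), seed = 1)
  r <- evaluate(m, X[401:500, ], y[401:500])
  expect_gt(r$balanced_accuracy, 35)
  expect_lt(r$balanced_accuracy, 65)
})

test_that("duplicating the training set leaves the chosen model unchanged", {
  # with a cleanly separable problem every grid point ties at 100% and the
  # documented tie-break must pick the same pair on both datasets
  d <- sep_data(n = 120, d = 10)
  cfg <- svm_config(C_grid = c(1, 4), w_grid = c(0.25, 1))
  m1 <- tune_and_train(d$X, d$y, cfg, inner_cv_folds = 3, seed = 5)
  m2 <- tune_and_train(rbind(d$X, d$X), c(d$y, d$y), cfg,
                       inner_cv_folds = 3, seed = 5)
  expect_equal(m1$hyper, m2$hyper)
})

test_that("single-class training data is rejected", {
  d <- sep_data()
  expect_error(tune_and_train(d$X, rep(1, nrow(d$X)), svm_config()),
               "single-class")
})

test_that("evaluate matches a brute-force confusion count", {
  set.seed(9)
  y <- sample(0:1, 500, replace = TRUE)
  pred <- sample(0:1, 500, replace = TRUE)
  r <- evaluate_predictions(y, pred)
  tp <- sum(y == 1 & pred == 1); fn <- sum(y == 1 & pred == 0)
  fp <- sum(y == 0 & pred == 1); tn <- sum(y == 0 & pred == 0)
  expect_equal(unname(r$confusion), c(tp, fn, fp, tn))
  expect_equal(r$sensitivity, 100 * tp / (tp + fn))
  expect_equal(r$specificity, 100 * tn / (tn + fp))
  expect_equal(r$balanced_accuracy,
               (r$sensitivity + r$specificity) / 2)
  expect_equal(sum(r$confusion), 500)
})

test_that("balanced accuracy identity reproduces the published value pairs", {
  # 67.43% sensitivity / 67.25% specificity -> 67.34% balanced accuracy
  y <- rep(c(1, 0), c(10000, 10000))
  pred <- rep(c(1, 0, 1, 0), c(6743, 3257, 3275, 6725))
  r <- evaluate_predictions(y, pred)
  expect_equal(r$sensitivity, 67.43)
  expect_equal(r$specificity, 67.25)
  expect_equal(r$balanced_accuracy, 67.34)
  # 65.09% / 67.49% -> 66.29%
  r2 <- eval_report(65.09, 67.49)
  expect_equal(r2$balanced_accuracy, 66.29)
  # perfect predictions
  r3 <- evaluate_predictions(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(r3$balanced_accuracy, 100)
  expect_equal(unname(r3$confusion[c("FN", "FP")]), c(0, 0))
})

test_that("an empty class leaves its rate undefined", {
  r <- evaluate_predictions(c(1, 1, 1), c(1, 0, 1))
  expect_true(is.na(r$specificity))
})

test_that("prediction refuses mismatched feature manifests and uses stored scaling", {
  d <- sep_data()
  m <- tune_and_train(d$X, d$y, svm_config(C_grid = 1, w_grid = 0.25),
                      seed = 1)
  bad <- d$X
  colnames(bad) <- paste0("g", 1:4)
  expect_error(predict(m, bad), "manifest")
  # per-row predictions are independent of the rest of the test set:
  # scaling comes from the stored training parameters, not the test data
  row <- d$X[5, , drop = FALSE]
  extreme <- matrix(100, 3, 4, dimnames = list(NULL, colnames(d$X)))
  p_alone <- predict(m, row)
  p_mixed <- predict(m, rbind(row, extreme))[1]
  expect_equal(p_alone, p_mixed)
})
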