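test_that("confusion counts follow the score >= threshold convention", {
  cm <- confusion_at_threshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(unlist(cm[c("tp", "fp", "tn", "fn")]),
               c(tp = 2, fp = 0, tn = 2, fn = 0))
  high <- confusion_at_threshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), 0.95)
  expect_equal(high$tp + high$fp, 0)
  # boundary scores count positive
  b <- confusion_at_threshold(c(0.5, 0.4), c(1, 0), 0.5)
  expect_equal(b$tp, 1)
  expect_equal(b$fp, 0)
  expect_error(confusion_at_threshold(numeric(0), integer(0), 0.5), "empty")
})

test_that("metrics use exact ratios with 3-decimal half-away rounding", {
  m1 <- metrics_from_confusion(confusion_counts(11, 4, 35, 2))
  expect_equal(m1[c("sensitivity", "specificity", "accuracy")],
               list(sensitivity = 0.846, specificity = 0.897,
                    accuracy = 0.885))
  expect_warning(
    expect_warning(mz <- metrics_from_confusion(confusion_counts(0, 0, 5, 0)),
                   "sensitivity undefined"),
    "ppv undefined")
  expect_true(is.nan(mz$sensitivity))
  expect_error(metrics_from_confusion(confusion_counts(0, 0, 0, 0)),
               "all-zero")
  expect_error(confusion_counts(-1, 0, 0, 0), "nonnegative")
})

test_that("ROC AUC equals exhaustive pair counting with tie credit", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2), c(1, 1, 0)), 1)
  sc <- c(1, 2, 2, 3, 3, 3, 4, 5, 5, 6, 7, 7)
  y <- c(0, 0, 1, 0, 1, 1, 0, 1, 0, 1, 1, 0)
  expect_equal(roc_auc(sc, y), brute_auc(sc, y))
  sc2 <- withr::with_seed(1, runif(2000))
  y2 <- withr::with_seed(2, rbinom(2000, 1, 0.5))
  expect_equal(roc_auc(sc2, y2), 0.5, tolerance = 0.03 / 0.5)
  expect_error(roc_auc(1:5, rep(1, 5)), "single class")
})

test_that("AUC is invariant under strictly increasing score transforms and
           agrees with an independent implementation", {
  sc <- withr::with_seed(3, rnorm(100))
  y <- withr::with_seed(4, rbinom(100, 1, 0.4))
  a <- roc_auc(sc, y)
  expect_equal(roc_auc(exp(sc), y), a)
  expect_equal(roc_auc(sc^3 + 2 * sc, y), a)
  skip_if_not_installed("pROC")
  theirs <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                           direction = "<")))
  expect_equal(a, theirs, tolerance = 1e-9)
})

test_that("AUC drop-off reproduces printed percentage points", {
  expect_equal(auc_dropoff(0.921, 0.872), 4.9)
  expect_equal(auc_dropoff(0.914, 0.872), 4.2)
  expect_equal(auc_dropoff(0.7, 0.7), 0)
})

test_that("sensitivity falls and specificity rises as the threshold
           increases", {
  sc <- withr::with_seed(5, runif(200))
  y <- withr::with_seed(6, rbinom(200, 1, 0.5))
  thresholds <- seq(0.05, 0.95, by = 0.05)
  sens <- numeric(0); spec <- numeric(0)
  for (t in thresholds) {
    cm <- confusion_at_threshold(sc, y, t)
    sens <- c(sens, cm$tp / (cm$tp + cm$fn))
    spec <- c(spec, cm$tn / (cm$tn + cm$fp))
  }
  expect_true(all(diff(sens) <= 1e-12))
  expect_true(all(diff(spec) >= -1e-12))
})

test_that("evaluate_model reports consistent counts and leaves the model
           untouched", {
  X <- withr::with_seed(7, data.frame(a = rnorm(60), b = rnorm(60)))
  y <- as.integer(X$a + 0.5 * withr::with_seed(8, rnorm(60)) > 0)
  spec <- structure(list(
    predictors = list(data.frame(feature = "a", sign = 1),
                      data.frame(feature = "b", sign = 1),
                      data.frame(feature = "a", sign = -1)),
    standardization = data.frame(feature = c("a", "b"),
                                 mean = colMeans(X), sd = sapply(X, sd)),
    objective = 0, seed = 1L), class = "predictor_spec")
  model <- suppressWarnings(fit_logistic(apply_predictors(spec, X), y))
  model$threshold <- 0.5
  hash_before <- cardiodyn:::object_hash(list(spec, model))
  rep1 <- evaluate_model(model, spec, X, y, "train")
  rep2 <- evaluate_model(model, spec, X, y, "test")
  expect_identical(cardiodyn:::object_hash(list(spec, model)), hash_before)
  expect_equal(with(rep1$counts, tp + fp + tn + fn), rep1$n)
  expect_equal(rep1$n, 60)
  for (v in c("sensitivity", "specificity", "accuracy", "auc")) {
    expect_gte(rep1[[v]], 0)
    expect_lte(rep1[[v]], 1)
  }
  expect_identical(rep1$counts, rep2$counts)
  expect_error(evaluate_model(model, spec, X, y[1:10], "test"), "mismatch")
})
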