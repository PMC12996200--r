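test_that("conditional entropy objective matches hand-enumerated cells", {
  # 8 samples, 2 bins/axis: samples 1-4 and 5-8 fall in two joint cells
  P <- cbind(1:8,
             c(5, 5, 5, 5, 1, 1, 1, 1),
             rep(0, 8))
  y <- c(0, 0, 1, 1, 0, 1, 1, 1)
  hand <- 0.5 * log(2) + 0.5 * (-(0.25 * log(0.25) + 0.75 * log(0.75)))
  expect_equal(conditional_entropy_objective(P, y, bins = 2), hand)
})

test_that("conditional entropy objective hits its analytic extremes", {
  y <- rep(c(0, 1), each = 50)
  sep <- cbind(y * 10 + seq(0.001, 0.1, length.out = 100),
               rnorm(100), rnorm(100))
  expect_equal(conditional_entropy_objective(sep, y), 0)
  Pn <- withr::with_seed(1, matrix(rnorm(6000), ncol = 3))
  yn <- withr::with_seed(2, rbinom(2000, 1, 0.3))
  expect_equal(conditional_entropy_objective(Pn, yn),
               shannon(c(mean(yn), 1 - mean(yn))), tolerance = 0.08)
  expect_warning(h0 <- conditional_entropy_objective(Pn[1:50, ],
                                                     rep(1, 50)),
                 "single-class")
  expect_equal(h0, 0)
})

test_that("the annealer finds an informative feature among noise and
           matches exhaustive search on a small pool", {
  n <- 300
  X <- withr::with_seed(7, {
    d <- as.data.frame(matrix(rnorm(n * 10), ncol = 10))
    names(d) <- paste0("noise", 1:10)
    d
  })
  y <- withr::with_seed(8, rbinom(n, 1, 0.4))
  X$informative <- y * 3 + withr::with_seed(9, rnorm(n))
  spec <- build_predictors(X, y, seed = 3)
  expect_true("informative" %in%
                unlist(lapply(spec$predictors, `[[`, "feature")))
  expect_length(spec$predictors, 3)
  # exhaustive oracle over single-feature triples on a pool of 6
  X6 <- withr::with_seed(10, {
    d <- as.data.frame(matrix(rnorm(n * 6), ncol = 6))
    names(d) <- paste0("f", 1:6)
    d
  })
  y6 <- as.integer(X6$f2 + 0.8 * X6$f5 +
                     withr::with_seed(11, rnorm(n)) * 0.8 > 0.3)
  cfg <- predictor_search_config(max_features = 1, pool_size = 6,
                                 iterations = 1500, restarts = 3)
  sp6 <- build_predictors(X6, y6, seed = 3, config = cfg)
  expect_equal(sp6$objective, exhaustive_predictor_objective(X6, y6),
               tolerance = 1e-9)
})

test_that("search on a pure-noise pool cannot beat the label entropy by
           more than selection bias", {
  n <- 2000
  X <- withr::with_seed(2, {
    d <- as.data.frame(matrix(rnorm(n * 12), ncol = 12))
    names(d) <- paste0("f", 1:12)
    d
  })
  y <- withr::with_seed(3, rbinom(n, 1, 0.4))
  sp <- build_predictors(X, y, seed = 5,
                         config = predictor_search_config(iterations = 600,
                                                          restarts = 2))
  hy <- shannon(c(mean(y), 1 - mean(y)))
  expect_lte(hy - sp$objective, 0.05)
  expect_lte(sp$objective, hy + 1e-9)
})

test_that("adding an informative feature to the pool never worsens the
           exhaustive minimum", {
  n <- 250
  X5 <- withr::with_seed(20, {
    d <- as.data.frame(matrix(rnorm(n * 5), ncol = 5))
    names(d) <- paste0("f", 1:5)
    d
  })
  y <- withr::with_seed(21, rbinom(n, 1, 0.5))
  base <- exhaustive_predictor_objective(X5, y)
  X6 <- X5
  X6$strong <- y * 2 + withr::with_seed(22, rnorm(n))
  expect_lte(exhaustive_predictor_objective(X6, y), base + 1e-12)
})

test_that("search is deterministic and firewalled", {
  n <- 120
  X <- withr::with_seed(4, {
    d <- as.data.frame(matrix(rnorm(n * 5), ncol = 5))
    names(d) <- paste0("f", 1:5)
    d
  })
  y <- rep(c(0, 1), each = 60)
  a <- build_predictors(X, y, seed = 11)
  b <- build_predictors(X, y, seed = 11)
  expect_identical(a, b)
  split <- structure(list(train_ids = sprintf("P%03d", 1:100),
                          test_ids = sprintf("P%03d", 101:120),
                          tuning_ids = NULL, seed = 1L),
                     class = "cohort_split")
  expect_error(build_predictors(X, y, seed = 1, split = split,
                                ids = sprintf("P%03d", 1:120)),
               "firewall")
  expect_error(build_predictors(X[1:15, ], y[1:15], seed = 1),
               "10 samples per class")
})

test_that("applying a spec reproduces signed z-scores without refitting", {
  X <- data.frame(a = c(1, 2, 3, 4), b = c(10, 20, 30, 40))
  spec <- structure(list(
    predictors = list(data.frame(feature = "a", sign = 1),
                      data.frame(feature = "b", sign = -1),
                      data.frame(feature = c("a", "b"), sign = c(1, -1))),
    standardization = data.frame(feature = c("a", "b"),
                                 mean = c(2, 20), sd = c(1, 10)),
    objective = 0, seed = 1L), class = "predictor_spec")
  P <- apply_predictors(spec, X)
  expect_equal(dim(P), c(4, 3))
  expect_equal(P[, 1], (X$a - 2) / 1)
  expect_equal(P[, 2], -(X$b - 20) / 10)
  expect_equal(P[, 3], P[, 1] + P[, 2])
  flipped <- spec
  for (i in 1:3) flipped$predictors[[i]]$sign <- -flipped$predictors[[i]]$sign
  expect_equal(apply_predictors(flipped, X), -P, ignore_attr = TRUE)
  expect_error(apply_predictors(spec, data.frame(a = 1)), "missing feature.*b")
})

test_that("logistic fitting recovers known coefficients", {
  truth <- c(-1, 1.5, -0.5, 2)
  est <- sapply(1:20, function(rep) {
    P <- withr::with_seed(rep, matrix(rnorm(3 * 2000), ncol = 3))
    eta <- truth[1] + P %*% truth[-1]
    y <- withr::with_seed(rep + 500, rbinom(2000, 1, 1 / (1 + exp(-eta))))
    fit_logistic(P, y)$coefficients
  })
  expect_true(all(abs(rowMeans(est) - truth) < 0.25))
})

test_that("degenerate logistic inputs are handled analytically", {
  Pc <- matrix(1, 200, 3)
  y <- rep(c(1, 0, 0, 0), 50)  # prevalence 0.25
  fit <- suppressWarnings(fit_logistic(Pc, y))
  score <- predict_scores(fit, Pc)
  expect_equal(unique(round(score, 6)), 0.25)
  sepP <- matrix(c(rep(0, 10), rep(1, 10)), ncol = 1)[, c(1, 1, 1)]
  ysep <- rep(c(0, 1), each = 10)
  expect_warning(fs <- fit_logistic(sepP, ysep), "separation")
  expect_true(all(is.finite(fs$coefficients)))
  expect_error(fit_logistic(Pc, rep(1, 200)), "single class")
})

test_that("linear AVAi fitting recovers coefficients exactly and under
           noise", {
  P <- withr::with_seed(5, matrix(rnorm(300), ncol = 3))
  truth <- c(1.2, 0.1, -0.2, 0.05)
  clean <- as.numeric(cbind(1, P) %*% truth)
  fit <- fit_linear_avai(P, clean)
  expect_equal(fit$coefficients, truth, tolerance = 1e-8)
  Pn <- withr::with_seed(6, matrix(rnorm(600), ncol = 3))
  noisy <- as.numeric(cbind(1, Pn) %*% truth) +
    withr::with_seed(7, rnorm(200, sd = 0.1))
  fitn <- fit_linear_avai(Pn, pmax(noisy, 0.01))
  expect_true(all(abs(fitn$coefficients - truth) < 0.1))
  expect_true(all(is.finite(predict_scores(fitn, Pn))))
  expect_error(fit_linear_avai(P[1:3, ], clean[1:3]), "at least 5")
  expect_error(fit_linear_avai(P, clean - 10), "positive")
})

test_that("Youden threshold matches exhaustive cut enumeration", {
  scores <- c(rep(0.1, 3), rep(0.9, 3))
  labels <- c(0, 0, 0, 1, 1, 1)
  expect_equal(choose_threshold(scores, labels), 0.5)
  sc <- withr::with_seed(8, runif(20))
  y <- withr::with_seed(9, rbinom(20, 1, 0.5))
  thr <- choose_threshold(sc, y)
  u <- sort(unique(sc))
  cands <- (u[-1] + u[-length(u)]) / 2
  J <- sapply(cands, function(t) {
    pred <- sc >= t
    sum(pred & y == 1) / sum(y == 1) + sum(!pred & y == 0) / sum(y == 0) - 1
  })
  achieved <- {
    pred <- sc >= thr
    sum(pred & y == 1) / sum(y == 1) + sum(!pred & y == 0) / sum(y == 0) - 1
  }
  expect_equal(achieved, max(J))
  expect_equal(thr, min(cands[J >= max(J) - 1e-12]))
  # labels independent of scores leave little to optimize at scale
  scb <- withr::with_seed(10, runif(2000))
  yb <- withr::with_seed(11, rbinom(2000, 1, 0.5))
  thrb <- choose_threshold(scb, yb)
  predb <- scb >= thrb
  Jb <- sum(predb & yb == 1) / sum(yb == 1) +
    sum(!predb & yb == 0) / sum(yb == 0) - 1
  expect_lte(Jb, 0.1)
})
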