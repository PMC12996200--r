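#' Conditional label entropy given jointly binned predictors
#'
#' The minimum-entropy objective for predictor search: each of the three
#' predictor columns is discretized into equal-frequency bins, and the
#' conditional Shannon entropy of the class label given the joint cell is
#' returned (nats; empty cells carry no mass). Zero means the binned
#' predictors separate the classes perfectly; label-independent predictors
#' score close to the marginal label entropy.
#'
#' @param predictor_values numeric matrix (or data.frame) of predictor
#'   columns.
#' @param labels binary vector (0/1 or logical) of class labels.
#' @param bins equal-frequency bins per predictor axis.
#' @return Nonnegative numeric scalar (nats).
#' @export
conditional_entropy_objective <- function(predictor_values, labels, bins = 4) {
  P <- as.matrix(predictor_values)
  y <- as.integer(as.logical(labels))
  n <- nrow(P)
  if (n != length(y)) stop("predictor rows and labels differ in length")
  if (n < bins) stop("need at least `bins` samples")
  if (length(unique(y)) < 2) {
    warning("single-class labels; conditional entropy is 0")
    return(0)
  }
  cell <- rep(0L, n)
  for (j in seq_len(ncol(P))) {
    r <- rank(P[, j], ties.method = "average")
    b <- pmin(pmax(ceiling(bins * (r - 0.5) / n), 1L), bins)
    cell <- cell * bins + (b - 1L)
  }
  H <- 0
  for (cl in unique(cell)) {
    sel <- cell == cl
    p_cell <- mean(sel)
    p1 <- mean(y[sel])
    h <- 0
    if (p1 > 0 && p1 < 1) h <- -p1 * log(p1) - (1 - p1) * log(1 - p1)
    H <- H + p_cell * h
  }
  H
}

#' Search configuration for predictor construction
#'
#' @param n_predictors number of predictors built (three, matching the
#'   low phase-space dimensionality that motivates the model size).
#' @param max_features maximum features per predictor.
#' @param pool_size number of top-ranked candidate features retained.
#' @param bins equal-frequency bins per axis in the entropy objective.
#' @param iterations simulated-annealing iterations per restart.
#' @param restarts independent annealing restarts.
#' @param t0 initial temperature (default: half the label entropy).
#' @return A `predictor_search_config` list.
#' @export
predictor_search_config <- function(n_predictors = 3, max_features = 4,
                                    pool_size = 20, bins = 4,
                                    iterations = 2000, restarts = 3,
                                    t0 = NULL) {
  structure(list(n_predictors = n_predictors, max_features = max_features,
                 pool_size = pool_size, bins = bins, iterations = iterations,
                 restarts = restarts, t0 = t0),
            class = "predictor_search_config")
}

#' Build unweighted signed-sum predictors by minimum-entropy annealing
#'
#' Features are z-scored on the tuning set, pre-ranked by univariate
#' two-sample KS separation between the classes, and the top `pool_size`
#' retained. A simulated-annealing search over (feature subset, sign)
#' assignments for the three predictors minimizes
#' [conditional_entropy_objective()]. Predictors are plain signed sums of
#' z-scored features — no weights are fitted, so the model's discriminative
#' power lives in the extracted features. Ties are broken by fewer total
#' features, then lexicographically, and the search is deterministic for a
#' fixed seed.
#'
#' @param features data.frame of numeric candidate features (tuning set
#'   only).
#' @param labels binary outcome for the same rows.
#' @param seed integer seed.
#' @param config a [predictor_search_config()].
#' @param split optional `cohort_split`; when given, `ids` are checked
#'   against the test-set firewall.
#' @param ids optional subject ids of `features` rows (for the firewall).
#' @return A `predictor_spec`: list with `predictors` (list of data.frames
#'   `feature`, `sign`), `standardization` (data.frame `feature`, `mean`,
#'   `sd`), `objective`, `seed`.
#' @export
build_predictors <- function(features, labels, seed = 1L,
                             config = predictor_search_config(),
                             split = NULL, ids = NULL) {
  if (!is.null(ids)) assert_not_test(ids, split, "build_predictors")
  y <- as.integer(as.logical(labels))
  if (length(unique(y)) < 2 || min(table(y)) < 10) {
    stop("need at least 10 samples per class")
  }
  num <- vapply(features, is.numeric, logical(1))
  X <- as.matrix(features[, num, drop = FALSE])
  sds <- apply(X, 2, sd)
  X <- X[, is.finite(sds) & sds > 0, drop = FALSE]
  if (ncol(X) < config$n_predictors) stop("fewer than 3 usable features")
  mu <- colMeans(X)
  sig <- apply(X, 2, sd)
  Z <- sweep(sweep(X, 2, mu), 2, sig, "/")
  ks_rank <- vapply(seq_len(ncol(Z)), function(j) {
    suppressWarnings(unname(ks.test(Z[y == 1, j], Z[y == 0, j],
                                    exact = FALSE)$statistic))
  }, numeric(1))
  pool <- order(ks_rank, decreasing = TRUE)[seq_len(min(config$pool_size,
                                                        ncol(Z)))]
  Zp <- Z[, pool, drop = FALSE]
  res <- withr::with_seed(seed, anneal_predictors(Zp, y, config))
  spec_predictors <- lapply(res$state, function(pr) {
    ord <- order(colnames(Zp)[abs(pr)])
    data.frame(feature = colnames(Zp)[abs(pr)][ord],
               sign = sign(pr)[ord], stringsAsFactors = FALSE)
  })
  used <- unique(unlist(lapply(spec_predictors, `[[`, "feature")))
  structure(list(predictors = spec_predictors,
                 standardization = data.frame(feature = used,
                                              mean = mu[used], sd = sig[used],
                                              row.names = NULL),
                 objective = res$objective,
                 seed = as.integer(seed)),
            class = "predictor_spec")
}

# Simulated annealing over signed feature subsets. State: list of
# n_predictors integer vectors of signed column indices into Zp.
anneal_predictors <- function(Zp, y, config) {
  np <- config$n_predictors
  nf <- ncol(Zp)
  obj <- function(state) {
    P <- vapply(state, function(pr) {
      Zp[, abs(pr), drop = FALSE] %*% sign(pr)
    }, numeric(nrow(Zp)))
    conditional_entropy_objective(P, y, config$bins)
  }
  state_key <- function(state) {
    paste(vapply(state, function(pr) {
      o <- order(colnames(Zp)[abs(pr)])
      paste(sign(pr)[o] * abs(pr)[o], collapse = ",")
    }, character(1)), collapse = "|")
  }
  better <- function(a, b) {
    # TRUE if candidate a beats incumbent b
    if (is.null(b)) return(TRUE)
    if (a$objective < b$objective - 1e-12) return(TRUE)
    if (a$objective > b$objective + 1e-12) return(FALSE)
    na <- sum(lengths(a$state)); nb <- sum(lengths(b$state))
    if (na != nb) return(na < nb)
    state_key(a$state) < state_key(b$state)
  }
  hy <- {
    p1 <- mean(y)
    -p1 * log(p1) - (1 - p1) * log(1 - p1)
  }
  t0 <- config$t0 %||% (0.5 * hy)
  cooling <- (1e-3)^(1 / max(1, config$iterations))
  best <- NULL
  for (r in seq_len(config$restarts)) {
    state <- lapply(seq_len(np), function(j) {
      sample(nf, 1)
    })
    cur_obj <- obj(state)
    if (better(list(state = state, objective = cur_obj), best)) {
      best <- list(state = state, objective = cur_obj)
    }
    temp <- t0
    for (it in seq_len(config$iterations)) {
      cand <- propose_move(state, nf, config$max_features)
      cand_obj <- obj(cand)
      if (cand_obj < cur_obj ||
          runif(1) < exp(-(cand_obj - cur_obj) / max(temp, 1e-9))) {
        state <- cand
        cur_obj <- cand_obj
        if (better(list(state = state, objective = cur_obj), best)) {
          best <- list(state = state, objective = cur_obj)
        }
      }
      temp <- temp * cooling
    }
  }
  best
}

propose_move <- function(state, nf, max_features) {
  p <- sample(length(state), 1)
  pr <- state[[p]]
  used <- abs(pr)
  free <- setdiff(seq_len(nf), used)
  ops <- c(if (length(pr) < max_features && length(free)) "add",
           if (length(pr) > 1) "drop",
           if (length(free)) "replace",
           "flip")
  op <- if (length(ops) == 1) ops else sample(ops, 1)
  pr <- switch(op,
    add = c(pr, sample(c(-1, 1), 1) * free[sample.int(length(free), 1)]),
    drop = pr[-sample.int(length(pr), 1)],
    replace = {
      i <- sample.int(length(pr), 1)
      pr[i] <- sign(pr[i]) * free[sample.int(length(free), 1)]
      pr
    },
    flip = {
      i <- sample.int(length(pr), 1)
      pr[i] <- -pr[i]
      pr
    })
  state[[p]] <- pr
  state
}

#' Apply a predictor spec to feature rows
#'
#' Each predictor is the signed sum of its features z-scored with the
#' standardization learned on the tuning set; nothing is refitted.
#'
#' @param spec a `predictor_spec`.
#' @param feature_rows data.frame containing every feature the predictor
#'   spec uses.
#' @return Numeric matrix with one column per predictor (`P1..P3`) and one
#'   row per input row.
#' @export
apply_predictors <- function(spec, feature_rows) {
  stopifnot(inherits(spec, "predictor_spec"))
  std <- spec$standardization
  missing <- setdiff(std$feature, names(feature_rows))
  if (length(missing)) {
    stop("missing feature(s) in input rows: ", paste(missing, collapse = ", "))
  }
  n <- nrow(feature_rows)
  P <- vapply(spec$predictors, function(pr) {
    acc <- numeric(n)
    for (k in seq_len(nrow(pr))) {
      f <- pr$feature[k]
      i <- match(f, std$feature)
      acc <- acc + pr$sign[k] * (feature_rows[[f]] - std$mean[i]) / std$sd[i]
    }
    acc
  }, numeric(n))
  P <- matrix(P, nrow = n)
  colnames(P) <- paste0("P", seq_along(spec$predictors))
  P
}

#' Fit a logistic model on the three predictors
#'
#' Maximum-likelihood logistic regression of the binary outcome on the
#' predictor columns. Complete separation (or non-convergence) is guarded
#' by refitting with a small ridge penalty on the slopes, with a warning.
#'
#' @param predictor_table matrix/data.frame of 3 predictor columns
#'   (tuning set only).
#' @param labels binary outcome.
#' @param split,ids optional test-set firewall (as in [build_predictors()]).
#' @param ridge penalty used by the separation guard.
#' @return A `fitted_model`: list with `kind = "logistic_binary"`,
#'   `coefficients` (intercept + 3 slopes), `threshold` (NA until
#'   [choose_threshold()]), `dependent`.
#' @export
fit_logistic <- function(predictor_table, labels, split = NULL, ids = NULL,
                         ridge = 1e-2) {
  if (!is.null(ids)) assert_not_test(ids, split, "fit_logistic")
  P <- as.matrix(predictor_table)
  y <- as.integer(as.logical(labels))
  if (length(unique(y)) < 2) stop("labels contain a single class")
  df <- data.frame(y = y, P)
  fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
  beta <- unname(coef(fit))
  if (!fit$converged || any(!is.finite(beta)) || any(abs(beta) > 15)) {
    warning("possible complete separation; refitting with a small ridge penalty")
    beta <- ridge_logistic(cbind(1, P), y, ridge)
  }
  structure(list(kind = "logistic_binary", coefficients = beta,
                 threshold = NA_real_, dependent = "binary diagnosis"),
            class = "fitted_model")
}

ridge_logistic <- function(X, y, lambda) {
  nll <- function(b) {
    eta <- X %*% b
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
      lambda * sum(b[-1]^2)
  }
  opt <- optim(rep(0, ncol(X)), nll, method = "BFGS",
               control = list(maxit = 500))
  opt$par
}

#' Fit a linear model of indexed aortic valve area on the predictors
#'
#' Least-squares regression of AVAi (cm^2/m^2) on the three predictors.
#' For classification the score is the negated predicted AVAi — a smaller
#' valve area means more severe stenosis — with the threshold chosen
#' downstream on the tuning set.
#'
#' @param predictor_table matrix/data.frame of 3 predictor columns.
#' @param avai_values positive AVAi outcomes.
#' @param split,ids optional test-set firewall.
#' @return A `fitted_model` with `kind = "linear_avai"`.
#' @export
fit_linear_avai <- function(predictor_table, avai_values, split = NULL,
                            ids = NULL) {
  if (!is.null(ids)) assert_not_test(ids, split, "fit_linear_avai")
  P <- as.matrix(predictor_table)
  if (nrow(P) < 5) stop("need at least 5 rows")
  if (any(avai_values <= 0)) stop("AVAi values must be positive")
  fit <- lm.fit(cbind(1, P), avai_values)
  structure(list(kind = "linear_avai", coefficients = unname(fit$coefficients),
                 threshold = NA_real_, dependent = "AVAi"),
            class = "fitted_model")
}

#' Score rows with a fitted model
#'
#' Logistic models return fitted probabilities; linear AVAi models return
#' the negated predicted valve area (higher score = more diseased).
#'
#' @param model a `fitted_model`.
#' @param predictor_table predictor columns from [apply_predictors()].
#' @return Numeric score vector.
#' @export
predict_scores <- function(model, predictor_table) {
  P <- as.matrix(predictor_table)
  eta <- as.numeric(cbind(1, P) %*% model$coefficients)
  if (model$kind == "logistic_binary") 1 / (1 + exp(-eta)) else -eta
}

#' Choose a decision threshold by Youden's J
#'
#' Maximizes sensitivity + specificity - 1 over midpoints between adjacent
#' sorted unique scores (prediction is positive when score >= threshold).
#' Ties take the lowest threshold, favouring sensitivity.
#'
#' @param scores numeric scores (tuning set only).
#' @param labels binary outcome.
#' @param split,ids optional test-set firewall.
#' @return Numeric threshold.
#' @export
choose_threshold <- function(scores, labels, split = NULL, ids = NULL) {
  if (!is.null(ids)) assert_not_test(ids, split, "choose_threshold")
  y <- as.integer(as.logical(labels))
  if (length(unique(y)) < 2) stop("labels contain a single class")
  u <- sort(unique(scores))
  cand <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  J <- vapply(cand, function(thr) {
    pred <- scores >= thr
    sens <- sum(pred & y == 1) / sum(y == 1)
    spec <- sum(!pred & y == 0) / sum(y == 0)
    sens + spec - 1
  }, numeric(1))
  cand[which(J >= max(J) - 1e-12)[1]]
}
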