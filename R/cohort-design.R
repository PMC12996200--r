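#' Cluster subjects on demographics, body measurements and dynamics
#'
#' Centroid (k-means) clustering on z-scored columns, blind to diagnosis.
#' The number of clusters is chosen by maximizing the mean silhouette width
#' over `k_range`. Deterministic for a fixed seed.
#'
#' @param feature_rows data.frame of numeric columns to cluster on
#'   (conventionally age, sex, BMI, BSA, MLE, DCorr).
#' @param k_range candidate cluster counts (each within `[2, n-1]`).
#' @param seed integer seed.
#' @param cols optional character vector restricting the columns used.
#' @return Integer vector of cluster labels (length `nrow(feature_rows)`).
#' @export
cluster_subjects <- function(feature_rows, k_range = 2:6, seed = 1L,
                             cols = NULL) {
  if (!is.null(cols)) feature_rows <- feature_rows[, cols, drop = FALSE]
  X <- as.matrix(feature_rows)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (n < 4) stop("degenerate input: need at least 4 subjects to cluster")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) X <- X[, sds > 0, drop = FALSE]
  if (ncol(X) == 0 || nrow(unique(X)) == 1) {
    warning("all rows identical; returning a single cluster")
    return(rep(1L, n))
  }
  Z <- scale(X)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1 &
                       k_range <= nrow(unique(Z))]
  if (!length(k_range)) k_range <- 2L
  D <- dist(Z)
  withr::with_seed(seed, {
    fits <- lapply(k_range, function(k) {
      suppressWarnings(kmeans(Z, centers = k, nstart = 10, iter.max = 50))
    })
  })
  sil <- vapply(seq_along(fits), function(i) {
    cl <- fits[[i]]$cluster
    if (length(unique(cl)) < 2) return(-Inf)
    mean(cluster::silhouette(cl, D)[, 3])
  }, numeric(1))
  as.integer(fits[[which.max(sil)]]$cluster)
}

#' Cluster-stratified train/test split
#'
#' Within each cluster-by-diagnosis stratum, assigns subjects to the test
#' set by largest-remainder rounding of `test_frac`, so diagnosis
#' proportions in train and test differ by at most one subject per stratum.
#' Singleton strata go to the training set with a warning. The resulting
#' split carries the test-set firewall honoured by the model-building
#' functions.
#'
#' @param subjects data.frame with columns `id` and `group` (diagnosis).
#' @param labels integer cluster labels from [cluster_subjects()].
#' @param test_frac test-set fraction in (0, 1).
#' @param seed integer seed.
#' @return A `cohort_split`: list with `cluster_of` (named), `train_ids`,
#'   `test_ids`, `tuning_ids` (NULL until [tuning_split()]), `seed`.
#' @export
split_cohort <- function(subjects, labels, test_frac = 0.2, seed = 1L) {
  if (test_frac <= 0 || test_frac >= 1) stop("test_frac must be in (0, 1)")
  stopifnot(nrow(subjects) == length(labels))
  ids <- subjects$id
  strata <- split(ids, list(cluster = labels, group = subjects$group),
                  drop = TRUE)
  sizes <- lengths(strata)
  single <- sizes == 1
  if (any(single)) {
    warning(sum(single), " singleton stratum(s) assigned to the training set")
  }
  quota <- ifelse(single, 0, sizes * test_frac)
  base <- floor(quota)
  remainder <- quota - base
  n_test <- round(sum(quota))
  extra <- n_test - sum(base)
  add <- rep(0L, length(strata))
  if (extra > 0) {
    ord <- order(remainder, decreasing = TRUE)
    add[ord[seq_len(extra)]] <- 1L
  }
  take <- pmin(base + add, ifelse(single, 0, sizes))
  test_ids <- character(0)
  withr::with_seed(seed, {
    for (s in seq_along(strata)) {
      if (take[s] > 0) {
        test_ids <- c(test_ids, sample(strata[[s]], take[s]))
      }
    }
  })
  cluster_of <- stats::setNames(as.integer(labels), ids)
  structure(list(cluster_of = cluster_of,
                 train_ids = setdiff(ids, test_ids),
                 test_ids = test_ids,
                 tuning_ids = NULL,
                 seed = as.integer(seed)),
            class = "cohort_split")
}

#' Carve a tuning (validation) set out of the training set
#'
#' Stratified by diagnosis; the tuning set size is
#' `ceiling(tuning_frac * |train|)` exactly, with per-stratum counts by
#' largest remainder.
#'
#' @param train_ids training-set subject ids.
#' @param tuning_frac tuning fraction in (0, 1).
#' @param seed integer seed.
#' @param strata optional vector (parallel to `train_ids`) of diagnosis
#'   labels; unstratified when NULL.
#' @return List with `tuning_ids` and `holdout_ids` (their union is
#'   `train_ids`).
#' @export
tuning_split <- function(train_ids, tuning_frac = 0.8, seed = 1L,
                         strata = NULL) {
  if (!length(train_ids)) stop("empty training set")
  if (tuning_frac <= 0 || tuning_frac >= 1) stop("tuning_frac must be in (0, 1)")
  total <- ceiling(tuning_frac * length(train_ids))
  groups <- if (is.null(strata)) {
    list(all = train_ids)
  } else {
    split(train_ids, strata, drop = TRUE)
  }
  sizes <- lengths(groups)
  quota <- sizes * total / sum(sizes)
  base <- pmin(floor(quota), sizes)
  extra <- total - sum(base)
  remainder <- quota - floor(quota)
  add <- rep(0L, length(groups))
  if (extra > 0) {
    room <- sizes - base
    ord <- order(remainder, decreasing = TRUE)
    for (s in ord) {
      if (extra == 0) break
      grab <- min(room[s], 1L)
      add[s] <- add[s] + grab
      extra <- extra - grab
    }
    while (extra > 0) {  # distribute any leftover where room remains
      room <- sizes - base - add
      s <- which(room > 0)[1]
      add[s] <- add[s] + 1L
      extra <- extra - 1L
    }
  }
  tuning_ids <- character(0)
  withr::with_seed(seed, {
    for (s in seq_along(groups)) {
      k <- base[s] + add[s]
      if (k > 0) tuning_ids <- c(tuning_ids, sample(groups[[s]], k))
    }
  })
  list(tuning_ids = tuning_ids,
       holdout_ids = setdiff(train_ids, tuning_ids))
}

#' Attach a tuning split to a cohort split
#' @param split a `cohort_split`.
#' @param tuning_frac,seed,strata passed to [tuning_split()].
#' @return The `cohort_split` with `tuning_ids` filled in.
#' @export
add_tuning_set <- function(split, tuning_frac = 0.8, seed = 1L, strata = NULL) {
  ts <- tuning_split(split$train_ids, tuning_frac, seed, strata)
  split$tuning_ids <- ts$tuning_ids
  split
}

# Firewall: stop if any id belongs to the held-out test set.
assert_not_test <- function(ids, split, what = "operation") {
  if (is.null(split)) return(invisible(TRUE))
  bad <- intersect(ids, split$test_ids)
  if (length(bad)) {
    stop("test-set firewall violation: ", what, " received test id(s) ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Kolmogorov-Smirnov train/test agreement screen
#'
#' Two-sample KS statistic and asymptotic p-value per shared feature
#' column; features with `p < alpha` are flagged as drawn from visibly
#' different distributions.
#'
#' @param train_features,test_features data.frames with matching numeric
#'   columns (>= 3 values per side).
#' @param alpha flagging level.
#' @return data.frame with `feature`, `D`, `p`, `flagged`.
#' @export
ks_screen <- function(train_features, test_features, alpha = 0.05) {
  common <- intersect(names(train_features), names(test_features))
  common <- common[vapply(common, function(cn) {
    is.numeric(train_features[[cn]]) && is.numeric(test_features[[cn]])
  }, logical(1))]
  if (!length(common)) stop("no shared numeric feature columns")
  rows <- lapply(common, function(cn) {
    a <- train_features[[cn]]; b <- test_features[[cn]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 3 || length(b) < 3) {
      stop("need at least 3 finite values per side for feature ", cn)
    }
    if (sd(a) == 0 && sd(b) == 0 && a[1] == b[1]) {
      warning("feature ", cn, " constant on both sides; D = 0")
      return(data.frame(feature = cn, D = 0, p = 1))
    }
    kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
    data.frame(feature = cn, D = unname(kt$statistic), p = kt$p.value)
  })
  out <- do.call(rbind, rows)
  out$flagged <- out$p < alpha
  out
}

#' Normalized mutual information between paired feature sources
#'
#' For each feature, both sources are discretized into equal-frequency bins
#' (rank-based, so any monotone transform of one source leaves the value
#' unchanged) and `I(A;B) / sqrt(H(A) H(B))` is computed on the joint
#' sample. The aggregate is the mean over features. Symmetric in its
#' arguments; identical paired values give exactly 1.
#'
#' @param features_a,features_b data.frames (or numeric vectors) paired row
#'   by row (same subjects, two collection sources).
#' @param bins number of equal-frequency bins (reduced with a warning when
#'   there are fewer subjects than bins).
#' @return List with `per_feature` (named numeric) and `aggregate`.
#' @export
nmi_paired <- function(features_a, features_b, bins = 8) {
  if (is.numeric(features_a)) features_a <- data.frame(x = features_a)
  if (is.numeric(features_b)) features_b <- data.frame(x = features_b)
  stopifnot(nrow(features_a) == nrow(features_b))
  common <- intersect(names(features_a), names(features_b))
  n <- nrow(features_a)
  if (bins < 2) stop("bins must be >= 2")
  if (n < bins) {
    warning("fewer subjects than bins; reducing bin count to ", max(2, n %/% 2))
    bins <- max(2, n %/% 2)
  }
  vals <- vapply(common, function(cn) {
    nmi_binned(features_a[[cn]], features_b[[cn]], bins)
  }, numeric(1))
  list(per_feature = vals, aggregate = mean(vals))
}

nmi_binned <- function(a, b, bins) {
  n <- length(a)
  bin_of <- function(v) {
    r <- rank(v, ties.method = "average")
    pmin(pmax(ceiling(bins * (r - 0.5) / n), 1L), bins)
  }
  ia <- bin_of(a); ib <- bin_of(b)
  joint <- tabulate(ia + bins * (ib - 1L), nbins = bins * bins) / n
  pa <- tabulate(ia, bins) / n
  pb <- tabulate(ib, bins) / n
  Ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  Hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  pij <- matrix(joint, bins, bins)
  denom <- outer(pa, pb)
  nz <- pij > 0 & denom > 0
  I <- sum(pij[nz] * log(pij[nz] / denom[nz]))
  if (Ha <= 0 || Hb <= 0) return(1)  # degenerate single-bin margins
  min(1, I / sqrt(Ha * Hb))
}

#' Effective degrees of freedom from a correlation-dimension bound
#'
#' The number of candidate model degrees of freedom is taken as twice the
#' correlation-dimension upper bound, rounded up — the delay-embedding
#' doubling that maps a bound of 2.5 to 5 effective degrees of freedom.
#'
#' @param dcorr_bound positive upper bound on the correlation dimension.
#' @return Integer degrees of freedom.
#' @export
effective_df <- function(dcorr_bound) {
  if (!is.numeric(dcorr_bound) || dcorr_bound <= 0) {
    stop("dcorr_bound must be > 0")
  }
  as.integer(ceiling(2 * dcorr_bound))
}

#' Minimum outcome events under the events-per-variable rule
#'
#' Logistic-regression sample-size heuristic: at least `epv` outcome events
#' per candidate degree of freedom.
#'
#' @param df degrees of freedom (>= 1).
#' @param epv events per degree of freedom (>= 1, conventionally 10).
#' @return Integer minimum number of training-set outcome events.
#' @export
peduzzi_min_events <- function(df, epv = 10) {
  if (df < 1 || epv < 1) stop("df and epv must be >= 1")
  as.integer(df) * as.integer(epv)
}

#' Enrollment target from the sample-size plan
#'
#' @param min_events_train minimum training-set events per condition.
#' @param extra_test_per_condition additional test-set subjects per
#'   condition.
#' @param n_groups number of outcome groups enrolled.
#' @param dcorr_bound,epv recorded plan inputs (defaults 2.5 and 10).
#' @return A `sample_size_plan` list with `dcorr_bound`, `effective_df`,
#'   `epv`, `min_events_train`, `extra_test_per_condition`,
#'   `per_condition_total`, `n_groups`, `enrollment_target`.
#' @export
enrollment_target <- function(min_events_train, extra_test_per_condition = 15,
                              n_groups = 4, dcorr_bound = 2.5, epv = 10) {
  if (min_events_train < 0 || extra_test_per_condition < 0 || n_groups < 0) {
    stop("all plan inputs must be >= 0")
  }
  per_condition <- min_events_train + extra_test_per_condition
  structure(list(dcorr_bound = dcorr_bound,
                 effective_df = effective_df(dcorr_bound),
                 epv = epv,
                 min_events_train = as.integer(min_events_train),
                 extra_test_per_condition = as.integer(extra_test_per_condition),
                 per_condition_total = as.integer(per_condition),
                 n_groups = as.integer(n_groups),
                 enrollment_target = as.integer(n_groups * per_condition)),
            class = "sample_size_plan")
}
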