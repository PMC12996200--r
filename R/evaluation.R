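#' Confusion counts at a decision threshold
#'
#' Prediction is positive when `score >= threshold` (boundary scores count
#' positive).
#'
#' @param scores numeric scores.
#' @param labels binary outcome (0/1 or logical).
#' @param threshold decision cut.
#' @return List of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at_threshold <- function(scores, labels, threshold) {
  if (!length(scores)) stop("empty input")
  y <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(y))
  pred <- scores >= threshold
  confusion_counts(tp = sum(pred & y == 1), fp = sum(pred & y == 0),
                   tn = sum(!pred & y == 0), fn = sum(!pred & y == 1))
}

#' @rdname confusion_at_threshold
#' @param tp,fp,tn,fn nonnegative integer counts.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn)),
            class = "confusion_counts")
}

#' Diagnostic metrics from confusion counts
#'
#' Exact rational arithmetic followed by 3-decimal rounding, half away from
#' zero — the convention that reproduces printed diagnostic tables (e.g.
#' 32/39 reported as 0.821). Ratios with zero denominators are returned as
#' `NaN` with a warning.
#'
#' @param counts a `confusion_counts` (or list with tp/fp/tn/fn).
#' @return List with `sensitivity`, `specificity`, `accuracy`, `ppv`, `npv`.
#' @export
metrics_from_confusion <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  n <- tp + fp + tn + fn
  if (n == 0) stop("all-zero counts")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)")
      return(NaN)
    }
    num / den
  }
  list(sensitivity = round_half_away(safe_div(tp, tp + fn, "sensitivity")),
       specificity = round_half_away(safe_div(tn, tn + fp, "specificity")),
       accuracy = round_half_away((tp + tn) / n),
       ppv = round_half_away(safe_div(tp, tp + fp, "ppv")),
       npv = round_half_away(safe_div(tn, tn + fn, "npv")))
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation, equivalent to the trapezoidal area over
#' the empirical ROC with half credit for ties.
#'
#' @param scores numeric scores.
#' @param labels binary outcome; both classes must be present.
#' @return Numeric in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("labels contain a single class")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train-to-test AUC drop-off in percentage points
#'
#' @param train_auc,test_auc AUCs in `[0, 1]`.
#' @return `100 * (train_auc - test_auc)` rounded to 1 decimal.
#' @export
auc_dropoff <- function(train_auc, test_auc) {
  stopifnot(train_auc >= 0, train_auc <= 1, test_auc >= 0, test_auc <= 1)
  round_half_away(100 * (train_auc - test_auc), digits = 1)
}

#' Evaluate a frozen model on a tagged subject set
#'
#' Applies the predictor spec and fitted model to the rows (no refitting),
#' computes confusion counts at the model's stored threshold, the rounded
#' metrics, and the AUC.
#'
#' @param model a `fitted_model` with a finite `threshold`.
#' @param spec the `predictor_spec` used to build the model.
#' @param feature_rows feature data.frame for the evaluated subjects.
#' @param labels binary outcome for the same rows.
#' @param set_name one of `"tuning"`, `"train_holdout"`, `"train"`,
#'   `"test"`.
#' @return An `evaluation_report`: list with `set_name`, `n`, `counts`,
#'   `sensitivity`, `specificity`, `accuracy`, `auc`.
#' @export
evaluate_model <- function(model, spec, feature_rows, labels,
                           set_name = c("test", "train", "tuning",
                                        "train_holdout")) {
  set_name <- match.arg(set_name)
  y <- as.integer(as.logical(labels))
  if (nrow(feature_rows) != length(y)) stop("label/row mismatch")
  P <- apply_predictors(spec, feature_rows)
  scores <- predict_scores(model, P)
  counts <- confusion_at_threshold(scores, y, model$threshold)
  m <- metrics_from_confusion(counts)
  structure(list(set_name = set_name, n = length(y), counts = counts,
                 sensitivity = m$sensitivity, specificity = m$specificity,
                 accuracy = m$accuracy, auc = roc_auc(scores, y)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> %s set  n=%d  TP=%d FP=%d TN=%d FN=%d\n",
    x$set_name, x$n, x$counts$tp, x$counts$fp, x$counts$tn, x$counts$fn))
  cat(sprintf("  sensitivity %.3f  specificity %.3f  accuracy %.3f  AUC %.3f\n",
              x$sensitivity, x$specificity, x$accuracy, x$auc))
  invisible(x)
}
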