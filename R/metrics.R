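check_scores_labels <- function(scores, labels, need_both_classes = FALSE) {
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (need_both_classes && length(unique(labels)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  invisible(TRUE)
}

#' Confusion counts at a classification threshold
#'
#' A sample is predicted positive when its score is greater than or equal
#' to the threshold (ties count as positive).
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 true labels, same length.
#' @param threshold Classification threshold (default 0.5).
#' @return A one-row tibble `tp`, `fp`, `tn`, `fn`; the four counts
#'   partition the samples.
#' @export
confusion_at_threshold <- function(scores, labels, threshold = 0.5) {
  check_scores_labels(scores, labels)
  pred <- scores >= threshold
  tibble::tibble(
    tp = sum(pred & labels == 1),
    fp = sum(pred & labels == 0),
    tn = sum(!pred & labels == 0),
    fn = sum(!pred & labels == 1)
  )
}

#' Precision, recall and F-score from confusion counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F = 2PR/(P+R)`. A zero denominator yields 0 with a warning rather than
#' NaN.
#'
#' @param counts A one-row tibble or named list with `tp`, `fp`, `tn`, `fn`.
#' @return A one-row tibble `precision`, `recall`, `f_score`.
#' @export
precision_recall_f <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  safe_ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); returning 0", call. = FALSE)
      return(0)
    }
    num / den
  }
  precision <- safe_ratio(tp, tp + fp, "precision")
  recall <- safe_ratio(tp, tp + fn, "recall")
  f_score <- if (precision + recall == 0) {
    warning("F-score undefined (zero denominator); returning 0", call. = FALSE)
    0
  } else 2 * precision * recall / (precision + recall)
  tibble::tibble(precision = precision, recall = recall, f_score = f_score)
}

#' ROC curve points
#'
#' One point per distinct threshold: a sentinel above every score (the
#' (0,0) anchor) followed by each distinct score in descending order; the
#' final point, at the minimum score, is (1,1) since ties count positive.
#' Both coordinates are non-decreasing along the curve.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 true labels; both classes must be present.
#' @return A tibble `threshold`, `fpr`, `tpr` (threshold `Inf` for the
#'   anchor point).
#' @export
roc_points <- function(scores, labels) {
  check_scores_labels(scores, labels, need_both_classes = TRUE)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  cum_tp <- cumsum(l == 1)
  cum_fp <- cumsum(l == 0)
  last <- !duplicated(s, fromLast = TRUE) # last index of each distinct score
  tibble::tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, cum_fp[last] / n_neg),
    tpr = c(0, cum_tp[last] / n_pos)
  )
}

#' Area under the ROC curve
#'
#' Trapezoidal area under [roc_points()]. Equals the concordance
#' probability that a random positive outscores a random negative, with
#' tied positive-negative pairs counting one half.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 true labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  roc <- roc_points(scores, labels)
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Evaluate scored test pairs
#'
#' Computes the full evaluation report: AUC with its ROC curve, and
#' precision/recall/F at the given classification threshold.
#'
#' @param scores Numeric prediction scores (probabilities).
#' @param labels 0/1 true labels; both classes must be present.
#' @param threshold Threshold for the confusion-based metrics (default 0.5).
#' @return An `adr_eval`: list with `auc`, `roc` (tibble of points),
#'   `precision`, `recall`, `f_score`, `threshold`, `confusion` and the
#'   test-set size `n`.
#' @export
evaluate_predictions <- function(scores, labels, threshold = 0.5) {
  check_scores_labels(scores, labels, need_both_classes = TRUE)
  roc <- roc_points(scores, labels)
  a <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  counts <- confusion_at_threshold(scores, labels, threshold)
  prf <- precision_recall_f(counts)
  structure(
    list(auc = a, roc = roc, precision = prf$precision, recall = prf$recall,
         f_score = prf$f_score, threshold = threshold, confusion = counts,
         n = length(scores)),
    class = "adr_eval"
  )
}

#' @export
print.adr_eval <- function(x, ...) {
  cat(sprintf(
    "<adr_eval> n = %d | AUC %.3f | precision %.3f recall %.3f F %.3f (threshold %.2f)\n",
    x$n, x$auc, x$precision, x$recall, x$f_score, x$threshold))
  invisible(x)
}

#' Tidy the ROC curve of an evaluation
#'
#' @param x An `adr_eval`.
#' @param ... Unused.
#' @return The tibble of ROC points (`threshold`, `fpr`, `tpr`).
#' @export
tidy.adr_eval <- function(x, ...) x$roc

#' One-row evaluation summary
#'
#' @param x An `adr_eval`.
#' @param ... Unused.
#' @return A tibble `auc`, `precision`, `recall`, `f_score`, `threshold`,
#'   `n`.
#' @export
glance.adr_eval <- function(x, ...) {
  tibble::tibble(auc = x$auc, precision = x$precision, recall = x$recall,
                 f_score = x$f_score, threshold = x$threshold, n = x$n)
}

#' Plot the ROC curve of an evaluation
#'
#' @param object An `adr_eval`.
#' @param ... Unused.
#' @return A ggplot of the ROC staircase with the chance diagonal.
#' @export
autoplot.adr_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("ROC (AUC = %.3f, n = %d)", object$auc, object$n)
    )
}

#' Write an evaluation report to disk
#'
#' The scalar metrics go to a JSON file; the ROC points optionally to a
#' CSV.
#'
#' @param report An `adr_eval`.
#' @param path Output JSON path.
#' @param roc_path Optional CSV path for the ROC points.
#' @return `path`, invisibly.
#' @export
eval_write <- function(report, path, roc_path = NULL) {
  stopifnot(inherits(report, "adr_eval"))
  jsonlite::write_json(
    list(auc = report$auc, precision = report$precision,
         recall = report$recall, f_score = report$f_score,
         threshold = report$threshold, n = report$n),
    path, auto_unbox = TRUE, digits = NA
  )
  if (!is.null(roc_path)) {
    readr::write_csv(report$roc, roc_path, progress = FALSE)
  }
  invisible(path)
}
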