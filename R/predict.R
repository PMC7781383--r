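# Nearest-zero z-score classification, confusion-matrix metrics, and ROC.

#' Classify predicted scores with the nearest-zero z rule
#'
#' For each score, `z_c = (score - mean_c) / sd_c` is computed against the
#' training-score statistics of each class; the call is the class whose
#' |z| is smaller.  An exact tie — a probability-zero event in continuous
#' data — goes to `pos`: a screening test prefers sensitivity.
#'
#' @param score Numeric vector of component-1 predicted values (a score
#'   matrix is reduced to its first column).
#' @param class_stats data.frame with rows `neg`, `pos` and columns
#'   `mean`, `sd` (as stored in an `aptamer_splsda` model); both SDs must
#'   be positive.
#' @return data.frame of class `prediction_outcome`: `score`, `z_neg`,
#'   `z_pos`, `call` (factor `neg`/`pos`).
#' @export
#' @examples
#' cs <- data.frame(class = c("neg", "pos"), mean = c(-4.76, 3.53),
#'                  sd = c(1, 1), row.names = c("neg", "pos"))
#' classify_nearest_zero(3.0, cs)$call  # pos: |z_pos| = 0.53 < |z_neg|
classify_nearest_zero <- function(score, class_stats) {
  if (is.matrix(score)) score <- score[, 1]
  stopifnot(is.numeric(score))
  cs <- class_stats
  if (!all(class_levels %in% rownames(cs)))
    stop("class_stats must have rows 'neg' and 'pos'", call. = FALSE)
  if (any(!is.finite(cs[class_levels, "sd"])) ||
      any(cs[class_levels, "sd"] <= 0))
    stop("degenerate training class: both class SDs must be > 0",
         call. = FALSE)
  z_neg <- (score - cs["neg", "mean"]) / cs["neg", "sd"]
  z_pos <- (score - cs["pos", "mean"]) / cs["pos", "sd"]
  call <- ifelse(abs(z_pos) <= abs(z_neg), "pos", "neg")
  out <- data.frame(score = score, z_neg = z_neg, z_pos = z_pos,
                    call = factor(call, levels = class_levels))
  if (!is.null(names(score))) out$sample_id <- names(score)
  class(out) <- c("prediction_outcome", "data.frame")
  out
}

#' Confusion matrix and binary metrics
#'
#' Counts true/false positives and negatives (positive = amyloid-positive
#' class) and the derived metrics: sensitivity `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)`, accuracy `(tp+tn)/n`.
#'
#' @param calls Predicted classes (`"neg"`/`"pos"`, factor or character,
#'   or a `prediction_outcome`).
#' @param truth True classes, aligned with `calls`; both classes must be
#'   present.
#' @return Object of class `confusion_matrix`: `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `accuracy`, `table`.
#' @export
#' @examples
#' truth <- rep(c("neg", "pos"), c(8, 7))
#' calls <- c(rep("neg", 6), "pos", "pos", "neg", rep("pos", 6))
#' evaluate_predictions(calls, truth)
evaluate_predictions <- function(calls, truth) {
  if (inherits(calls, "prediction_outcome")) calls <- calls$call
  calls <- as_class_factor(calls, "calls")
  truth <- as_class_factor(truth, "truth")
  if (length(calls) == 0L) stop("empty input", call. = FALSE)
  if (length(calls) != length(truth))
    stop("calls and truth must have equal length", call. = FALSE)
  if (length(unique(truth)) < 2L)
    stop("both classes must be present in truth", call. = FALSE)
  tp <- sum(calls == "pos" & truth == "pos")
  fp <- sum(calls == "pos" & truth == "neg")
  tn <- sum(calls == "neg" & truth == "neg")
  fn <- sum(calls == "neg" & truth == "pos")
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 accuracy = (tp + tn) / length(calls),
                 table = table(truth = truth, call = calls)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion matrix (rows = truth, cols = call):\n")
  print(x$table)
  cat(sprintf("sensitivity %.3f | specificity %.3f | accuracy %.3f\n",
              x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps a threshold over the unique scores (higher score = more
#' positive, per the model's sign convention), computing one
#' (false-positive-rate, true-positive-rate) point per threshold, and the
#' area under the curve by the trapezoidal rule.
#'
#' @param scores Numeric scores.
#' @param truth True classes (`"neg"`/`"pos"`), both present.
#' @return List of class `roc_result`: `points` (data.frame `threshold`,
#'   `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(scores, truth) {
  stopifnot(is.numeric(scores))
  truth <- as_class_factor(truth, "truth")
  if (length(unique(truth)) < 2L)
    stop("both classes must be present in truth", call. = FALSE)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  n_pos <- sum(truth == "pos")
  n_neg <- sum(truth == "neg")
  tpr <- vapply(thr, function(t) sum(scores >= t & truth == "pos") / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & truth == "neg") / n_neg, 0)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: %d thresholds, AUC = %.3f\n",
              nrow(x$points) - 2L, x$auc))
  invisible(x)
}
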