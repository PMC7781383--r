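# Repeated hold-out cross-validation of the full modelling chain:
# split -> fit standardizer on train -> apply to test -> sparse PLS-DA ->
# nearest-zero classification -> confusion matrix.

#' Repeated hold-out cross-validation
#'
#' Draws `n_repeats` random train/test splits (default 54 training and 15
#' test samples).  Per repeat the standardizer and the sparse PLS-DA
#' model are fitted on the training split only; the training means and
#' SDs standardize the test split, which is then classified with the
#' nearest-zero z rule against the training-score class statistics.
#' Splits are plain random draws; a split leaving one class empty in the
#' training (or test) set is redrawn with a warning.
#'
#' @param fm Raw (unstandardised) [feature_matrix()].
#' @param labels Class labels aligned with the rows of `fm`.
#' @param n_repeats Number of random splits (default 5).
#' @param n_train,n_test Split sizes (default 54/15;
#'   `n_train + n_test <= n`).
#' @param keepX Variables kept per component (`NULL` = all).
#' @param n_components Latent components (default 1).
#' @param loading_cutoff Optional absolute-loading filter applied to each
#'   fitted model before prediction (e.g. 0.04).
#' @param seed Integer seed driving every split.
#' @param max_redraw Redraw limit for degenerate splits.
#' @return Object of class `cv_report`: per-repeat `confusion` list and
#'   `metrics` data.frame, the mean sensitivity/specificity/accuracy,
#'   and the seed.
#' @export
cross_validate <- function(fm, labels, n_repeats = 5L, n_train = 54L,
                           n_test = 15L, keepX = NULL, n_components = 1L,
                           loading_cutoff = NULL, seed = 1L,
                           max_redraw = 100L) {
  stopifnot(inherits(fm, "feature_matrix"))
  labels <- as_class_factor(labels, "labels")
  n <- nrow(fm$values)
  if (length(labels) != n)
    stop("labels must align with the rows of fm", call. = FALSE)
  n_train <- as.integer(n_train)
  n_test <- as.integer(n_test)
  if (n_train < 2L || n_test < 1L || n_train + n_test > n)
    stop(sprintf("impossible split sizes: n_train=%d, n_test=%d, n=%d",
                 n_train, n_test, n), call. = FALSE)
  folds <- vector("list", n_repeats)
  metrics <- data.frame(repeat_id = seq_len(n_repeats), sensitivity = NA_real_,
                        specificity = NA_real_, accuracy = NA_real_)
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(n_repeats)) {
      for (attempt in seq_len(max_redraw)) {
        idx <- sample.int(n)
        tr <- idx[seq_len(n_train)]
        te <- idx[n_train + seq_len(n_test)]
        ok <- length(unique(labels[tr])) == 2L &&
          length(unique(labels[te])) == 2L
        if (ok) break
        warning(sprintf("repeat %d: single-class split redrawn", r),
                call. = FALSE)
      }
      if (!ok)
        stop(sprintf("repeat %d: no two-class split found in %d draws",
                     r, max_redraw), call. = FALSE)
      fmtr <- fit_standardizer(fm_rows(fm, tr))
      fmte <- apply_standardizer(fm_rows(fm, te), fmtr)
      model <- splsda_fit(fmtr$values, labels[tr],
                          n_components = n_components,
                          keepX = keepX %||% ncol(fmtr$values))
      if (!is.null(loading_cutoff))
        model <- filter_by_loading(model, loading_cutoff)
      sc <- predict_scores(model, fmte)[, 1]
      out <- classify_nearest_zero(sc, model$class_stats)
      cm <- evaluate_predictions(out$call, labels[te])
      folds[[r]] <- cm
      metrics[r, c("sensitivity", "specificity", "accuracy")] <-
        c(cm$sensitivity, cm$specificity, cm$accuracy)
    }
  })
  structure(list(n_repeats = n_repeats,
                 confusion = folds,
                 metrics = metrics,
                 mean_sensitivity = mean(metrics$sensitivity),
                 mean_specificity = mean(metrics$specificity),
                 mean_accuracy = mean(metrics$accuracy),
                 n_train = n_train, n_test = n_test,
                 seed = as.integer(seed)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("repeated hold-out CV: %d repeats of %d train / %d test\n",
              x$n_repeats, x$n_train, x$n_test))
  print(x$metrics, row.names = FALSE)
  cat(sprintf("means: sensitivity %.3f | specificity %.3f | accuracy %.3f\n",
              x$mean_sensitivity, x$mean_specificity, x$mean_accuracy))
  invisible(x)
}
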