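# Sparse partial least squares discriminant analysis, written from
# scratch: NIPALS with soft-thresholded X-loadings (keepX variables per
# component), a centred -1/+1 class response, and the loading-cutoff
# filter used to prune the final model.

#' Soft-threshold a weight vector to a fixed support size
#'
#' Keeps the `keep` entries of largest magnitude (stable first-index
#' tie-break), shrinks them towards zero by `lambda` — the largest |v|
#' outside the kept support (0 when `keep = length(v)`) — zeroes the
#' rest, and rescales to unit Euclidean norm.  With distinct |v| this
#' yields exactly `keep` nonzeros; exact ties at the boundary shrink to
#' zero, so the nonzero count can fall below `keep` (if the entire kept
#' support ties away, the selected entries are retained unshrunk).
#'
#' @param v Numeric vector, not all zero.
#' @param keep Number of entries to retain, `1 <= keep <= length(v)`.
#' @return Unit-norm numeric vector with the sparsity pattern above.
#' @export
#' @examples
#' soft_threshold_keep(c(0.9, 0.5, 0.1), 2)  # proportional to (0.8, 0.4, 0)
soft_threshold_keep <- function(v, keep) {
  stopifnot(is.numeric(v), length(v) >= 1L)
  keep <- as.integer(keep)
  if (keep < 1L || keep > length(v))
    stop("keep must lie in 1..length(v)", call. = FALSE)
  if (all(v == 0)) stop("cannot threshold an all-zero vector", call. = FALSE)
  av <- abs(v)
  ord <- order(av, decreasing = TRUE)    # stable: ties broken by first index
  sel <- ord[seq_len(keep)]
  lambda <- if (keep < length(v)) max(av[-sel]) else 0
  w <- numeric(length(v))
  w[sel] <- sign(v[sel]) * pmax(av[sel] - lambda, 0)
  if (all(w == 0)) w[sel] <- v[sel]      # total tie: keep support unshrunk
  w / sqrt(sum(w^2))
}

#' Fit a sparse PLS-DA model
#'
#' The two-level class factor is coded as a centred -1/+1 column Y.  Per
#' component, NIPALS iterates `u = soft_threshold_keep(X' y_score, keepX)`
#' (unit norm), `t = X u`, with Y-side regression, to convergence
#' (`tol`, `max_iter`); X and Y are then deflated by regression on `t`.
#' For one component with this Y coding the solution is closed form, but
#' NIPALS is kept for multi-component generality.  The component-1
#' loading sign is fixed so the positive-class training-score mean
#' exceeds the negative-class mean.  Per-class mean and SD of the
#' component-1 training scores are stored for the nearest-zero decision
#' rule.
#'
#' @param X Standardized numeric matrix (samples x features) with
#'   dimnames, e.g. `$values` of a standardized [feature_matrix()].
#' @param y Class labels (`"neg"`/`"pos"`), both classes present.
#' @param n_components Number of latent components (default 1).
#' @param keepX Number of variables retained per component; `NULL` means
#'   all (dense fit); values above `p` are clamped with a warning.
#'   Recycled across components.
#' @param tol,max_iter NIPALS convergence control.
#' @return Object of class `aptamer_splsda`: loadings (`p x K`),
#'   projection loadings, y-loadings, training `scores`, `keepX`,
#'   `class_stats` (per-class mean/SD of component-1 scores),
#'   `feature_names`, and the training data (`X`, `y`) used by
#'   [filter_by_loading()].
#' @export
splsda_fit <- function(X, y, n_components = 1L, keepX = NULL,
                       tol = 1e-9, max_iter = 500L) {
  if (inherits(X, "feature_matrix")) X <- X$values
  stopifnot(is.matrix(X), is.numeric(X))
  if (is.null(colnames(X)))
    colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  y <- as_class_factor(y, "y")
  if (length(y) != nrow(X))
    stop("length(y) must equal nrow(X)", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("both classes must be present in y", call. = FALSE)
  p <- ncol(X)
  K <- as.integer(n_components)
  if (is.null(keepX)) keepX <- p
  keepX <- as.integer(rep_len(keepX, K))
  if (any(keepX > p)) {
    warning(sprintf("keepX clamped to the number of features (%d)", p),
            call. = FALSE)
    keepX <- pmin(keepX, p)
  }
  if (any(keepX < 1L)) stop("keepX must be >= 1", call. = FALSE)

  ynum <- ifelse(y == "pos", 1, -1)
  Y <- matrix(ynum - mean(ynum), ncol = 1)
  Xd <- X
  Yd <- Y
  U <- matrix(0, p, K, dimnames = list(colnames(X), NULL))
  P <- matrix(0, p, K, dimnames = list(colnames(X), NULL))
  Tm <- matrix(0, nrow(X), K, dimnames = list(rownames(X), NULL))
  qv <- numeric(K)
  for (h in seq_len(K)) {
    yscore <- Yd[, 1]
    u <- rep(0, p)
    for (it in seq_len(max_iter)) {
      u_raw <- drop(crossprod(Xd, yscore))
      if (all(u_raw == 0))
        stop("X carries no covariance with the class indicator ",
             sprintf("(component %d)", h), call. = FALSE)
      u_new <- soft_threshold_keep(u_raw, keepX[h])
      t <- drop(Xd %*% u_new)
      q <- drop(crossprod(Yd, t)) / sum(t^2)
      yscore <- drop(Yd %*% q) / sum(q^2)
      if (sqrt(sum((u_new - u)^2)) < tol) { u <- u_new; break }
      u <- u_new
    }
    t <- drop(Xd %*% u)
    pl <- drop(crossprod(Xd, t)) / sum(t^2)
    q <- drop(crossprod(Yd, t)) / sum(t^2)
    U[, h] <- u
    P[, h] <- pl
    Tm[, h] <- t
    qv[h] <- q
    Xd <- Xd - tcrossprod(t, pl)
    Yd <- Yd - t %*% t(q)
  }
  # sign convention: positive class scores on the positive side (comp 1)
  if (mean(Tm[y == "pos", 1]) < mean(Tm[y == "neg", 1])) {
    U[, 1] <- -U[, 1]
    P[, 1] <- -P[, 1]
    Tm[, 1] <- -Tm[, 1]
    qv[1] <- -qv[1]
  }
  model <- structure(list(
    n_components = K,
    keepX = keepX,
    x_loadings = U,
    x_projection = P,
    y_loadings = qv,
    scores = Tm,
    feature_names = colnames(X),
    class_stats = score_class_stats(Tm[, 1], y),
    X = X, y = y), class = "aptamer_splsda")
  model
}

#' @noRd
score_class_stats <- function(score, y) {
  data.frame(class = class_levels,
             mean = vapply(class_levels,
                           function(c) mean(score[y == c]), 0),
             sd = vapply(class_levels,
                         function(c) sd(score[y == c]), 0),
             row.names = class_levels, stringsAsFactors = FALSE)
}

#' @export
print.aptamer_splsda <- function(x, ...) {
  nz <- colSums(x$x_loadings != 0)
  cat(sprintf("sparse PLS-DA model: %d component(s), %d features\n",
              x$n_components, length(x$feature_names)))
  cat(sprintf("  nonzero loadings per component: %s\n",
              paste(nz, collapse = ", ")))
  cat(sprintf("  training scores (comp 1): neg %.3f +/- %.3f, pos %.3f +/- %.3f\n",
              x$class_stats["neg", "mean"], x$class_stats["neg", "sd"],
              x$class_stats["pos", "mean"], x$class_stats["pos", "sd"]))
  invisible(x)
}

#' Predict latent scores for new samples
#'
#' Component-1 predicted value is `X_new %*% u_1`; further components use
#' the same deflation chain as training (`X` deflated by the projection
#' loadings).  `X_new` must be standardized with the model's training
#' parameters; features are aligned by name.
#'
#' @param model An `aptamer_splsda` model.
#' @param X_new Standardized matrix or standardized [feature_matrix()].
#' @return Numeric matrix (samples x components) of predicted scores.
#' @export
predict_scores <- function(model, X_new) {
  stopifnot(inherits(model, "aptamer_splsda"))
  if (inherits(X_new, "feature_matrix")) X_new <- X_new$values
  stopifnot(is.matrix(X_new))
  missing <- setdiff(model$feature_names, colnames(X_new))
  if (length(missing) > 0)
    stop("features required by the model are absent: ",
         paste(missing, collapse = ", "), call. = FALSE)
  Xd <- X_new[, model$feature_names, drop = FALSE]
  K <- model$n_components
  Tm <- matrix(0, nrow(Xd), K, dimnames = list(rownames(Xd), NULL))
  for (h in seq_len(K)) {
    t <- drop(Xd %*% model$x_loadings[, h])
    Tm[, h] <- t
    Xd <- Xd - tcrossprod(t, model$x_projection[, h])
  }
  Tm
}

#' Filter a fitted model by a loading cutoff
#'
#' Zeroes every loading with `|loading| <= cutoff`, renormalizes each
#' component to unit norm, and recomputes training scores and the
#' per-class score statistics from the stored training data.  The filter
#' is applied to the unit-norm fitted loadings.
#'
#' @param model A fitted `aptamer_splsda` (with training data attached).
#' @param cutoff Absolute-loading cutoff (default 0.04).
#' @return The filtered `aptamer_splsda`; `$n_retained` holds the number
#'   of surviving variables per component.
#' @export
filter_by_loading <- function(model, cutoff = 0.04) {
  stopifnot(inherits(model, "aptamer_splsda"))
  if (is.null(model$X))
    stop("model carries no training data; filtering needs the original fit",
         call. = FALSE)
  U <- model$x_loadings
  U[abs(U) <= cutoff] <- 0
  n_ret <- colSums(U != 0)
  if (any(n_ret == 0L))
    stop(sprintf("cutoff %g removes every variable from component %d",
                 cutoff, which(n_ret == 0L)[1]), call. = FALSE)
  U <- sweep(U, 2, sqrt(colSums(U^2)), "/")
  out <- model
  out$x_loadings <- U
  # rebuild the deflation chain with the filtered directions
  Xd <- model$X
  K <- model$n_components
  P <- model$x_projection
  Tm <- model$scores
  for (h in seq_len(K)) {
    t <- drop(Xd %*% U[, h])
    P[, h] <- drop(crossprod(Xd, t)) / sum(t^2)
    Tm[, h] <- t
    Xd <- Xd - tcrossprod(t, P[, h])
  }
  out$x_projection <- P
  out$scores <- Tm
  out$class_stats <- score_class_stats(Tm[, 1], model$y)
  out$n_retained <- n_ret
  out$loading_cutoff <- cutoff
  out
}

#' Tune keepX by leave-one-out misclassification
#'
#' For each grid value, fits the model on all samples but one
#' (standardizing inside the loop so the left-out sample never leaks into
#' the fit), classifies the left-out sample with the nearest-zero rule,
#' and picks the keepX minimizing the LOO error (ties go to the smaller,
#' i.e. sparser, value).
#'
#' @param fm Raw (unstandardised) [feature_matrix()] or numeric matrix.
#' @param y Class labels.
#' @param grid Candidate keepX values; defaults to
#'   `{10, 25, 50, 100, 250, 500, 961, p}` clamped to `p`.
#' @param n_components Components of each candidate fit.
#' @return List: `keepX` (chosen), `errors` (named LOO error per grid
#'   value), `metrics` (per-grid sensitivity/specificity/accuracy).
#' @export
tune_keepx <- function(fm, y, grid = NULL, n_components = 1L) {
  if (is.matrix(fm)) fm <- feature_matrix(fm)
  p <- ncol(fm$values)
  if (is.null(grid)) grid <- c(10, 25, 50, 100, 250, 500, 961, p)
  grid <- sort(unique(pmin(as.integer(grid), p)))
  grid <- grid[grid >= 1L]
  y <- as_class_factor(y, "y")
  res <- lapply(grid, function(k)
    splsda_loo(fm, y, keepX = k, n_components = n_components))
  err <- vapply(res, function(r) 1 - r$accuracy, 0)
  names(err) <- grid
  metrics <- do.call(rbind, lapply(res, function(r)
    data.frame(sensitivity = r$sensitivity, specificity = r$specificity,
               accuracy = r$accuracy)))
  metrics$keepX <- grid
  list(keepX = grid[which.min(err)], errors = err, metrics = metrics)
}

#' Leave-one-out CV of a sparse PLS-DA fit with the nearest-zero rule
#' @noRd
splsda_loo <- function(fm, y, keepX, n_components = 1L) {
  n <- nrow(fm$values)
  calls <- character(n)
  for (i in seq_len(n)) {
    tr <- fit_standardizer(fm_rows(fm, -i))
    te <- apply_standardizer(fm_rows(fm, i), tr)
    m <- splsda_fit(tr$values, y[-i], n_components = n_components,
                    keepX = min(keepX, ncol(tr$values)))
    sc <- predict_scores(m, te)[, 1]
    calls[i] <- as.character(classify_nearest_zero(sc, m$class_stats)$call)
  }
  cm <- evaluate_predictions(calls, y)
  list(sensitivity = cm$sensitivity, specificity = cm$specificity,
       accuracy = cm$accuracy, calls = calls)
}

#' Serialize a fitted model to JSON
#'
#' Writes loadings, projections, class statistics, keepX and (when
#' available) the feature standardization parameters; enough to predict
#' on new standardized data after [load_model()].
#'
#' @param model An `aptamer_splsda`.
#' @param path Output JSON path.
#' @param standardizer Optional `cq_standardizer` to embed.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, standardizer = NULL) {
  stopifnot(inherits(model, "aptamer_splsda"))
  obj <- list(
    n_components = model$n_components,
    keepX = model$keepX,
    feature_names = model$feature_names,
    x_loadings = unname(as.data.frame(model$x_loadings)),
    x_projection = unname(as.data.frame(model$x_projection)),
    y_loadings = model$y_loadings,
    class_stats = model$class_stats,
    n_retained = model$n_retained,
    loading_cutoff = model$loading_cutoff)
  if (!is.null(standardizer)) {
    stopifnot(inherits(standardizer, "cq_standardizer"))
    obj$standardization <- list(feature = standardizer$feature,
                                mean = unname(standardizer$mean),
                                sd = unname(standardizer$sd),
                                dropped = standardizer$dropped)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model serialized with [save_model()]
#'
#' @param path JSON path.
#' @return An `aptamer_splsda` (without training data; usable for
#'   prediction and classification).  Any embedded standardizer is
#'   attached as `$standardization`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  U <- as.matrix(as.data.frame(obj$x_loadings))
  P <- as.matrix(as.data.frame(obj$x_projection))
  rownames(U) <- rownames(P) <- obj$feature_names
  colnames(U) <- colnames(P) <- NULL
  cs <- as.data.frame(obj$class_stats)
  rownames(cs) <- cs$class
  model <- structure(list(
    n_components = obj$n_components,
    keepX = obj$keepX,
    x_loadings = U,
    x_projection = P,
    y_loadings = obj$y_loadings,
    scores = NULL,
    feature_names = obj$feature_names,
    class_stats = cs,
    n_retained = obj$n_retained,
    loading_cutoff = obj$loading_cutoff,
    X = NULL, y = NULL), class = "aptamer_splsda")
  if (!is.null(obj$standardization)) {
    s <- obj$standardization
    model$standardization <- structure(
      list(feature = s$feature,
           mean = stats::setNames(s$mean, s$feature),
           sd = stats::setNames(s$sd, s$feature),
           dropped = s$dropped %||% character(0)),
      class = "cq_standardizer")
  }
  model
}
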