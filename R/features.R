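# Feature engineering: Cq values plus one-direction pairwise Cq ratios,
# standardised with training-set parameters.

#' Construct a feature matrix object
#'
#' Light container used throughout the modelling stages.
#'
#' @param values Numeric matrix with sample row names and feature column
#'   names.
#' @param standardization Optional `cq_standardizer` already applied.
#' @param dropped Character vector of features dropped (zero variance).
#' @return Object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, standardization = NULL,
                           dropped = character(0)) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry sample row names and feature column names",
         call. = FALSE)
  structure(list(values = values,
                 sample_ids = rownames(values),
                 feature_names = colnames(values),
                 standardization = standardization,
                 dropped_features = dropped),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d samples x %d features (%s; %d dropped)\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$standardization)) "raw" else "standardized",
              length(x$dropped_features)))
  invisible(x)
}

#' @noRd
fm_rows <- function(fm, i) {
  feature_matrix(fm$values[i, , drop = FALSE], fm$standardization,
                 fm$dropped_features)
}

#' Build the combined Cq + pairwise-ratio feature matrix
#'
#' Columns are all Cq values in fixed panel order (lexicographic aptamer
#' id), followed by the ratios `Cq_i / Cq_j` for every ordered pair with
#' `i < j` in panel order — one direction only, so no ratio `B/A` exists
#' when `A/B` does.  For a panel of `p` aptamers with full Cq calls this
#' gives `p + p(p-1)/2` features (990 for p = 44).  A no-call (NA) Cq
#' propagates to every feature involving that aptamer.
#'
#' @param cq Numeric sample-by-aptamer Cq matrix (e.g. from [cq_wide()]),
#'   sample ids as row names.
#' @param na_action What to do with samples carrying missing Cq values:
#'   `"drop"` removes them with a warning (default), `"impute"` replaces
#'   missing Cq with the per-aptamer median before ratios are formed,
#'   `"keep"` propagates NA into the features.
#' @return A raw (unstandardised) [feature_matrix()].
#' @export
#' @examples
#' cq <- matrix(c(20, 10, 22, 11), 2, 2, byrow = TRUE,
#'              dimnames = list(c("s1", "s2"), c("A", "B")))
#' build_features(cq)$values
build_features <- function(cq, na_action = c("drop", "impute", "keep")) {
  na_action <- match.arg(na_action)
  if (is.data.frame(cq)) cq <- as.matrix(cq)
  stopifnot(is.matrix(cq), is.numeric(cq))
  if (nrow(cq) < 2L || ncol(cq) < 1L)
    stop("need >= 2 samples and >= 1 aptamer", call. = FALSE)
  if (is.null(rownames(cq)))
    rownames(cq) <- sprintf("S%03d", seq_len(nrow(cq)))
  if (is.null(colnames(cq)))
    colnames(cq) <- sprintf("APT%02d", seq_len(ncol(cq)))
  cq <- cq[, order(colnames(cq)), drop = FALSE]
  if (anyNA(cq)) {
    if (na_action == "drop") {
      bad <- rownames(cq)[apply(is.na(cq), 1, any)]
      warning(sprintf("dropping %d sample(s) with missing Cq calls: %s",
                      length(bad), paste(bad, collapse = ", ")),
              call. = FALSE)
      cq <- cq[!rownames(cq) %in% bad, , drop = FALSE]
      if (nrow(cq) < 2L)
        stop("fewer than 2 samples remain after dropping missing Cq",
             call. = FALSE)
    } else if (na_action == "impute") {
      for (j in seq_len(ncol(cq))) {
        miss <- is.na(cq[, j])
        if (any(miss)) cq[miss, j] <- median(cq[, j], na.rm = TRUE)
      }
    }
  }
  p <- ncol(cq)
  if (p >= 2L && any(cq[, -1L, drop = FALSE] == 0, na.rm = TRUE))
    stop("Cq of exactly 0 found in a ratio denominator; upstream data corrupt",
         call. = FALSE)
  if (p >= 2L) {
    pair <- combn(p, 2L)
    ratios <- cq[, pair[1L, ], drop = FALSE] / cq[, pair[2L, ], drop = FALSE]
    colnames(ratios) <- paste(colnames(cq)[pair[1L, ]],
                              colnames(cq)[pair[2L, ]], sep = "/")
    values <- cbind(cq, ratios)
  } else {
    values <- cq
  }
  feature_matrix(values)
}

#' Fit a standardizer on a feature matrix
#'
#' Stores the per-feature mean and sample SD (denominator n-1) of the
#' fitting set, transforms the values to zero mean and unit SD, and moves
#' zero-variance features to `dropped_features`.
#'
#' @param fm A raw [feature_matrix()] (no missing values).
#' @return The standardized `feature_matrix`, carrying a
#'   `cq_standardizer` in `$standardization`.
#' @export
fit_standardizer <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  v <- fm$values
  if (nrow(v) < 2L) stop("need >= 2 samples to standardize", call. = FALSE)
  if (anyNA(v))
    stop("feature matrix contains missing values; resolve them in ",
         "build_features(na_action=)", call. = FALSE)
  mu <- colMeans(v)
  s <- apply(v, 2, sd)
  dropped <- colnames(v)[s < 1e-12]
  keep <- setdiff(colnames(v), dropped)
  if (length(keep) == 0L)
    stop("all features have zero variance", call. = FALSE)
  std <- structure(list(feature = keep, mean = mu[keep], sd = s[keep],
                        dropped = dropped), class = "cq_standardizer")
  z <- sweep(sweep(v[, keep, drop = FALSE], 2, std$mean), 2, std$sd, "/")
  feature_matrix(z, standardization = std, dropped = dropped)
}

#' Apply training-set standardization to new samples
#'
#' Transforms new data with the *training* means and SDs; features dropped
#' during training are dropped here too, and the new columns are not
#' recentred on themselves.
#'
#' @param fm_new A raw [feature_matrix()] whose features are a superset of
#'   the trained ones.
#' @param standardizer A `cq_standardizer` (from `$standardization` of a
#'   fitted feature matrix) or a standardized `feature_matrix`.
#' @return Standardized `feature_matrix` for the new samples.
#' @export
apply_standardizer <- function(fm_new, standardizer) {
  if (inherits(standardizer, "feature_matrix"))
    standardizer <- standardizer$standardization
  stopifnot(inherits(standardizer, "cq_standardizer"),
            inherits(fm_new, "feature_matrix"))
  missing <- setdiff(standardizer$feature, fm_new$feature_names)
  if (length(missing) > 0)
    stop("features required by the standardizer are absent: ",
         paste(missing, collapse = ", "), call. = FALSE)
  v <- fm_new$values[, standardizer$feature, drop = FALSE]
  z <- sweep(sweep(v, 2, standardizer$mean), 2, standardizer$sd, "/")
  feature_matrix(z, standardization = standardizer,
                 dropped = standardizer$dropped)
}
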