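# Selection-library NGS analysis: extract the 40-mer random regions
# between the constant flanks, count unique sequences per sample, keep
# the top-N by copy number, and select a candidate aptamer subset by
# sparse PLS-DA on the relative frequencies.

#' Extract 40-mer random regions from a FASTQ library
#'
#' A read is accepted iff the 5' flank matches at its start and the 3'
#' flank at position `nchar(flank5) + 40`, each within `max_mismatch`
#' substitutions; the intervening 40-mer is returned uppercased.  Reads
#' shorter than `flank5 + 40 + flank3`, or whose extracted region
#' contains a non-ACGT character (violating the 40-mer contract), count
#' as length rejections; flank mismatches count separately.  The report
#' always partitions the input:
#' `n_reads == n_extracted + n_rejected_flank + n_rejected_length`.
#'
#' @param fastq Path to a FASTQ file (optionally gzipped).
#' @param flank5,flank3 Constant flank sequences (defaults from
#'   [aptamer_flanks()]).
#' @param max_mismatch Maximum substitutions tolerated per flank
#'   (default 0; sequencing-error tolerance is assay-dependent).
#' @return Object of class `extraction_result`: `sequences` (character
#'   vector of 40-mers, one per accepted read) and `report` (list with
#'   `n_reads`, `n_extracted`, `n_rejected_flank`, `n_rejected_length`).
#' @export
extract_random_regions <- function(fastq,
                                   flank5 = aptamer_flanks()[["flank5"]],
                                   flank3 = aptamer_flanks()[["flank3"]],
                                   max_mismatch = 0L) {
  stopifnot(nchar(flank5) > 0, nchar(flank3) > 0)
  validate_fastq_structure(fastq)
  reads <- tryCatch(
    Biostrings::readDNAStringSet(fastq, format = "fastq"),
    error = function(e) {
      stop(sprintf("unreadable or truncated FASTQ record in '%s': %s",
                   fastq, conditionMessage(e)), call. = FALSE)
    })
  s <- toupper(as.character(reads))
  n <- length(s)
  n5 <- nchar(flank5)
  n3 <- nchar(flank3)
  need <- n5 + 40L + n3
  flank5 <- toupper(flank5)
  flank3 <- toupper(flank3)
  len_ok <- nchar(s) >= need
  mid_ok <- flank_ok <- logical(n)
  if (any(len_ok)) {
    sl <- s[len_ok]
    mm5 <- str_mismatches(substr(sl, 1L, n5), flank5)
    mm3 <- str_mismatches(substr(sl, n5 + 41L, n5 + 40L + n3), flank3)
    flank_ok[len_ok] <- mm5 <= max_mismatch & mm3 <= max_mismatch
    mid_ok[len_ok] <- !grepl("[^ACGT]", substr(sl, n5 + 1L, n5 + 40L))
  }
  accept <- len_ok & flank_ok & mid_ok
  report <- list(
    n_reads = n,
    n_extracted = sum(accept),
    n_rejected_flank = sum(len_ok & !flank_ok),
    n_rejected_length = sum(!len_ok) + sum(len_ok & flank_ok & !mid_ok))
  structure(list(sequences = unname(substr(s[accept], n5 + 1L, n5 + 40L)),
                 report = report),
            class = "extraction_result")
}

#' Structural validation of a FASTQ file (record boundaries)
#'
#' The parser used downstream silently tolerates truncated final records;
#' this pass enforces the 4-line record structure and reports the first
#' malformed record by index.
#' @noRd
validate_fastq_structure <- function(fastq) {
  lines <- readLines(fastq, warn = FALSE)
  n <- length(lines)
  if (n == 0L) stop(sprintf("empty FASTQ file '%s'", fastq), call. = FALSE)
  if (n %% 4L != 0L)
    stop(sprintf("truncated FASTQ record %d in '%s'", n %/% 4L + 1L, fastq),
         call. = FALSE)
  heads <- substr(lines[seq(1L, n, by = 4L)], 1L, 1L)
  seps <- substr(lines[seq(3L, n, by = 4L)], 1L, 1L)
  bad <- which(heads != "@" | seps != "+")
  if (length(bad) > 0)
    stop(sprintf("malformed FASTQ record %d in '%s'", bad[1], fastq),
         call. = FALSE)
  invisible(TRUE)
}

#' Count unique 40-mers across samples
#'
#' Builds the sample-by-sequence count matrix from per-sample extracted
#' 40-mer lists, with per-sample totals and relative frequencies.
#' Relative frequencies are computed against the per-sample total of
#' extracted reads, so each row of `rel_freq` sums to 1 before any
#' truncation.
#'
#' @param extracted Named list (one element per sample) of 40-mer
#'   character vectors, or of `extraction_result` objects.
#' @return Object of class `aptamer_count_matrix`: `sample_ids`,
#'   `sequences`, `counts` (samples x sequences integer matrix),
#'   `totals`, `rel_freq`.
#' @export
count_frequencies <- function(extracted) {
  if (is.null(names(extracted)) || any(names(extracted) == ""))
    stop("extracted must be a named list (one element per sample)",
         call. = FALSE)
  extracted <- lapply(extracted, function(x) {
    if (inherits(x, "extraction_result")) x$sequences else as.character(x)
  })
  empty <- names(extracted)[lengths(extracted) == 0L]
  if (length(empty) > 0)
    stop("sample(s) with zero extracted reads: ",
         paste(empty, collapse = ", "), call. = FALSE)
  seqs <- sort(unique(unlist(extracted, use.names = FALSE)))
  counts <- t(vapply(extracted, function(x)
    tabulate(match(x, seqs), nbins = length(seqs)),
    integer(length(seqs))))
  dimnames(counts) <- list(names(extracted), seqs)
  totals <- lengths(extracted)
  structure(list(sample_ids = names(extracted),
                 sequences = seqs,
                 counts = counts,
                 totals = totals,
                 rel_freq = counts / totals),
            class = "aptamer_count_matrix")
}

#' @export
print.aptamer_count_matrix <- function(x, ...) {
  cat(sprintf("aptamer count matrix: %d samples x %d unique sequences\n",
              length(x$sample_ids), length(x$sequences)))
  invisible(x)
}

#' Keep the top-N sequences by copy number
#'
#' Retains the `n` sequences with the largest counts summed over all
#' samples (all of them when fewer exist); ties are broken
#' lexicographically by sequence.  Relative frequencies are *not*
#' renormalized after truncation, so they remain frequencies among all
#' extracted reads.
#'
#' @param m An `aptamer_count_matrix`.
#' @param n Number of sequences to keep (default 10000, the conventional
#'   screening depth).
#' @return The truncated `aptamer_count_matrix`.
#' @export
top_n_matrix <- function(m, n = 10000L) {
  stopifnot(inherits(m, "aptamer_count_matrix"))
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  sums <- colSums(m$counts)
  ord <- order(-sums, m$sequences)
  keep <- ord[seq_len(min(n, length(ord)))]
  structure(list(sample_ids = m$sample_ids,
                 sequences = m$sequences[keep],
                 counts = m$counts[, keep, drop = FALSE],
                 totals = m$totals,
                 rel_freq = m$rel_freq[, keep, drop = FALSE]),
            class = "aptamer_count_matrix")
}

#' Select candidate aptamers discriminating the two classes
#'
#' Runs sparse PLS-DA on the standardized relative frequencies and
#' returns the variables with nonzero loadings, ordered by |loading|
#' descending.  With `target_perfect_cv` (default), keepX is increased
#' over a grid until leave-one-out sensitivity and specificity both reach
#' 1.0 or the grid is exhausted; otherwise the keepX with the smallest
#' LOO error is used.  The achieved LOO metrics are always reported —
#' this step is known to be unstable (different candidates can emerge
#' from different runs when variables far outnumber samples), so the
#' metrics, not a fixed panel size, are the honest summary.
#'
#' @param m An `aptamer_count_matrix` (typically after [top_n_matrix()]).
#' @param labels Class per sample (`"neg"`/`"pos"`), aligned with
#'   `m$sample_ids`; both classes required.
#' @param target_perfect_cv Stop at the first grid value achieving
#'   perfect LOO sensitivity and specificity (default TRUE).
#' @param keepx_grid Candidate keepX values (default
#'   `{5, 10, 25, 44, 100, 250, 500}` clamped to the number of usable
#'   variables).
#' @param n_components Components of each fit (default 1).
#' @param seed Integer seed, set for reproducibility of any randomized
#'   step (the current procedure is deterministic).
#' @return Object of class `aptamer_selection`: `sequences` (ordered by
#'   |loading|), `loadings` (named, nonzero), `keepX`, `loo`
#'   (sensitivity/specificity/accuracy), and the final `model`.
#' @export
select_candidate_aptamers <- function(m, labels, target_perfect_cv = TRUE,
                                      keepx_grid = NULL, n_components = 1L,
                                      seed = 1L) {
  stopifnot(inherits(m, "aptamer_count_matrix"))
  labels <- as_class_factor(labels, "labels")
  if (length(labels) != length(m$sample_ids))
    stop("labels must align with m$sample_ids", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present among the samples", call. = FALSE)
  X <- m$rel_freq
  fm <- feature_matrix(X)
  fm_std <- fit_standardizer(fm)
  p <- ncol(fm_std$values)
  if (is.null(keepx_grid)) keepx_grid <- c(5, 10, 25, 44, 100, 250, 500)
  grid <- sort(unique(pmin(as.integer(keepx_grid), p)))
  grid <- grid[grid >= 1L]
  withr::with_seed(as.integer(seed), {
    chosen <- NULL
    loo_best <- NULL
    for (k in grid) {
      loo <- splsda_loo(fm, labels, keepX = k,
                        n_components = n_components)
      if (is.null(loo_best) || loo$accuracy > loo_best$accuracy) {
        loo_best <- loo
        chosen <- k
      }
      if (target_perfect_cv &&
          loo$sensitivity == 1 && loo$specificity == 1) {
        chosen <- k
        loo_best <- loo
        break
      }
    }
    model <- splsda_fit(fm_std$values, labels,
                        n_components = n_components, keepX = chosen)
  })
  u <- model$x_loadings[, 1]
  nz <- u[u != 0]
  ord <- order(-abs(nz))
  structure(list(sequences = names(nz)[ord],
                 loadings = nz[ord],
                 keepX = chosen,
                 loo = list(sensitivity = loo_best$sensitivity,
                            specificity = loo_best$specificity,
                            accuracy = loo_best$accuracy),
                 model = model),
            class = "aptamer_selection")
}

#' @export
print.aptamer_selection <- function(x, ...) {
  cat(sprintf("candidate aptamer selection: %d sequences (keepX = %d)\n",
              length(x$sequences), x$keepX))
  cat(sprintf("  LOO CV: sensitivity %.2f | specificity %.2f | accuracy %.2f\n",
              x$loo$sensitivity, x$loo$specificity, x$loo$accuracy))
  invisible(x)
}
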