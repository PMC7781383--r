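# Cq calling and PCR efficiency from raw amplification curves.
#
# The caller uses a derivative-threshold rule: the quantification cycle is
# where the first-difference of fluorescence first exceeds six sample
# standard deviations above the mean derivative over baseline cycles 3-10.

#' First-difference derivative of an amplification curve
#'
#' `d(c) = F(c) - F(c-1)` for cycles `c = 2..n`; the derivative is
#' undefined at cycle 1.  First differences are used rather than central
#' differences so end cycles need no special casing.
#'
#' @param fluorescence Numeric fluorescence vector indexed by cycle (RFU).
#' @return Numeric vector of length `n - 1`, named by cycle (`2..n`),
#'   in RFU/cycle.
#' @export
#' @examples
#' curve_derivative(c(1, 2, 4, 8))  # 1, 2, 4 at cycles 2, 3, 4
curve_derivative <- function(fluorescence) {
  stopifnot(is.numeric(fluorescence), length(fluorescence) >= 2L)
  d <- diff(fluorescence)
  names(d) <- seq_along(d) + 1L
  d
}

#' Call a quantification cycle (Cq) from one amplification curve
#'
#' The threshold is `T = mean(d) + k * sd(d)` over the derivative within
#' the baseline window (sample SD, denominator n-1).  The crossing cycle
#' `c*` is the first cycle strictly after the baseline window with
#' `d(c*) > T`; the fractional Cq linearly interpolates the derivative
#' across `T` between `c* - 1` and `c*`, so `cq` lies in `(c* - 1, c*]`.
#' With `interpolate = FALSE` the integer crossing cycle is returned.
#' If the derivative never exceeds the threshold (including the degenerate
#' flat-curve case with baseline SD 0), the result is a no-call, not an
#' error.
#'
#' @param fluorescence Numeric fluorescence-by-cycle vector (cycle 1..n;
#'   n >= 12 so the baseline window fits).
#' @param baseline_window Integer cycle range (inclusive) over which the
#'   baseline derivative statistics are taken; default cycles 3 to 10.
#' @param k Number of baseline SDs above the baseline mean defining the
#'   threshold (default 6).
#' @param interpolate Fractional Cq by linear interpolation (default), or
#'   the integer crossing cycle.
#' @return A list of class `cq_result`: `cq` (NA on no-call), `called`,
#'   `threshold`, `baseline_mean`, `baseline_sd` (RFU/cycle),
#'   `max_derivative_cycle`, `n_cycles`.
#' @export
#' @examples
#' f <- 100 / (1 + exp(-1.2 * ((1:30) - 20)))
#' call_cq(f)$cq
call_cq <- function(fluorescence, baseline_window = c(3L, 10L), k = 6,
                    interpolate = TRUE) {
  stopifnot(is.numeric(fluorescence), all(is.finite(fluorescence)))
  n <- length(fluorescence)
  if (n < 12L)
    stop("curve must have >= 12 cycles (baseline window 3-10 must fit)",
         call. = FALSE)
  bw <- as.integer(baseline_window)
  if (length(bw) != 2L || bw[1] < 2L || bw[2] >= n || bw[1] >= bw[2])
    stop("baseline_window must lie within cycles 2..(n_cycles - 1)",
         call. = FALSE)
  d <- diff(fluorescence)          # d[i] = derivative at cycle i + 1
  dcycles <- seq_len(n - 1L) + 1L
  base <- d[dcycles >= bw[1] & dcycles <= bw[2]]
  bm <- mean(base)
  bs <- sd(base)
  thr <- bm + k * bs
  max_dc <- dcycles[which.max(d)]
  search <- which(dcycles > bw[2])
  hit <- search[d[search] > thr]
  res <- list(cq = NA_real_, called = FALSE, threshold = thr,
              baseline_mean = bm, baseline_sd = bs,
              max_derivative_cycle = max_dc, n_cycles = n)
  if (length(hit) > 0) {
    i <- hit[1]                    # index into d; cycle is dcycles[i]
    cstar <- dcycles[i]
    if (interpolate) {
      d_prev <- d[i - 1L]
      frac <- (thr - d_prev) / (d[i] - d_prev)
      frac <- min(max(frac, 0), 1)
      res$cq <- (cstar - 1L) + frac
    } else {
      res$cq <- as.numeric(cstar)
    }
    res$called <- TRUE
  }
  structure(res, class = "cq_result")
}

#' PCR efficiency from the exponential phase of a curve
#'
#' Fits a least-squares line to `log10(F(c) - baseline_fluorescence)`
#' over the window from `ceiling(cq)` to the cycle of maximum derivative,
#' and returns `10^slope - 1`, the per-cycle amplification gain (1.0 =
#' perfect doubling).  `baseline_fluorescence` is the mean fluorescence
#' over the baseline window; values <= 0 after subtraction are excluded
#' from the fit.  The log-linear fit is the standard exponential-phase
#' qPCR model; `log_scale = FALSE` instead returns the raw linear slope
#' (RFU/cycle), provided for diagnostics only.  Efficiency is a QC output
#' and never enters the classifier.
#'
#' @param fluorescence Numeric fluorescence-by-cycle vector.
#' @param cq_result A `cq_result` from [call_cq()] on the same curve.
#' @param baseline_window Cycle range for the baseline fluorescence mean.
#' @param log_scale Fit on log10 fluorescence (default TRUE).
#' @param warn Warn when the efficiency falls outside [0, 1.1].
#' @return Scalar efficiency, or NA if the curve was a no-call or fewer
#'   than 2 usable points remain in the window.
#' @export
#' @examples
#' f <- c(rep(0, 10), 2^(1:20))
#' r <- call_cq(f)
#' pcr_efficiency(f, r)  # 1.0: perfect doubling
pcr_efficiency <- function(fluorescence, cq_result,
                           baseline_window = c(3L, 10L),
                           log_scale = TRUE, warn = TRUE) {
  stopifnot(inherits(cq_result, "cq_result"))
  if (!cq_result$called) return(NA_real_)
  w <- seq(ceiling(cq_result$cq), cq_result$max_derivative_cycle)
  if (length(w) < 2L) return(NA_real_)
  bw <- as.integer(baseline_window)
  base_f <- mean(fluorescence[bw[1]:bw[2]])
  y <- fluorescence[w] - base_f
  keep <- y > 0
  if (sum(keep) < 2L) return(NA_real_)
  x <- w[keep]
  yy <- if (log_scale) log10(y[keep]) else y[keep]
  slope <- coef(stats::.lm.fit(cbind(1, x), yy))[2]
  eff <- if (log_scale) 10^slope - 1 else slope
  if (log_scale) {
    if (eff < -1 || eff > 3) eff <- NA_real_
    else if (warn && (eff < 0 || eff > 1.1))
      warning(sprintf("efficiency %.3f outside the expected [0, 1.1] range",
                      eff), call. = FALSE)
  }
  unname(eff)
}

#' Call Cq and efficiency for a table of curves
#'
#' Applies [call_cq()] (and optionally [pcr_efficiency()]) to every
#' (sample, aptamer) curve in a long-format table.
#'
#' @param curves Long data.frame with columns `sample_id`, `aptamer_id`,
#'   `cycle`, `fluorescence`, or an `aptamer_curve_set` from
#'   [simulate_amplification_curves()].
#' @param baseline_window,k,interpolate Passed to [call_cq()].
#' @param efficiency Also compute PCR efficiency (default TRUE).
#' @return data.frame with one row per curve: `sample_id`, `aptamer_id`,
#'   `cq`, `called`, and `efficiency` when requested.
#' @export
call_cq_table <- function(curves, baseline_window = c(3L, 10L), k = 6,
                          interpolate = TRUE, efficiency = TRUE) {
  if (inherits(curves, "aptamer_curve_set")) curves <- curves$curves
  need <- c("sample_id", "aptamer_id", "cycle", "fluorescence")
  if (!all(need %in% names(curves)))
    stop("curves must have columns sample_id, aptamer_id, cycle, fluorescence",
         call. = FALSE)
  key <- paste(curves$sample_id, curves$aptamer_id, sep = "\r")
  ord <- order(key, curves$cycle)
  curves <- curves[ord, ]
  key <- key[ord]
  groups <- split(curves$fluorescence, factor(key, levels = unique(key)))
  out <- lapply(groups, function(f) {
    r <- call_cq(f, baseline_window = baseline_window, k = k,
                 interpolate = interpolate)
    eff <- if (efficiency)
      pcr_efficiency(f, r, baseline_window = baseline_window, warn = FALSE)
    else NA_real_
    c(cq = r$cq, called = as.numeric(r$called), efficiency = eff)
  })
  m <- do.call(rbind, out)
  ids <- do.call(rbind, strsplit(names(groups), "\r", fixed = TRUE))
  res <- data.frame(sample_id = ids[, 1], aptamer_id = ids[, 2],
                    cq = m[, "cq"], called = m[, "called"] > 0,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (efficiency) res$efficiency <- m[, "efficiency"]
  res
}

#' Reshape a long Cq table to a sample-by-aptamer matrix
#'
#' @param cq_table data.frame from [call_cq_table()] (columns `sample_id`,
#'   `aptamer_id`, `cq`).
#' @return Numeric matrix, rows = samples, columns = aptamers
#'   (lexicographic order); no-calls become NA.
#' @export
cq_wide <- function(cq_table) {
  need <- c("sample_id", "aptamer_id", "cq")
  if (!all(need %in% names(cq_table)))
    stop("cq_table must have columns sample_id, aptamer_id, cq",
         call. = FALSE)
  samples <- unique(cq_table$sample_id)
  aptamers <- sort(unique(cq_table$aptamer_id))
  m <- matrix(NA_real_, length(samples), length(aptamers),
              dimnames = list(samples, aptamers))
  m[cbind(match(cq_table$sample_id, samples),
          match(cq_table$aptamer_id, aptamers))] <- cq_table$cq
  m
}
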