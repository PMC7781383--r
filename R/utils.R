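#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count character mismatches against a fixed pattern
#'
#' Vectorised Hamming distance between equal-length strings and a single
#' pattern.  Callers guarantee equal nchar.
#' @noRd
str_mismatches <- function(strs, pattern) {
  pint <- utf8ToInt(pattern)
  vapply(strs, function(s) sum(utf8ToInt(s) != pint), integer(1),
         USE.NAMES = FALSE)
}

#' @noRd
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' @noRd
class_levels <- c("neg", "pos")

#' Coerce a class-label vector to the canonical neg/pos factor
#' @noRd
as_class_factor <- function(x, arg = "labels") {
  if (is.factor(x)) x <- as.character(x)
  bad <- setdiff(unique(x), class_levels)
  if (length(bad) > 0) {
    stop(sprintf("%s must be 'neg' or 'pos'; found: %s", arg,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  factor(x, levels = class_levels)
}
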