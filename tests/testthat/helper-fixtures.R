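# Shared fixtures and independent oracles for the test suite.

# Independent exhaustive-scan Cq caller: cycle-by-cycle loop, written
# separately from the package's vectorised implementation.
oracle_cq <- function(f, bw = c(3L, 10L), k = 6) {
  n <- length(f)
  d <- rep(NA_real_, n)
  for (c in 2:n) d[c] <- f[c] - f[c - 1]
  base <- d[bw[1]:bw[2]]
  thr <- mean(base) + k * sd(base)
  for (c in (bw[2] + 1):n) {
    if (d[c] > thr) {
      frac <- (thr - d[c - 1]) / (d[c] - d[c - 1])
      frac <- min(max(frac, 0), 1)
      return(c - 1 + frac)
    }
  }
  NA_real_
}

# Random logistic amplification curve (plateau 100, baseline 0).
random_logistic <- function(midpoint, slope, noise_sd, n = 30L) {
  100 / (1 + exp(-slope * (seq_len(n) - midpoint))) +
    rnorm(n, 0, noise_sd)
}

# Minimal FASTQ writer used to build fixtures independently of the
# package's own (Biostrings-based) writer.
write_fastq <- function(reads, path, qual = "I") {
  lines <- character(0)
  for (i in seq_along(reads)) {
    lines <- c(lines,
               sprintf("@read%03d", i), reads[i], "+",
               strrep(qual, nchar(reads[i])))
  }
  writeLines(lines, path)
  path
}

flank5 <- aptamer_flanks()[["flank5"]]
flank3 <- aptamer_flanks()[["flank3"]]

random_40mer <- function(n = 1) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
          collapse = ""), character(1))
}

# Small standardized two-class dataset for model tests.
toy_classed_matrix <- function(n = 20, p = 8, shift = 2, seed = 42) {
  withr::with_seed(seed, {
    y <- rep(c("neg", "pos"), length.out = n)
    X <- matrix(rnorm(n * p), n, p)
    X[y == "pos", seq_len(min(2, p))] <-
      X[y == "pos", seq_len(min(2, p))] + shift
    X <- scale(X)
    attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
    dimnames(X) <- list(sprintf("s%02d", seq_len(n)),
                        sprintf("f%02d", seq_len(p)))
    list(X = X, y = factor(y, levels = c("neg", "pos")))
  })
}

# Full synthetic chain up to the raw feature matrix + labels.
synthetic_features <- function(seed, n_samples = 69, panel_size = 44,
                               n_informative = 5, cq_shift = 2.0,
                               cq_noise_sd = 0.5) {
  cfg <- simulation_config(n_samples = n_samples, panel_size = panel_size,
                           n_informative = n_informative,
                           cq_shift = cq_shift, cq_noise_sd = cq_noise_sd,
                           seed = seed)
  cohort <- simulate_cohort(cfg)
  curves <- simulate_amplification_curves(cohort, cfg)
  cq <- call_cq_table(curves, efficiency = FALSE)
  w <- cq_wide(cq)
  labels <- cohort$amyloid_class[match(rownames(w), cohort$sample_id)]
  list(fm = build_features(w), labels = labels, cohort = cohort,
       truth = curves$truth)
}
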