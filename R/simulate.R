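# Synthetic-data generators: cohorts, qPCR amplification curves and
# selection-library FASTQ files with the statistical structure the
# downstream analysis assumes.  Every generator is seeded through the
# config and is bit-reproducible.

#' Constant flanking regions of the aptamer library
#'
#' The single-stranded DNA library is a 40-mer random region flanked by two
#' constant primer-hybridisation regions.  These flanks delimit the random
#' region in every sequencing read.
#'
#' @return Named character vector with elements `flank5` and `flank3`.
#' @export
#' @examples
#' aptamer_flanks()
aptamer_flanks <- function() {
  c(flank5 = "AACTACATGGTATGTGGTGAACT",
    flank3 = "GACGTACAATGTACCCTATAGTG")
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators.  The defaults
#' emulate the study cohort the analysis was designed for: 69 usable
#' samples (one of the original 70 excluded as an outlier) split 31
#' amyloid-negative / 38 amyloid-positive at an SUVR threshold of 0.79, a
#' 44-aptamer qPCR panel measured over 30 cycles, and 22 selection
#' libraries (11 per class) of 40-mer reads between the constant flanks.
#'
#' @param n_samples Number of cohort members.
#' @param pos_fraction Fraction of amyloid-positive samples; the positive
#'   count is `round(n_samples * pos_fraction)`.
#' @param panel_size Number of aptamers in the qPCR panel.
#' @param n_informative Number of panel aptamers whose Cq differs between
#'   classes (must be `<= panel_size`).
#' @param cq_shift True crossing-cycle difference between classes on
#'   informative aptamers (cycles; positives amplify earlier).
#' @param cq_noise_sd SD of per-curve Gaussian noise on the true crossing
#'   cycle (cycles).
#' @param n_cycles Number of PCR cycles per curve (30 or 35 in the assay;
#'   must be >= 12 so the baseline window, cycles 3-10, fits).
#' @param reads_per_library Reads per selection-library FASTQ file.
#' @param n_enriched_sequences Number of class-enriched 40-mers.
#' @param enrichment_fold Sampling-probability fold increase of enriched
#'   sequences in positive libraries (>= 1; 1 means no enrichment).
#' @param n_background_sequences Size of the shared 40-mer background pool
#'   (the enriched sequences are drawn from this pool).
#' @param class_threshold SUVR threshold separating the classes.
#' @param curve_baseline,curve_plateau Baseline and plateau fluorescence of
#'   the logistic curve model (relative fluorescence units).
#' @param curve_slope Logistic growth rate (per cycle); the default 0.7
#'   gives a per-cycle amplification factor of `exp(0.7)` (about 2), i.e.
#'   an exponential-phase efficiency near 1.
#' @param curve_noise_sd SD of additive Gaussian fluorescence noise (RFU).
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#'
#' @return An object of class `simulation_config` (a validated list).
#' @export
#' @examples
#' simulation_config(n_samples = 10, pos_fraction = 0.5)
simulation_config <- function(n_samples = 69L,
                              pos_fraction = 39 / 70,
                              panel_size = 44L,
                              n_informative = 5L,
                              cq_shift = 2.0,
                              cq_noise_sd = 0.5,
                              n_cycles = 30L,
                              reads_per_library = 10000L,
                              n_enriched_sequences = 3L,
                              enrichment_fold = 10,
                              n_background_sequences = 200L,
                              class_threshold = 0.79,
                              curve_baseline = 50,
                              curve_plateau = 1000,
                              curve_slope = 0.7,
                              curve_noise_sd = 1,
                              seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              pos_fraction = pos_fraction,
              panel_size = as.integer(panel_size),
              n_informative = as.integer(n_informative),
              cq_shift = cq_shift,
              cq_noise_sd = cq_noise_sd,
              n_cycles = as.integer(n_cycles),
              reads_per_library = as.integer(reads_per_library),
              n_enriched_sequences = as.integer(n_enriched_sequences),
              enrichment_fold = enrichment_fold,
              n_background_sequences = as.integer(n_background_sequences),
              class_threshold = class_threshold,
              curve_baseline = curve_baseline,
              curve_plateau = curve_plateau,
              curve_slope = curve_slope,
              curve_noise_sd = curve_noise_sd,
              seed = as.integer(seed))
  if (cfg$n_samples < 2L)
    stop("n_samples must be >= 2", call. = FALSE)
  if (cfg$pos_fraction <= 0 || cfg$pos_fraction >= 1)
    stop("pos_fraction must lie in (0, 1)", call. = FALSE)
  if (cfg$panel_size < 1L)
    stop("panel_size must be >= 1", call. = FALSE)
  if (cfg$n_informative > cfg$panel_size)
    stop("n_informative must not exceed panel_size", call. = FALSE)
  if (cfg$n_informative < 0L || cfg$n_enriched_sequences < 0L)
    stop("n_informative and n_enriched_sequences must be >= 0",
         call. = FALSE)
  if (cfg$enrichment_fold < 1)
    stop("enrichment_fold must be >= 1", call. = FALSE)
  if (cfg$n_enriched_sequences > cfg$n_background_sequences)
    stop("n_enriched_sequences must not exceed n_background_sequences",
         call. = FALSE)
  structure(cfg, class = "simulation_config")
}

#' Simulate a cohort of amyloid-classified samples
#'
#' Draws `n_samples` sample records.  Class sizes are
#' `round(n_samples * pos_fraction)` positives and the complement;
#' SUVR is drawn Uniform(0.60, 0.78) for negatives and Uniform(0.80, 1.20)
#' for positives so the class/threshold relation holds by construction
#' (only the threshold relationship matters downstream).  Age, sex and
#' APOE genotype are drawn from the published per-class cohort
#' composition; they are carried as metadata and never modelled.
#'
#' @param config A [simulation_config()].
#' @return A data.frame with columns `sample_id`, `suvr`, `amyloid_class`
#'   (factor, levels `neg`/`pos`), `age`, `sex`, `apoe`.
#' @export
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_samples = 10, seed = 1))
#' table(cohort$amyloid_class)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_samples
  n_pos <- as.integer(round(n * config$pos_fraction))
  n_neg <- n - n_pos
  if (n_pos < 1L || n_neg < 1L) {
    stop(sprintf(paste0("degenerate cohort: %d negative and %d positive ",
                        "samples; both classes need at least one member"),
                 n_neg, n_pos), call. = FALSE)
  }
  thr <- config$class_threshold
  withr::with_seed(config$seed, {
    cls <- sample(rep(class_levels, c(n_neg, n_pos)))
    suvr <- ifelse(cls == "pos",
                   runif(n, 0.80, 1.20),
                   runif(n, 0.60, 0.78))
    # clamp in case a non-default threshold breaks the uniform ranges
    suvr <- ifelse(cls == "pos", pmax(suvr, thr + 1e-6),
                   pmin(suvr, thr - 1e-6))
    age <- ifelse(cls == "pos", rnorm(n, 77.4, 3.7), rnorm(n, 77.4, 3.1))
    sex <- ifelse(runif(n) < ifelse(cls == "pos", 21 / 39, 16 / 31),
                  "F", "M")
    geno <- c("E2/E3", "E3/E3", "E3/E4", "E4/E4")
    apoe <- character(n)
    apoe[cls == "neg"] <- sample(geno, sum(cls == "neg"), replace = TRUE,
                                 prob = c(5, 22, 3, 1) / 31)
    apoe[cls == "pos"] <- sample(geno, sum(cls == "pos"), replace = TRUE,
                                 prob = c(1, 20, 16, 2) / 39)
  })
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             suvr = suvr,
             amyloid_class = factor(cls, levels = class_levels),
             age = age, sex = sex, apoe = apoe,
             stringsAsFactors = FALSE)
}

#' Simulate qPCR amplification curves for a cohort
#'
#' One curve per (sample, aptamer).  Fluorescence follows a logistic in
#' cycle number,
#' `F(c) = baseline + plateau / (1 + exp(-k (c - c0))) + N(0, noise_sd)`,
#' the standard qPCR sigmoid shape.  Each aptamer has a per-aptamer base
#' crossing cycle drawn Uniform(21.5, 25.5) — placed so that every
#' derivative-threshold crossing, including class-shifted ones, falls
#' strictly inside the searchable cycle range; for the `n_informative` panel
#' members the true crossing cycle of positive samples is lowered by
#' `cq_shift` cycles (earlier amplification, i.e. more bound target), and
#' every curve receives Gaussian crossing-cycle noise `cq_noise_sd`.
#' Remaining aptamers are class-independent.
#'
#' @param samples Cohort data.frame from [simulate_cohort()].
#' @param config A [simulation_config()].
#' @return An object of class `aptamer_curve_set`: a list with
#'   * `curves`: long data.frame (`sample_id`, `aptamer_id`, `cycle`,
#'     `fluorescence`),
#'   * `truth`: ground-truth data.frame (`sample_id`, `aptamer_id`,
#'     `true_cq`, `informative`) enabling parameter-recovery tests.
#' @export
simulate_amplification_curves <- function(samples, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_cycles < 12L)
    stop("n_cycles must be >= 12 so the baseline window (cycles 3-10) fits",
         call. = FALSE)
  if (config$panel_size < 1L) stop("panel_size must be >= 1", call. = FALSE)
  n <- nrow(samples)
  p <- config$panel_size
  aptamers <- sprintf("APT%02d", seq_len(p))
  informative <- seq_len(config$n_informative)
  withr::with_seed(config$seed + 1L, {
    base_cq <- runif(p, 21.5, 25.5)
    shift <- matrix(0, n, p)
    if (length(informative) > 0) {
      shift[samples$amyloid_class == "pos", informative] <- -config$cq_shift
    }
    true_cq <- matrix(base_cq, n, p, byrow = TRUE) + shift +
      matrix(rnorm(n * p, 0, config$cq_noise_sd), n, p)
    cyc <- seq_len(config$n_cycles)
    # curves in column-major (sample, aptamer) order, cycles fastest
    c0 <- as.vector(true_cq)
    fl <- config$curve_baseline +
      config$curve_plateau /
        (1 + exp(-config$curve_slope * outer(cyc, c0, "-"))) +
      matrix(rnorm(config$n_cycles * n * p, 0, config$curve_noise_sd),
             config$n_cycles, n * p)
  })
  curves <- data.frame(
    sample_id = rep(rep(samples$sample_id, p), each = config$n_cycles),
    aptamer_id = rep(aptamers, each = config$n_cycles * n),
    cycle = rep(cyc, n * p),
    fluorescence = as.vector(fl),
    stringsAsFactors = FALSE)
  truth <- data.frame(
    sample_id = rep(samples$sample_id, p),
    aptamer_id = rep(aptamers, each = n),
    true_cq = as.vector(true_cq),
    informative = rep(seq_len(p) %in% informative, each = n),
    stringsAsFactors = FALSE)
  structure(list(curves = curves, truth = truth,
                 n_cycles = config$n_cycles),
            class = "aptamer_curve_set")
}

#' Simulate per-sample selection-library FASTQ files
#'
#' Emulates one round of positive selection against individual plasma
#' samples followed by sequencing: every read is the 5' flank, a 40-mer
#' from a shared background pool, and the 3' flank (86 nt total).  The
#' first `n_enriched_sequences` pool members are sampled with
#' `enrichment_fold` higher probability in positive-class libraries.
#' Quality strings are constant `"I"` (Q40); quality is never used
#' downstream.  A ground-truth JSON sidecar with the enriched sequences is
#' written alongside the FASTQ files.
#'
#' @param samples Cohort data.frame (both classes must be present;
#'   typically 22 samples, 11 per class).
#' @param config A [simulation_config()].
#' @param dir Output directory (created if missing).
#' @return An object of class `selection_library_set`: list with
#'   `manifest` (data.frame `sample_id`, `amyloid_class`, `path`),
#'   `enriched_sequences`, `pool`, and `truth_path`.
#' @export
simulate_selection_reads <- function(samples, config, dir = tempfile("libs")) {
  stopifnot(inherits(config, "simulation_config"))
  cls <- as_class_factor(samples$amyloid_class, "samples$amyloid_class")
  if (length(unique(cls)) < 2L || any(table(cls) == 0L))
    stop("both classes must be present among the samples", call. = FALSE)
  if (config$reads_per_library <= 0L)
    stop("reads_per_library must be > 0", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fl <- aptamer_flanks()
  n_pool <- config$n_background_sequences
  n_enr <- config$n_enriched_sequences
  withr::with_seed(config$seed + 2L, {
    pool <- unique(vapply(seq_len(2L * n_pool), function(i) {
      paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
            collapse = "")
    }, character(1)))[seq_len(n_pool)]
    w_neg <- rep(1, n_pool)
    w_pos <- w_neg
    if (n_enr > 0) w_pos[seq_len(n_enr)] <- config$enrichment_fold
    paths <- character(nrow(samples))
    for (i in seq_len(nrow(samples))) {
      w <- if (cls[i] == "pos") w_pos else w_neg
      idx <- sample.int(n_pool, config$reads_per_library, replace = TRUE,
                        prob = w / sum(w))
      reads <- paste0(fl[["flank5"]], pool[idx], fl[["flank3"]])
      dss <- Biostrings::DNAStringSet(reads)
      names(dss) <- sprintf("%s_read%06d", samples$sample_id[i],
                            seq_along(reads))
      qual <- Biostrings::BStringSet(rep(strrep("I", 86L), length(reads)))
      paths[i] <- file.path(dir, paste0(samples$sample_id[i], ".fastq"))
      Biostrings::writeXStringSet(dss, paths[i], format = "fastq",
                                  qualities = qual)
    }
  })
  enriched <- if (n_enr > 0) pool[seq_len(n_enr)] else character(0)
  truth_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(enriched_sequences = enriched,
         enrichment_fold = config$enrichment_fold,
         n_background_sequences = n_pool),
    truth_path, auto_unbox = TRUE, pretty = TRUE)
  structure(list(
    manifest = data.frame(sample_id = samples$sample_id,
                          amyloid_class = as.character(cls),
                          path = paths, stringsAsFactors = FALSE),
    enriched_sequences = enriched,
    pool = pool,
    truth_path = truth_path), class = "selection_library_set")
}
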