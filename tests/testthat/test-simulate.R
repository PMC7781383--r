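# Synthetic-data generators: cohort composition, curve structure,
# selection libraries, and the determinism contract.

test_that("cohort composition matches the configured class split", {
  cohort <- simulate_cohort(simulation_config(n_samples = 70,
                                              pos_fraction = 39 / 70,
                                              seed = 1))
  expect_equal(as.vector(table(cohort$amyloid_class)), c(31, 39))

  tiny <- simulate_cohort(simulation_config(n_samples = 2,
                                            pos_fraction = 0.5, seed = 3))
  expect_equal(as.vector(table(tiny$amyloid_class)), c(1, 1))

  # default config: 69 usable samples, 31 neg / 38 pos
  def <- simulate_cohort(simulation_config(seed = 5))
  expect_equal(as.vector(table(def$amyloid_class)), c(31, 38))
})

test_that("cohort SUVR respects the class threshold invariant", {
  cfg <- simulation_config(n_samples = 50, seed = 11)
  cohort <- simulate_cohort(cfg)
  expect_true(all(cohort$suvr > 0))
  expect_equal(cohort$amyloid_class == "pos",
               cohort$suvr > cfg$class_threshold)
})

test_that("degenerate single-class cohorts error with the class sizes", {
  expect_error(simulate_cohort(simulation_config(n_samples = 5,
                                                 pos_fraction = 0.01)),
               "5 negative and 0 positive")
})

test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 17)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
})

test_that("one curve of n_cycles points is generated per sample-aptamer pair", {
  cfg <- simulation_config(n_samples = 10, panel_size = 7, seed = 2)
  cohort <- simulate_cohort(cfg)
  cs <- simulate_amplification_curves(cohort, cfg)
  expect_equal(nrow(cs$curves), 10 * 7 * 30)
  counts <- table(cs$curves$sample_id, cs$curves$aptamer_id)
  expect_true(all(counts == 30))
  expect_equal(nrow(cs$truth), 10 * 7)
  expect_identical(cs, simulate_amplification_curves(cohort, cfg))
})

test_that("curves with too few cycles for the baseline window are refused", {
  cfg <- simulation_config(n_samples = 4, panel_size = 2, n_cycles = 11,
                           n_informative = 1, seed = 1)
  cohort <- simulate_cohort(cfg)
  expect_error(simulate_amplification_curves(cohort, cfg), "baseline window")
})

test_that("zero shift and zero noise give class-identical true crossing cycles", {
  cfg <- simulation_config(n_samples = 12, panel_size = 5, n_informative = 3,
                           cq_shift = 0, cq_noise_sd = 0, seed = 4)
  cohort <- simulate_cohort(cfg)
  truth <- simulate_amplification_curves(cohort, cfg)$truth
  per_apt <- tapply(truth$true_cq, truth$aptamer_id,
                    function(x) diff(range(x)))
  expect_true(all(per_apt == 0))
})

test_that("a 2-cycle class shift is recovered by the Cq caller", {
  cfg <- simulation_config(n_samples = 40, panel_size = 6, n_informative = 3,
                           cq_shift = 2.0, cq_noise_sd = 0.5, seed = 8)
  cohort <- simulate_cohort(cfg)
  cs <- simulate_amplification_curves(cohort, cfg)
  cq <- call_cq_table(cs, efficiency = FALSE)
  w <- cq_wide(cq)
  lab <- cohort$amyloid_class[match(rownames(w), cohort$sample_id)]
  d <- colMeans(w[lab == "neg", , drop = FALSE]) -
    colMeans(w[lab == "pos", , drop = FALSE])
  expect_true(all(abs(d[1:3] - 2.0) < 0.5))   # informative aptamers
  expect_true(all(abs(d[4:6]) < 0.5))         # class-independent aptamers
})

test_that("selection libraries have the documented read structure", {
  cfg <- simulation_config(n_samples = 6, pos_fraction = 0.5,
                           reads_per_library = 200,
                           n_background_sequences = 50,
                           n_enriched_sequences = 2, seed = 6)
  cohort <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  libs <- simulate_selection_reads(cohort, cfg, dir = dir)
  expect_equal(nrow(libs$manifest), 6)
  expect_true(all(file.exists(libs$manifest$path)))
  reads <- Biostrings::readDNAStringSet(libs$manifest$path[1],
                                        format = "fastq")
  expect_length(reads, 200)
  expect_true(all(nchar(as.character(reads)) == 86))
  expect_true(all(startsWith(as.character(reads), flank5)))
  expect_true(all(endsWith(as.character(reads), flank3)))
  # ground truth sidecar is always emitted
  expect_true(file.exists(libs$truth_path))
  gt <- jsonlite::read_json(libs$truth_path, simplifyVector = TRUE)
  expect_identical(sort(gt$enriched_sequences),
                   sort(libs$enriched_sequences))

  # byte-identical regeneration under the same config and seed
  dir2 <- withr::local_tempdir()
  libs2 <- simulate_selection_reads(cohort, cfg, dir = dir2)
  expect_identical(unname(tools::md5sum(libs$manifest$path)),
                   unname(tools::md5sum(libs2$manifest$path)))
})

test_that("enrichment_fold scales pooled enriched frequency between classes", {
  cfg <- simulation_config(n_samples = 8, pos_fraction = 0.5,
                           reads_per_library = 5000,
                           n_background_sequences = 100,
                           n_enriched_sequences = 3,
                           enrichment_fold = 10, seed = 9)
  cohort <- simulate_cohort(cfg)
  libs <- simulate_selection_reads(cohort, cfg, dir = withr::local_tempdir())
  freq <- function(cls) {
    paths <- libs$manifest$path[libs$manifest$amyloid_class == cls]
    seqs <- unlist(lapply(paths, function(p)
      extract_random_regions(p)$sequences))
    mean(seqs %in% libs$enriched_sequences)
  }
  # pos weight 10 vs neg weight 1 -> expected pooled frequency ratio
  # (3*10/127) / (3/100) = 7.87 (the pos denominator renormalizes)
  expect_gt(freq("pos") / freq("neg"), 5)
  expect_lt(freq("pos") / freq("neg"), 11)

  flat <- simulation_config(n_samples = 8, pos_fraction = 0.5,
                            reads_per_library = 5000,
                            n_background_sequences = 100,
                            n_enriched_sequences = 3,
                            enrichment_fold = 1, seed = 9)
  libs_flat <- simulate_selection_reads(cohort, flat,
                                        dir = withr::local_tempdir())
  f <- function(cls) {
    paths <- libs_flat$manifest$path[libs_flat$manifest$amyloid_class == cls]
    seqs <- unlist(lapply(paths, function(p)
      extract_random_regions(p)$sequences))
    mean(seqs %in% libs_flat$enriched_sequences)
  }
  expect_lt(abs(f("pos") - f("neg")), 0.01)
})

test_that("selection-read generation rejects invalid inputs", {
  cfg <- simulation_config(n_samples = 4, pos_fraction = 0.5,
                           reads_per_library = 0, seed = 1)
  cohort <- simulate_cohort(cfg)
  expect_error(simulate_selection_reads(cohort, cfg, withr::local_tempdir()),
               "reads_per_library")
  cfg2 <- simulation_config(n_samples = 4, pos_fraction = 0.5, seed = 1)
  single <- simulate_cohort(cfg2)
  single$amyloid_class <- factor(rep("pos", 4), levels = c("neg", "pos"))
  expect_error(simulate_selection_reads(single, cfg2,
                                        withr::local_tempdir()),
               "both classes")
})

test_that("simulation_config validates its invariants", {
  expect_error(simulation_config(n_informative = 45), "panel_size")
  expect_error(simulation_config(enrichment_fold = 0.5), "enrichment_fold")
  expect_error(simulation_config(pos_fraction = 1.2), "pos_fraction")
})
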