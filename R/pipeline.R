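# Pipeline driver: chains simulate -> (selection NGS) -> cq -> features ->
# train/predict -> crossval from a YAML config, writing every stage
# artifact plus a reproducibility manifest.

#' Default pipeline configuration
#'
#' All analysis thresholds are surfaced here with their conventional
#' defaults: derivative threshold `k = 6` over baseline cycles 3-10,
#' SUVR class threshold 0.79, top-N screening depth 10000, optional
#' loading cutoff 0.04.
#'
#' @return Nested named list; see [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(seed = 1L,
       out_dir = "aptamarker_run",
       stages = c("simulate", "cq", "features", "train", "predict",
                  "crossval"),
       simulate = list(),               # overrides for simulation_config()
       inputs = list(curves = NULL, metadata = NULL, model = NULL),
       selection = list(top_n = 10000L, max_mismatch = 0L,
                        n_per_class = 11L),
       qpcr = list(k = 6, baseline_window = c(3L, 10L),
                   interpolate = TRUE, efficiency = TRUE),
       features = list(na_action = "drop"),
       model = list(keepx = NULL, loading_cutoff = NULL,
                    n_train = 54L, n_test = 15L),
       crossval = list(n_repeats = 5L, n_train = 54L, n_test = 15L),
       exclude_samples = character(0))
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the requested stages in order:
#' `simulate` (cohort + amplification curves; `selection` additionally
#' writes and analyses per-sample selection-library FASTQ files),
#' `cq` (derivative-threshold Cq calling), `features` (Cq + one-direction
#' pairwise ratios), `train` (random train/test split, standardizer and
#' sparse PLS-DA fitted on the training split, model saved as JSON),
#' `predict` (nearest-zero classification of the held-out split, metrics
#' and ROC), and `crossval` (repeated hold-out cross-validation).
#' Without the `simulate` stage, curve and metadata CSV paths must be
#' given under `inputs`.  Every stage output is written under `out_dir`
#' and digested into `manifest.json`; re-running with the same config and
#' seed reproduces byte-identical outputs.
#'
#' @param config Path to a YAML file or a named list; entries override
#'   [default_pipeline_config()].
#' @param out_dir Optional output directory overriding the config.
#' @return Object of class `run_manifest` (invisibly): config, seed,
#'   stage outputs with MD5 digests, and headline metrics.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- default_pipeline_config()
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- modifyList(cfg, config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- cfg$stages
  outputs <- character(0)
  results <- list()
  emit <- function(name, writer) {
    path <- file.path(cfg$out_dir, name)
    writer(path)
    outputs[[name]] <<- path
  }

  cohort <- NULL
  curves <- NULL
  if ("simulate" %in% stages) {
    sim_cfg <- do.call(simulation_config,
                       modifyList(list(seed = cfg$seed), cfg$simulate))
    cohort <- simulate_cohort(sim_cfg)
    curves <- simulate_amplification_curves(cohort, sim_cfg)
    if (length(cfg$exclude_samples) > 0) {
      cohort <- cohort[!cohort$sample_id %in% cfg$exclude_samples, ,
                       drop = FALSE]
      curves$curves <- curves$curves[
        !curves$curves$sample_id %in% cfg$exclude_samples, , drop = FALSE]
      curves$truth <- curves$truth[
        !curves$truth$sample_id %in% cfg$exclude_samples, , drop = FALSE]
    }
    emit("metadata.csv", function(p) write.csv(cohort, p, row.names = FALSE))
    emit("curves.csv",
         function(p) write.csv(curves$curves, p, row.names = FALSE))
    emit("curve_truth.csv",
         function(p) write.csv(curves$truth, p, row.names = FALSE))
    if ("selection" %in% stages) {
      per <- cfg$selection$n_per_class
      sel_samples <- do.call(rbind, lapply(class_levels, function(cl) {
        sub <- cohort[cohort$amyloid_class == cl, , drop = FALSE]
        if (nrow(sub) < per)
          stop(sprintf("stage 'selection' needs %d samples per class", per),
               call. = FALSE)
        sub[seq_len(per), , drop = FALSE]
      }))
      libs <- simulate_selection_reads(sel_samples, sim_cfg,
                                       dir = file.path(cfg$out_dir,
                                                       "libraries"))
      extracted <- lapply(seq_len(nrow(libs$manifest)), function(i)
        extract_random_regions(libs$manifest$path[i],
                               max_mismatch = cfg$selection$max_mismatch))
      names(extracted) <- libs$manifest$sample_id
      counts <- top_n_matrix(count_frequencies(extracted),
                             cfg$selection$top_n)
      selection <- select_candidate_aptamers(
        counts, libs$manifest$amyloid_class, seed = cfg$seed)
      emit("counts.csv", function(p)
        write.csv(t(counts$counts), p))    # sequences x samples
      emit("selection_report.json", function(p)
        jsonlite::write_json(
          list(sequences = selection$sequences,
               loadings = unname(selection$loadings),
               keepX = selection$keepX,
               loo = selection$loo),
          p, auto_unbox = TRUE, digits = NA))
      results$selection <- selection
    }
  } else if (any(c("cq", "features", "train", "predict", "crossval")
                 %in% stages)) {
    if (is.null(cfg$inputs$curves) || is.null(cfg$inputs$metadata))
      stop("stage 'cq' requires simulated data or inputs$curves and ",
           "inputs$metadata", call. = FALSE)
    curves <- list(curves = read.csv(cfg$inputs$curves,
                                     stringsAsFactors = FALSE))
    cohort <- read.csv(cfg$inputs$metadata, stringsAsFactors = FALSE)
    if (length(cfg$exclude_samples) > 0) {
      cohort <- cohort[!cohort$sample_id %in% cfg$exclude_samples, ,
                       drop = FALSE]
      curves$curves <- curves$curves[
        !curves$curves$sample_id %in% cfg$exclude_samples, , drop = FALSE]
    }
  }

  cq_tab <- NULL
  if ("cq" %in% stages) {
    if (is.null(curves))
      stop("stage 'cq' is missing its upstream curves artifact",
           call. = FALSE)
    cq_tab <- call_cq_table(curves$curves,
                            baseline_window = cfg$qpcr$baseline_window,
                            k = cfg$qpcr$k,
                            interpolate = cfg$qpcr$interpolate,
                            efficiency = cfg$qpcr$efficiency)
    emit("cq.csv", function(p) write.csv(cq_tab, p, row.names = FALSE))
  }

  fm <- NULL
  if ("features" %in% stages) {
    if (is.null(cq_tab))
      stop("stage 'features' is missing its upstream cq artifact",
           call. = FALSE)
    fm <- build_features(cq_wide(cq_tab),
                         na_action = cfg$features$na_action)
    emit("features.csv", function(p) write.csv(fm$values, p))
  }

  model <- NULL
  std <- NULL
  test_ids <- NULL
  if ("train" %in% stages) {
    if (is.null(fm))
      stop("stage 'train' is missing its upstream features artifact",
           call. = FALSE)
    lab <- cohort$amyloid_class[match(fm$sample_ids, cohort$sample_id)]
    lab <- as_class_factor(lab, "amyloid_class")
    n <- nrow(fm$values)
    n_train <- min(cfg$model$n_train, n - 1L)
    withr::with_seed(cfg$seed, {
      idx <- sample.int(n)
    })
    tr <- idx[seq_len(n_train)]
    te <- idx[-seq_len(n_train)]
    if (length(te) > cfg$model$n_test) te <- te[seq_len(cfg$model$n_test)]
    fmtr <- fit_standardizer(fm_rows(fm, tr))
    std <- fmtr$standardization
    model <- splsda_fit(fmtr$values, lab[tr],
                        keepX = cfg$model$keepx %||% ncol(fmtr$values))
    if (!is.null(cfg$model$loading_cutoff))
      model <- filter_by_loading(model, cfg$model$loading_cutoff)
    test_ids <- fm$sample_ids[te]
    emit("model.json", function(p) save_model(model, p, standardizer = std))
    results$model <- model
  }

  if ("predict" %in% stages) {
    if (is.null(model)) {
      if (is.null(cfg$inputs$model))
        stop("stage 'predict' requires a model: run stage 'train' or set ",
             "inputs$model", call. = FALSE)
      model <- load_model(cfg$inputs$model)
      std <- model$standardization
      test_ids <- fm$sample_ids
    }
    if (is.null(fm))
      stop("stage 'predict' is missing its upstream features artifact",
           call. = FALSE)
    lab <- cohort$amyloid_class[match(fm$sample_ids, cohort$sample_id)]
    lab <- as_class_factor(lab, "amyloid_class")
    te <- match(test_ids, fm$sample_ids)
    fmte <- apply_standardizer(fm_rows(fm, te), std)
    sc <- predict_scores(model, fmte)[, 1]
    names(sc) <- test_ids
    outcome <- classify_nearest_zero(sc, model$class_stats)
    emit("predictions.csv",
         function(p) write.csv(outcome, p, row.names = FALSE))
    cm <- evaluate_predictions(outcome$call, lab[te])
    roc <- roc_curve(sc, lab[te])
    emit("metrics.json", function(p)
      jsonlite::write_json(
        list(tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
             sensitivity = cm$sensitivity, specificity = cm$specificity,
             accuracy = cm$accuracy, auc = roc$auc),
        p, auto_unbox = TRUE, digits = NA))
    emit("roc.csv", function(p) write.csv(roc$points, p, row.names = FALSE))
    results$confusion <- cm
    results$roc <- roc
  }

  if ("crossval" %in% stages) {
    if (is.null(fm))
      stop("stage 'crossval' is missing its upstream features artifact",
           call. = FALSE)
    lab <- cohort$amyloid_class[match(fm$sample_ids, cohort$sample_id)]
    lab <- as_class_factor(lab, "amyloid_class")
    n <- nrow(fm$values)
    cv <- cross_validate(fm, lab,
                         n_repeats = cfg$crossval$n_repeats,
                         n_train = min(cfg$crossval$n_train, n - 1L),
                         n_test = min(cfg$crossval$n_test,
                                      n - min(cfg$crossval$n_train, n - 1L)),
                         keepX = cfg$model$keepx,
                         loading_cutoff = cfg$model$loading_cutoff,
                         seed = cfg$seed)
    emit("cv_report.json", function(p)
      jsonlite::write_json(
        list(n_repeats = cv$n_repeats,
             metrics = cv$metrics,
             mean_sensitivity = cv$mean_sensitivity,
             mean_specificity = cv$mean_specificity,
             mean_accuracy = cv$mean_accuracy,
             seed = cv$seed),
        p, auto_unbox = TRUE, digits = NA, dataframe = "rows"))
    results$cv <- cv
  }

  cfg_path <- file.path(cfg$out_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  manifest <- structure(list(
    package_version = as.character(utils::packageVersion("aptamarkers")),
    seed = cfg$seed,
    stages = stages,
    config_hash = unname(tools::md5sum(cfg_path)),
    outputs = as.list(unname(tools::md5sum(unlist(outputs)))),
    results = list(
      cv_mean_accuracy = results$cv$mean_accuracy %||% NA,
      test_accuracy = results$confusion$accuracy %||% NA)),
    class = "run_manifest")
  names(manifest$outputs) <- names(outputs)
  jsonlite::write_json(unclass(manifest),
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest$results_full <- results
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("pipeline run manifest\n")
  cat("  stages:", paste(x$stages, collapse = " -> "), "\n")
  cat("  seed:", x$seed, "\n")
  cat("  outputs:\n")
  for (nm in names(x$outputs))
    cat(sprintf("    %-22s %s\n", nm, x$outputs[[nm]]))
  invisible(x)
}
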