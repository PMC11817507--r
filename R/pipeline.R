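# End-to-end pipeline: simulate -> SUL -> extract -> prune -> grid ->
# select -> test -> follow-up decision -> occlusion, with a validated
# configuration, a single global seed fanned out per stage, and a JSON run
# manifest of every artefact written.

#' Pipeline configuration
#'
#' Nested, schema-checked configuration for [run_pipeline()]. Unknown keys
#' are rejected so typos fail fast. A serialised copy is written into the
#' output directory of every run.
#'
#' @param phantom A [phantom_params()] object (or list of overrides).
#' @param target_spacing Isotropic analysis spacing in mm.
#' @param discretisation [discretisation_settings()] or overrides.
#' @param selectors,feature_counts,classifiers Grid registries.
#' @param test_fraction Patient-wise test fraction.
#' @param prune_threshold Pearson threshold for [prune_correlated()].
#' @param n_folds Cross-validation folds.
#' @param n_followup_active,n_followup_inactive Follow-up scans to
#'   simulate for the decision stage.
#' @param occlusion [occlusion_spec()] or overrides; `NULL` skips the
#'   occlusion stage.
#' @param youden_weight Sensitivity weight of the generalised Youden index.
#' @param seed Global seed fanned out to the stages via [stage_seed()].
#' @param output_dir Output directory, or `NULL` to keep results in
#'   memory only.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_params(),
                            target_spacing = 2.0,
                            discretisation = discretisation_settings(),
                            selectors = selector_registry(),
                            feature_counts = feature_count_registry(),
                            classifiers = classifier_registry(),
                            test_fraction = 0.2,
                            prune_threshold = 0.9,
                            n_folds = 10L,
                            n_followup_active = 7L,
                            n_followup_inactive = 12L,
                            occlusion = occlusion_spec(),
                            youden_weight = 0.5,
                            seed = 1L,
                            output_dir = NULL) {
  if (is.list(phantom) && !inherits(phantom, "phantom_params")) {
    phantom <- do.call(phantom_params, phantom)
  }
  if (is.list(discretisation) && !inherits(discretisation,
                                           "discretisation_settings")) {
    discretisation <- do.call(discretisation_settings, discretisation)
  }
  if (!is.null(occlusion) && is.list(occlusion) &&
      !inherits(occlusion, "occlusion_spec")) {
    occlusion <- do.call(occlusion_spec, occlusion)
  }
  assert_positive(target_spacing, "target_spacing")
  if (phantom$n_gca < 2 || phantom$n_athero < 2) {
    stop_petvasc("the pipeline needs at least 2 patients per class (stratified split)",
                 class = "petvasc_validation_error")
  }
  cfg <- list(phantom = phantom, target_spacing = target_spacing,
              discretisation = discretisation, selectors = selectors,
              feature_counts = as.integer(feature_counts),
              classifiers = classifiers,
              test_fraction = test_fraction,
              prune_threshold = prune_threshold,
              n_folds = as.integer(n_folds),
              n_followup_active = as.integer(n_followup_active),
              n_followup_inactive = as.integer(n_followup_inactive),
              occlusion = occlusion, youden_weight = youden_weight,
              seed = as.integer(seed), output_dir = output_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys must be arguments of [pipeline_config()]; unknown keys
#' raise an error.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop_petvasc(sprintf("unknown config keys: %s",
                         paste(unknown, collapse = ", ")),
                 class = "petvasc_validation_error")
  }
  do.call(pipeline_config, raw)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "petvasc_stage_error")) stop(e)
    stop_petvasc(sprintf("pipeline stage `%s` failed: %s",
                         name, conditionMessage(e)),
                 class = "petvasc_stage_error")
  })
}

#' Run the full pipeline
#'
#' Simulates a baseline cohort, converts to SUL and resamples, extracts
#' the 95-feature table, applies the calcification exclusion, splits
#' patient-wise, prunes correlated features on the training half, runs the
#' model grid with cross-validation, selects and tests the final model,
#' scores simulated follow-up scans (max-segment aggregation + Youden
#' threshold + diagnostic report), and computes an occlusion map for the
#' first active follow-up scan.
#'
#' @param config A [pipeline_config()].
#' @param grid Optional pre-built grid data frame (defaults to the full
#'   product of the configured registries).
#' @return A `pipeline_run` list with the artefacts of every stage and a
#'   `manifest`.
#' @export
run_pipeline <- function(config, grid = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  cohort <- run_stage("phantom", generate_cohort(
    modifyList(config$phantom, list(seed = stage_seed(seed, "phantom")),
               keep.null = TRUE)))
  table <- run_stage("features", extract_cohort_features(
    cohort, config$discretisation, config$target_spacing, "baseline"))
  table <- run_stage("calcification_filter", filter_calcified(table))
  split <- run_stage("split", split_patientwise(
    table, config$test_fraction, seed = stage_seed(seed, "split")))
  train_tab <- table[table$patient_id %in% split$train_patient_ids, ]
  test_tab <- table[table$patient_id %in% split$test_patient_ids, ]
  pruned <- run_stage("prune", prune_correlated(train_tab,
                                                config$prune_threshold))
  if (is.null(grid)) {
    grid <- enumerate_grid(config$selectors, config$feature_counts,
                           config$classifiers)
  }
  results <- run_stage("grid", run_grid(grid, train_tab,
                                        n_folds = config$n_folds,
                                        seed = stage_seed(seed, "cv"),
                                        feature_names = pruned$kept))
  final <- run_stage("select", select_final(results))
  test_perf <- run_stage("test", fit_final_and_test(final, train_tab,
                                                    test_tab))
  followup <- run_stage("followup", run_followup(config, final))
  occ <- NULL
  if (!is.null(config$occlusion) && length(followup$scans)) {
    first_active <- which(vapply(followup$scans, `[[`, TRUE, "active"))[1]
    if (!is.na(first_active)) {
      sc <- followup$scans[[first_active]]
      sul <- resample_isotropic(to_sul(sc$pet, sc$meta),
                                config$target_spacing)
      msk <- resample_isotropic(sc$mask, config$target_spacing)
      occ <- run_stage("occlusion", occlusion_map(
        sul, msk, final, config$occlusion, config$discretisation))
    }
  }
  run <- list(config = config, cohort_table = table, split = split,
              pruned = pruned, grid = grid,
              grid_results = grid_summary(results), final = final,
              test_performance = test_perf, followup = followup,
              occlusion = occ)
  class(run) <- "pipeline_run"
  if (!is.null(config$output_dir)) write_pipeline_run(run, config$output_dir)
  run
}

# Simulate follow-up scans, score them with the final model, place the
# Youden threshold on the follow-up set itself (in-sample, as flagged in
# the report), and compare calls against the simulated ground truth.
run_followup <- function(config, final) {
  n_act <- config$n_followup_active
  n_inact <- config$n_followup_inactive
  if (n_act + n_inact == 0) {
    return(list(scans = list(), decisions = NULL, report = NULL))
  }
  base_seed <- stage_seed(config$seed, "followup")
  scans <- lapply(seq_len(n_act + n_inact), function(i) {
    generate_followup_scan(config$phantom, active = i <= n_act,
                           patient_id = sprintf("FUP%03d", i),
                           seed = base_seed + i)
  })
  tabs <- lapply(scans, function(sc) {
    extract_cohort_features(list(sc), config$discretisation,
                            config$target_spacing, "followup")
  })
  fu_table <- do.call(rbind, tabs)
  probs <- predict_segments(final, fu_table)
  labels <- vapply(scans, function(sc) {
    if (sc$active) "active" else "inactive"
  }, character(1))
  names(labels) <- vapply(scans, function(sc) {
    paste0(sc$meta$patient_id, "_fo")
  }, character(1))
  dec <- scan_decisions(fu_table, probs, threshold = 0.5)
  lab <- labels[dec$scan_id]
  threshold <- if (length(unique(lab)) == 2) {
    youden_cutoff(dec$scan_prob, lab, weight = config$youden_weight)
  } else 0.5
  dec$call <- ifelse(dec$scan_prob >= threshold, "active", "inactive")
  dec$label <- unname(lab)
  report <- if (length(unique(lab)) == 2) {
    diagnostic_report(dec$call, dec$label)
  } else NULL
  list(scans = scans, table = fu_table, decisions = dec,
       threshold = threshold, report = report)
}

#' Write pipeline artefacts to disk
#'
#' Feature table and grid summary as CSV, split/threshold/report and the
#' configuration as JSON, the occlusion delta as NIfTI, plus a manifest
#' with seeds and content hashes so reruns are diffable.
#'
#' @param run A `pipeline_run`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(features = file.path(dir, "features.csv"),
             grid = file.path(dir, "grid_results.csv"),
             split = file.path(dir, "split.json"),
             config = file.path(dir, "config.json"),
             final = file.path(dir, "final_model.json"))
  utils::write.csv(run$cohort_table, paths["features"], row.names = FALSE)
  utils::write.csv(run$grid_results, paths["grid"], row.names = FALSE)
  write_split_assignment(run$split, paths["split"])
  jsonlite::write_json(config_to_list(run$config), paths["config"],
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(list(
    config = run$final$config,
    auc_mean = run$final$auc_mean, auc_sd = run$final$auc_sd,
    cv_features = lapply(Filter(Negate(is.null), run$final$models),
                         `[[`, "features"),
    test = run$test_performance[c("auc_mean", "auc_sd", "ppv_mean",
                                  "npv_mean")],
    followup_threshold = run$followup$threshold
  ), paths["final"], auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(run$followup$decisions)) {
    utils::write.csv(run$followup$decisions,
                     file.path(dir, "followup_decisions.csv"),
                     row.names = FALSE)
    paths["decisions"] <- file.path(dir, "followup_decisions.csv")
  }
  if (!is.null(run$occlusion)) {
    write_occlusion_map(run$occlusion, rep(run$config$target_spacing, 3),
                        file.path(dir, "occlusion_delta.nii.gz"))
    paths["occlusion"] <- file.path(dir, "occlusion_delta.nii.gz")
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("petvasc")),
    seed = run$config$seed,
    created = format(Sys.time(), tz = "UTC"),
    files = lapply(stats::setNames(as.list(paths), names(paths)),
                   function(p) list(path = basename(p),
                                    md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

config_to_list <- function(cfg) {
  lapply(unclass(cfg), function(x) if (is.list(x)) unclass(x) else x)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  cat(sprintf("  segments: %d (after calcification filter)\n",
              nrow(x$cohort_table)))
  cat(sprintf("  features kept after pruning: %d of %d\n",
              length(x$pruned$kept),
              length(x$pruned$kept) + length(x$pruned$dropped)))
  cat(sprintf("  grid: %d configs; final: %s (CV AUC %.3f +/- %.3f)\n",
              nrow(x$grid), x$final$config$config_id,
              x$final$auc_mean, x$final$auc_sd))
  cat(sprintf("  test AUC %.3f +/- %.3f\n",
              x$test_performance$auc_mean, x$test_performance$auc_sd))
  if (!is.null(x$followup$report)) {
    cat(sprintf("  follow-up threshold %.3f; accuracy %.2f\n",
                x$followup$threshold, x$followup$report$accuracy))
  }
  invisible(x)
}
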