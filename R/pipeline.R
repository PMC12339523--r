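# End-to-end pipeline orchestration.

#' Pipeline run configuration
#'
#' Builds and validates the configuration for [run_pipeline()]. All
#' settings are plain values so the configuration serializes to JSON/YAML
#' and a run can be reproduced from its manifest alone.
#'
#' @param seed Master seed.
#' @param counts Per-group subject counts (length 4).
#' @param duration,fs Record length (s) and sampling rate (Hz).
#' @param noise_profile `"clean"` or `"clinical"`.
#' @param algos Models to benchmark (subset of `"rf"`, `"bdt"`, `"svm"`,
#'   `"fsrf"`).
#' @param folds Outer CV folds (>= 2).
#' @param smote_k SMOTE neighbor count.
#' @param smote_before_split Balance before splitting (leaky protocol).
#' @param grid Optional named list of hyperparameter grids per algorithm.
#' @return A validated `pf_config` list.
#' @export
pipeline_config <- function(seed = 1L, counts = c(20L, 20L, 20L, 20L),
                            duration = 20, fs = 1100,
                            noise_profile = "clean",
                            algos = c("rf", "fsrf"), folds = 5L,
                            smote_k = 5L, smote_before_split = FALSE,
                            grid = NULL) {
  if (length(counts) != 4L || any(counts < 0)) {
    pf_abort("counts must be 4 non-negative integers", "pf_invalid_config")
  }
  if (folds < 2L) pf_abort("folds must be >= 2", "pf_invalid_config")
  if (!noise_profile %in% c("clean", "clinical")) {
    pf_abort("noise_profile must be 'clean' or 'clinical'", "pf_invalid_config")
  }
  bad <- setdiff(algos, c("rf", "bdt", "svm", "fsrf"))
  if (length(bad)) pf_abort(paste("unknown algorithm:", bad[1]), "pf_invalid_config")
  assert_scalar_num(duration, "duration", lower = 3)
  assert_scalar_num(fs, "fs", lower = 50)
  structure(list(seed = as.integer(seed), counts = as.integer(counts),
                 duration = duration, fs = fs,
                 noise_profile = noise_profile, algos = algos,
                 folds = as.integer(folds), smote_k = as.integer(smote_k),
                 smote_before_split = isTRUE(smote_before_split),
                 grid = grid),
            class = "pf_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with fields matching [pipeline_config()].
#' @return A validated `pf_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    pf_abort("the yaml package is required to read YAML configurations",
             "pf_invalid_config")
  }
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' One reproducible run: synthesize the cohort, extract pulse and ECG
#' features, compute the group-comparison table, benchmark the configured
#' models under stratified cross-validation (SMOTE inside training folds by
#' default), and write everything to a run directory:
#' `features.csv`, `group_tests.csv`, `metrics.csv`, per-model
#' `confusion_<algo>.csv`, and `manifest.json` (configuration + seeds +
#' per-fold results, sufficient to re-execute the run bit-identically).
#'
#' @param config A `pf_config` from [pipeline_config()].
#' @param out_dir Output directory (created; must not contain a previous
#'   manifest unless `overwrite = TRUE`).
#' @param overwrite Replace existing outputs.
#' @return Invisibly, a list with `features`, `group_tests`, `cv` (named
#'   list of `pf_cv`), and `manifest`.
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE) {
  stopifnot(inherits(config, "pf_config"))
  if (dir.exists(out_dir) && file.exists(file.path(out_dir, "manifest.json")) &&
      !overwrite) {
    pf_abort("output directory already holds a run (set overwrite = TRUE)",
             "pf_invalid_config")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(file.path(out_dir, c("features.csv", "group_tests.csv",
                                  "metrics.csv", "manifest.json")))
      pf_abort(sprintf("pipeline stage '%s' failed: %s", name,
                       conditionMessage(e)), "pf_stage_failure")
    })
  }

  cohort <- stage("synth", synth_cohort(config$counts, seed = config$seed,
                                        duration = config$duration,
                                        fs = config$fs,
                                        noise = noise_profile(config$noise_profile)))
  features <- stage("features", extract_features(cohort))
  readr::write_csv(features, file.path(out_dir, "features.csv"))

  tests <- stage("stats", compare_groups(features, "group",
                                         features = setdiff(names(features),
                                                            c("id", "group", "sex"))))
  readr::write_csv(tidy(tests), file.path(out_dir, "group_tests.csv"))

  cv <- list()
  metrics <- list()
  for (algo in config$algos) {
    res <- stage(paste0("train_", algo), {
      if (algo == "fsrf") {
        fsrf_cv(features, "group", folds = config$folds,
                seed = config$seed, smote = TRUE, k = config$smote_k)
      } else {
        train_eval_cv(features, "group", algo = algo,
                      grid = config$grid[[algo]],
                      folds = config$folds, seed = config$seed,
                      smote = TRUE,
                      smote_before_split = config$smote_before_split,
                      k = config$smote_k)
      }
    })
    cv[[algo]] <- res
    metrics[[algo]] <- glance(res)
    utils::write.csv(res$cm, file.path(out_dir, paste0("confusion_", algo, ".csv")))
  }
  metrics_tbl <- dplyr::bind_rows(metrics)
  readr::write_csv(metrics_tbl, file.path(out_dir, "metrics.csv"))

  manifest <- list(
    config = unclass(config),
    n_subjects = nrow(features),
    models = lapply(cv, function(r) list(
      algo = r$algo, fold_acc = r$fold_acc,
      accuracy = r$metrics$accuracy,
      best_params = if (!is.null(r$best_params)) as.list(r$best_params) else NULL,
      selected = if (!is.null(r$selected)) r$selected else NULL)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(features = features, group_tests = tests, cv = cv,
                 manifest = manifest))
}
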