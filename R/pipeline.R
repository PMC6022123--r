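#' Reproducible end-to-end run configuration
#'
#' Bundles every knob of the full pipeline — simulate (or load) walks, trim
#' and calibrate, extract the 165-attribute vectors, split, stability-rank
#' attributes, train the final ensemble, evaluate on the held-out set — so a
#' run is a pure function of `(config)`; all stage seeds derive from
#' `seed`.
#'
#' @param seed master integer seed.
#' @param n_normal,n_hemi simulated subjects per class (defaults 15 and 20,
#'   two walks each).
#' @param param_ranges simulator parameter ranges
#'   ([default_param_ranges()]).
#' @param train_frac training fraction of the stratified grouped split
#'   (default 0.75).
#' @param top_k number of top stability-ranked attributes used by the final
#'   classifier (default 2).
#' @param n_stability stability-ranking iterations (default 100).
#' @param cv_folds wrapper cross-validation folds (default 4).
#' @param wrapper_trees trees of the wrapper classifier inside the search
#'   (default 10).
#' @param final_trees trees of the final classifier (default 50).
#' @param termination_tolerance forward-search stopping tolerance (default
#'   `1e-6`).
#' @param sampling_rate_hz simulator sampling rate (default 100).
#' @param max_features optional cap on attributes per search.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, n_normal = 15L, n_hemi = 20L,
                       param_ranges = default_param_ranges(),
                       train_frac = 0.75, top_k = 2L, n_stability = 100L,
                       cv_folds = 4L, wrapper_trees = 10L, final_trees = 50L,
                       termination_tolerance = 1e-6, sampling_rate_hz = 100,
                       max_features = 6L) {
  structure(as.list(environment()), class = "run_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full detection pipeline
#'
#' Executes simulate (or load) -> trim/calibrate -> extract -> stratified
#' grouped split -> stability-ranked forward selection on the training set ->
#' final bagged-tree fit on the top-ranked attributes -> held-out evaluation,
#' writing every intermediate artifact (recording CSVs, `features.csv`,
#' `stability.csv`, `model_meta.json`, `metrics.json`, `log.txt`) into
#' `out_dir`. Rerunning with the same config reproduces the
#' artifacts bit-identically.
#'
#' @param config a [run_config()].
#' @param out_dir output directory; default a fresh directory under
#'   [tempdir()].
#' @param cohort_dir optional directory of real recordings (layout of
#'   [write_cohort()]); when given, simulation is skipped.
#' @param write_artifacts write the artifact files (default `TRUE`).
#' @return Invisibly, a list with `dataset`, `split`, `ranking`, `selected`,
#'   `model`, `confusion`, `metrics`, `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         cohort_dir = NULL, write_artifacts = TRUE) {
  out_dir <- out_dir %||% file.path(tempdir(), sprintf("hemigait_run_%d", config$seed))
  if (write_artifacts) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 4L)

  cohort <- run_stage("simulate", {
    if (is.null(cohort_dir)) {
      simulate_cohort(config$n_normal, config$n_hemi, config$param_ranges,
                      seed = seeds[1L],
                      sampling_rate_hz = config$sampling_rate_hz)
    } else {
      load_cohort(cohort_dir)
    }
  })
  if (write_artifacts && is.null(cohort_dir)) {
    run_stage("simulate", write_cohort(cohort, file.path(out_dir, "cohort")))
  }

  dataset <- run_stage("extract", cohort_features(cohort))
  if (write_artifacts) {
    write_feature_table(dataset, file.path(out_dir, "features.csv"))
  }

  split <- run_stage("split", {
    stratified_split(dataset, train_frac = config$train_frac,
                     seed = seeds[2L], group_by_subject = TRUE)
  })

  sfs_cfg <- sfs_config(
    termination_tolerance = config$termination_tolerance,
    cv_folds = config$cv_folds,
    classifier_config = forest_config(n_trees = config$wrapper_trees),
    max_features = config$max_features, seed = seeds[3L]
  )
  ranking <- run_stage("select", {
    stability_rank(split$train, sfs_cfg, n_iterations = config$n_stability)
  })
  selected <- utils::head(ranking$ordered, config$top_k)
  if (write_artifacts) {
    write_stability(ranking, file.path(out_dir, "stability.csv"))
  }

  model <- run_stage("train", {
    train_forest(ds_cols(split$train, selected),
                 forest_config(n_trees = config$final_trees, seed = seeds[4L]))
  })
  cm <- run_stage("evaluate", {
    confusion(split$test$labels, predict(model, ds_cols(split$test, selected)))
  })
  mr <- metrics(cm)

  if (write_artifacts) {
    jsonlite::write_json(
      list(seed = config$seed, selected_attributes = selected,
           stability_counts = as.list(ranking$counts[selected]),
           n_trees = config$final_trees, oob_error = model$oob_error,
           n_train = length(split$train$labels),
           n_test = length(split$test$labels)),
      file.path(out_dir, "model_meta.json"), auto_unbox = TRUE, digits = NA
    )
    jsonlite::write_json(
      list(confusion = unclass(cm), metrics = unclass(mr)),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
      na = "null"
    )
    writeLines(c(
      sprintf("hemigait %s", as.character(utils::packageVersion("hemigait"))),
      sprintf("seed: %d", config$seed),
      sprintf("walks: %d train / %d test", length(split$train$labels),
              length(split$test$labels)),
      sprintf("selected attributes: %s", paste(selected, collapse = ", ")),
      sprintf("held-out: SE %.1f SP %.1f AC %.1f PPV %.1f",
              mr$se, mr$sp, mr$ac, mr$ppv)
    ), file.path(out_dir, "log.txt"))
  }

  invisible(list(dataset = dataset, split = split, ranking = ranking,
                 selected = selected, model = model, confusion = cm,
                 metrics = mr, out_dir = out_dir))
}

#' Load a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing `labels.csv` and one recording CSV per
#'   walk.
#' @return A `gait_cohort` (without profiles).
#' @export
load_cohort <- function(dir) {
  lab_path <- file.path(dir, "labels.csv")
  if (!file.exists(lab_path)) {
    abort_hg("cohort directory must contain labels.csv", "hemigait_format_error")
  }
  lab <- utils::read.csv(lab_path, stringsAsFactors = FALSE)
  recs <- lapply(lab$recording_id, function(id) {
    rec <- read_recording(file.path(dir, paste0(id, ".csv")))
    rec$subject_id <- lab$subject_id[lab$recording_id == id]
    rec
  })
  structure(
    list(recordings = recs, labels = as.integer(lab$label),
         subject_ids = as.character(lab$subject_id), walk = lab$walk,
         recording_ids = lab$recording_id, profiles = NULL),
    class = "gait_cohort"
  )
}
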