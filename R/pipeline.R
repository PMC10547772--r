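#' Default pipeline configuration
#'
#' Every setting has a documented default matching the study design where
#' one is stated: SMOTE k = 10 with 100 seeds, 100 Boruta states (internal
#' forest depth 5), mixture K range 1..40, G-mean thresholding. Desk-scale
#' work overrides `n_runs`, `n_states` and the model list.
#'
#' @param ... overrides for any top-level config entry.
#' @return A `run_config` list.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    seed = 1,
    simulate = NULL,                 # synthetic_config(), or NULL
    manifest = NULL,                 # path to a manifest, if not simulating
    smoothing = "gcv",
    min_prominence_frac = 0.005,
    window = NULL,                   # c(lo, hi) analysis window, NULL = full
    k_min = 1, k_max = 40,
    intervals_file = NULL,           # externally supplied intervals TSV
    n_runs = 100, n_states = 100, k_smote = 10,
    boruta_max_iter = 100, boruta_num_trees = 100,
    boruta_fallback_frac = NULL, boruta_include_tentative = FALSE,
    models = "default",              # "default", "reference", or a list
    top_n = 20,
    out_dir = NULL
  )
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Unknown keys are rejected; known keys override [default_run_config()].
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- names(default_run_config())
  bad <- setdiff(names(raw), c(known, "simulate_preset", "simulate_seed"))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$simulate_preset)) {
    raw$simulate <- synthetic_config(preset = raw$simulate_preset,
                                     seed = raw$simulate_seed %||% raw$seed
                                     %||% 1)
    raw$simulate_preset <- NULL; raw$simulate_seed <- NULL
  }
  do.call(default_run_config, raw)
}

resolve_models <- function(models) {
  if (is.character(models))
    switch(models, default = default_model_grid(),
           reference = reference_model_grid(),
           stop("unknown model list: ", models, call. = FALSE))
  else models
}

#' Run the full pipeline
#'
#' Executes preprocess -> interval discovery -> feature engineering ->
#' nested evaluation -> explanation on either a simulated dataset or the
#' spectra referenced by a manifest, and returns a results bundle with a
#' provenance record (settings, seeds, package version). With
#' `config$out_dir` set, artifacts (intervals, feature table, SHAP ranking,
#' results JSON) are also written to disk.
#'
#' @param config a `run_config` from [default_run_config()] or
#'   [read_run_config()].
#' @return A `pipeline_result` list: `dataset`, `preprocessed`, `mixture`,
#'   `intervals`, `features`, `evaluation`, `explanation`, `ranking`,
#'   `provenance`.
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dataset <- stage("load", {
    if (!is.null(config$simulate)) generate_dataset(config$simulate)
    else if (!is.null(config$manifest)) load_dataset(read_manifest(config$manifest))
    else stop("config must set either simulate or manifest")
  })
  pre <- stage("preprocess", {
    out <- lapply(dataset$spectra, preprocess_spectrum,
                  smoothing = config$smoothing)
    if (!is.null(config$window)) {
      out <- lapply(out, function(g) {
        sel <- g$shifts >= config$window[1] & g$shifts <= config$window[2]
        g$shifts <- g$shifts[sel]; g$intensities <- g$intensities[sel]
        normalize_area(g)
      })
    }
    out
  })
  mixture <- NULL
  intervals <- stage("discover-intervals", {
    if (!is.null(config$intervals_file)) {
      tb <- read_table_tsv(config$intervals_file)
      finalize_intervals(as_interval_set(tb$lo, tb$hi))
    } else {
      peaks <- pool_maxima(pre, config$min_prominence_frac)
      mixture <- fit_peak_mixture(peaks, config$k_min, config$k_max,
                                  seed = config$seed)
      finalize_intervals(mixture)
    }
  })
  features <- stage("featurize", build_feature_table(pre, intervals))
  evaluation <- stage("evaluate", evaluate_models(
    features, dataset$class, specs = resolve_models(config$models),
    n_runs = config$n_runs, n_states = config$n_states,
    k_smote = config$k_smote, diagnoses = dataset$diagnosis,
    boruta_args = list(max_iter = config$boruta_max_iter,
                       num_trees = config$boruta_num_trees,
                       fallback_frac = config$boruta_fallback_frac,
                       include_tentative = config$boruta_include_tentative)
  ))
  expl <- stage("explain",
                explain_best_model(evaluation, features, top_n = config$top_n))
  provenance <- list(
    package_version = as.character(utils::packageVersion("ramanprom")),
    settings = config[setdiff(names(config),
                              c("simulate", "models", "out_dir"))],
    models = vapply(resolve_models(config$models), format, ""),
    simulate = if (!is.null(config$simulate))
      config$simulate[setdiff(names(config$simulate), "bands")],
    master_seed = config$seed,
    spectrum_seeds = dataset$seeds,
    boruta_states = seq_len(config$n_states),
    smote_seeds = seq_len(config$n_runs),
    selected_K = if (!is.null(mixture)) mixture$K,
    n_intervals = nrow(intervals),
    n_features = ncol(features)
  )
  res <- structure(
    list(dataset = dataset, preprocessed = pre, mixture = mixture,
         intervals = intervals, features = features,
         evaluation = evaluation, explanation = expl$explanation,
         ranking = expl$ranking, provenance = provenance),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) write_pipeline_artifacts(res, config$out_dir)
  res
}

#' Serialisable results document of a pipeline run
#'
#' @param res a `pipeline_result`.
#' @return A plain list mirroring the results JSON schema.
#' @export
pipeline_results_json <- function(res) {
  ev <- res$evaluation
  list(
    provenance = res$provenance,
    models = ev$model_table,
    best_model = ev$model_table$model[ev$best],
    auc = list(per_model = ev$auc_dists,
               best_median = stats::median(ev$auc_dists[[ev$best]]),
               best_iqr = stats::IQR(ev$auc_dists[[ev$best]])),
    thresholds = ev$thresholds,
    confusion = matrix(as.numeric(ev$aggregate$confusion), 2, 2,
                       dimnames = dimnames(ev$aggregate$confusion)),
    stability_buckets = as.list(stats::setNames(
      as.integer(ev$aggregate$stability_buckets),
      names(ev$aggregate$stability_buckets))),
    per_diagnosis = ev$aggregate$per_diagnosis,
    top_features = res$ranking
  )
}

write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_table(as.data.frame(res$intervals), file.path(out_dir, "intervals.tsv"))
  ft <- data.frame(sample_id = res$dataset$sample_id,
                   as.data.frame(unclass(res$features)), check.names = FALSE)
  write_table(ft, file.path(out_dir, "features.tsv"))
  if (!is.null(res$mixture))
    write_table(res$mixture$components, file.path(out_dir, "mixture.tsv"))
  write_table(res$ranking, file.path(out_dir, "shap_ranking.tsv"))
  sh <- data.frame(sample_id = res$dataset$sample_id,
                   as.data.frame(res$explanation$mean_shap),
                   check.names = FALSE)
  write_table(sh, file.path(out_dir, "shap_values.tsv"))
  jsonlite::write_json(pipeline_results_json(res),
                       file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", matrix = "rowmajor")
  invisible(out_dir)
}
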