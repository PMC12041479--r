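#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end workflow on a paired dataset: feature
#' generation ([compute_features()]), paired per-chip standardization,
#' grouped leave-one-chip-out classification for every requested model,
#' SHAP importance ranking and cross-model similarity, and the per-feature
#' linear mixed-model screen.  When `out_dir` is given, all tabular results
#' are written as CSV together with a JSON manifest (configuration, seed,
#' package version) so every output row is traceable.
#'
#' @param spikes A [spike_tbl()]; alternatively pass `synth_cfg` to generate
#'   data on the fly.
#' @param synth_cfg Optional [synth_config()] used when `spikes` is `NULL`.
#' @param window_s,overlap_pct,bin_s,method,threshold Preprocessing
#'   parameters; defaults are the recommended setting (240 s windows, 75%
#'   overlap, 1 ms bins, Pearson, threshold 0.5).
#' @param models Character vector of model names (default all seven).
#' @param seed Master seed; all stage seeds are derived from it.
#' @param include_sync Keep the Spike-Contrast column (default `TRUE`).
#' @param shap Compute SHAP attributions (default `TRUE`).
#' @param shap_nperm Permutation draws per explained window.
#' @param out_dir Optional output directory for CSV artifacts.
#' @param features Optional precomputed feature table (skips feature
#'   generation; useful to re-run classification from cached features).
#' @return A list of class `mea_run`: `features`, `standardized`, `reports`
#'   (named list of `cv_report`), `auc_summary`, `similarity`, `lmm`,
#'   `config`.
#' @export
run_pipeline <- function(spikes = NULL, synth_cfg = NULL, window_s = 240,
                         overlap_pct = 75, bin_s = 0.001, method = "pearson",
                         threshold = 0.5, models = model_names(), seed = 42L,
                         include_sync = TRUE, shap = TRUE, shap_nperm = 120L,
                         out_dir = NULL, features = NULL) {
  models <- match.arg(models, model_names(), several.ok = TRUE)
  config <- list(window_s = window_s, overlap_pct = overlap_pct,
                 bin_s = bin_s, method = method, threshold = threshold,
                 models = models, seed = seed, include_sync = include_sync,
                 version = as.character(utils::packageVersion("meadrug")))
  if (is.null(features)) {
    if (is.null(spikes)) {
      if (is.null(synth_cfg)) abort("supply `spikes`, `synth_cfg` or `features`")
      spikes <- generate_dataset(synth_cfg)
    }
    features <- compute_features(
      spikes, window_s = window_s, overlap_pct = overlap_pct, bin_s = bin_s,
      method = method, threshold = threshold, include_sync = include_sync,
      seed = derive_seed(seed, "features")
    )
  }
  standardized <- paired_standardize(features)

  reports <- stats::setNames(lapply(models, function(m) {
    grouped_loocv(standardized, model = m,
                  seed = derive_seed(seed, "cv", m),
                  shap = shap, shap_nperm = shap_nperm)
  }), models)

  auc_summary <- purrr::map_dfr(reports, function(r) {
    tibble(model = r$model, auc_lower_ci = r$auc_lower_ci,
           mean_auc = mean(r$splits$auc, na.rm = TRUE))
  })
  similarity <- if (shap && length(reports) >= 2) {
    model_similarity(reports)
  } else {
    NULL
  }
  lmm <- suppressWarnings(lmm_screen(standardized))

  run <- structure(list(features = features, standardized = standardized,
                        reports = reports, auc_summary = auc_summary,
                        similarity = similarity, lmm = lmm, config = config),
                   class = "mea_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$features, file.path(out_dir, "features.csv"))
  readr::write_csv(run$standardized,
                   file.path(out_dir, "features_standardized.csv"))
  splits <- purrr::map_dfr(run$reports, function(r)
    mutate(r$splits, model = r$model))
  readr::write_csv(splits, file.path(out_dir, "auc_per_split.csv"))
  readr::write_csv(run$auc_summary, file.path(out_dir, "auc_summary.csv"))
  rankings <- purrr::map_dfr(run$reports, function(r) {
    if (is.null(r$ranking)) return(tibble())
    mutate(r$ranking, model = r$model)
  })
  if (nrow(rankings) > 0) {
    readr::write_csv(rankings, file.path(out_dir, "shap_ranking.csv"))
  }
  if (!is.null(run$similarity)) {
    sim <- as_tibble(run$similarity, rownames = "model")
    readr::write_csv(sim, file.path(out_dir, "model_similarity.csv"))
  }
  readr::write_csv(run$lmm, file.path(out_dir, "lmm_table.csv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(run$config, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(out_dir)
}

#' @export
print.mea_run <- function(x, ...) {
  cat("MEA drug-effect analysis run\n")
  cat("  windows:", nrow(x$features), " features:",
      length(setdiff(names(x$features), key_cols())), "\n")
  print(x$auc_summary)
  invisible(x)
}

#' Preprocessing parameter sweep
#'
#' Evaluates the Cartesian product of segmentation, binning and correlation
#' settings: for every combination the feature table is recomputed and each
#' requested model scored by its grouped LOO-CV lower-confidence-bound AUC.
#' Spike-Contrast can be excluded (`include_sync = FALSE`) when studying
#' bin-size effects, since synchrony is independent of the bin size and the
#' correlation method.  SHAP is skipped during sweeps.
#'
#' @inheritParams run_pipeline
#' @param window_s,overlap_pct,bin_s,method Vectors of settings to cross.
#' @return A tibble with one row per (combination, model): the settings,
#'   `auc_lower_ci` and `mean_auc`, sorted by decreasing `auc_lower_ci`.
#' @export
parameter_sweep <- function(spikes, window_s = c(60, 120, 240),
                            overlap_pct = c(0, 25, 50, 75),
                            bin_s = c(0.001, 0.01, 0.1),
                            method = c("pearson", "spearman"),
                            models = "svm", seed = 42L,
                            include_sync = TRUE, threshold = 0.5) {
  grid <- tidyr::crossing(window_s = window_s, overlap_pct = overlap_pct,
                          bin_s = bin_s, method = method)
  purrr::pmap_dfr(grid, function(window_s, overlap_pct, bin_s, method) {
    run <- run_pipeline(spikes, window_s = window_s,
                        overlap_pct = overlap_pct, bin_s = bin_s,
                        method = method, threshold = threshold,
                        models = models, seed = seed,
                        include_sync = include_sync, shap = FALSE)
    mutate(run$auc_summary, window_s = window_s, overlap_pct = overlap_pct,
           bin_s = bin_s, method = method, .before = 1)
  }) |>
    arrange(desc(.data$auc_lower_ci))
}
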