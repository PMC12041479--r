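#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a cross-validation report
#'
#' One row per outer split with the held-out chip, its AUC and the tuned
#' parameters.
#'
#' @param x A `cv_report` from [grouped_loocv()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cv_report <- function(x, ...) {
  mutate(x$splits, model = x$model, .before = 1)
}

#' One-row summary of a cross-validation report
#'
#' @inheritParams tidy.cv_report
#' @return A tibble with `model`, `n_splits`, `mean_auc`, `auc_lower_ci`
#'   and the top-ranked feature (when SHAP was computed).
#' @export
glance.cv_report <- function(x, ...) {
  tibble(
    model = x$model,
    n_splits = nrow(x$splits),
    mean_auc = mean(x$splits$auc, na.rm = TRUE),
    auc_lower_ci = x$auc_lower_ci,
    top_feature = if (is.null(x$ranking)) NA_character_ else
      x$ranking$feature[1]
  )
}

#' Tidy a full pipeline run
#'
#' @param x An `mea_run` from [run_pipeline()].
#' @param ... Unused.
#' @return Per-split AUCs of every model, one row per (model, chip).
#' @export
tidy.mea_run <- function(x, ...) {
  purrr::map_dfr(x$reports, tidy)
}

#' @rdname tidy.mea_run
#' @return `glance()`: one row per model with summary AUCs.
#' @export
glance.mea_run <- function(x, ...) {
  purrr::map_dfr(x$reports, glance)
}
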