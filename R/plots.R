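#' @import ggplot2
NULL

#' SHAP importance ranking plot
#'
#' Dot-and-range plot of the median absolute SHAP attribution per feature
#' (range = min/max across cross-validation splits), coloured by whether
#' the feature increased or decreased after the drug.
#'
#' @param report A `cv_report` with SHAP attributions.
#' @param top_n Number of features to show (default all).
#' @return A ggplot object.
#' @export
plot_shap_ranking <- function(report, top_n = Inf) {
  if (is.null(report$ranking)) abort("report has no SHAP ranking")
  df <- utils::head(report$ranking, top_n) |>
    mutate(
      feature = factor(.data$feature, levels = rev(.data$feature)),
      shift = factor(ifelse(.data$direction >= 0, "increased", "decreased"),
                     levels = c("increased", "decreased"))
    )
  ggplot(df, aes(x = .data$median_abs_shap, y = .data$feature,
                 colour = .data$shift)) +
    geom_errorbarh(aes(xmin = .data$min_abs_shap, xmax = .data$max_abs_shap),
                   height = 0.2, alpha = 0.6) +
    geom_point(size = 2) +
    scale_colour_manual(values = c(increased = "#b2182b",
                                   decreased = "#2166ac"),
                        name = "after drug") +
    labs(x = "median |SHAP| (post-drug windows)", y = NULL,
         title = paste0("Feature importance — ", report$model)) +
    theme_minimal()
}

#' @rdname plot_shap_ranking
#' @param object,... Passed from the `autoplot()` generic.
#' @export
autoplot.cv_report <- function(object, ...) plot_shap_ranking(object, ...)

#' Model-similarity heatmap
#'
#' @param similarity Correlation matrix from [model_similarity()].
#' @return A ggplot object.
#' @export
plot_model_similarity <- function(similarity) {
  df <- as_tibble(similarity, rownames = "model_a") |>
    tidyr::pivot_longer(-"model_a", names_to = "model_b",
                        values_to = "correlation")
  ggplot(df, aes(.data$model_a, .data$model_b, fill = .data$correlation)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f", .data$correlation)), size = 3) +
    scale_fill_gradient2(low = "#b2182b", mid = "white", high = "#2166ac",
                         limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, title = "SHAP importance similarity") +
    theme_minimal()
}

#' Per-condition feature distributions
#'
#' Box plots of selected (standardized) features split by condition, the
#' companion view to the LMM screen.
#'
#' @param ft Feature table (typically standardized).
#' @param features Character vector of features to plot.
#' @return A ggplot object.
#' @export
plot_feature_effects <- function(ft, features) {
  df <- as_tibble(ft) |>
    select(all_of(c(key_cols(), features))) |>
    tidyr::pivot_longer(all_of(features), names_to = "feature") |>
    mutate(condition = factor(.data$condition, levels = condition_levels()))
  ggplot(df, aes(.data$condition, .data$value, fill = .data$condition)) +
    geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    facet_wrap(~feature, scales = "free_y") +
    labs(x = NULL, y = "standardized value") +
    theme_minimal()
}
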