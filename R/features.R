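#' Compute the full feature table of a paired dataset
#'
#' Runs the feature-generation half of the workflow: each (chip, condition)
#' recording is segmented into sliding windows, every window is binned into
#' a binary occupancy matrix, correlated into a connectivity graph,
#' thresholded, and summarized by the 25 graph features plus the
#' Spike-Contrast synchrony of the window's raw spike trains.  Stochastic
#' community detection is seeded per (chip, condition, window) so the table
#' is reproducible from `seed`.
#'
#' @param spikes A [spike_tbl()] with one or more paired recordings.
#' @param window_s,overlap_pct Segmentation parameters (defaults 240 s and
#'   75%, the recommended setting).
#' @param bin_s Bin width in seconds (default 1 ms).
#' @param method Correlation method (default `"pearson"`).
#' @param threshold Edge threshold on the raw correlations (default 0.5).
#' @param include_sync Include the `spike_contrast` column (default `TRUE`).
#' @param seed Seed fanned out to the stochastic community methods.
#' @param min_active Minimum active electrodes for a window to be scored;
#'   windows below it get zero features with a warning (default 2).
#' @return A tibble with key columns `chip_id`, `condition`, `window_index`
#'   and one column per feature ([feature_names()]).
#' @export
compute_features <- function(spikes, window_s = 240, overlap_pct = 75,
                             bin_s = 0.001, method = "pearson",
                             threshold = 0.5, include_sync = TRUE,
                             seed = 1L, min_active = 2L) {
  windows <- segment_windows(spikes, window_s, overlap_pct)
  feat_cols <- setdiff(feature_names(), if (!include_sync) "spike_contrast"
                       else character())
  graph_cols <- setdiff(feat_cols, "spike_contrast")
  rows <- purrr::pmap(
    list(windows$chip_id, windows$condition, windows$window_index,
         windows$spikes),
    function(ch, co, k, sp) {
      vals <- stats::setNames(as.list(rep(0, length(feat_cols))), feat_cols)
      n_active <- length(unique(sp$electrode))
      if (n_active >= min_active) {
        binned <- bin_binary(sp, bin_s, window_s)
        graph <- binarize(correlate(binned, method), threshold)
        gf <- graph_features(graph$adjacency,
                             seed = derive_seed(seed, ch, co, k))
        vals[graph_cols] <- gf[graph_cols]
        if (include_sync) {
          sc <- suppressWarnings(
            spike_contrast(sp, duration_s = window_s)$s_max)
          vals$spike_contrast <- sc
        }
      } else {
        warn(paste0("window (", ch, ", ", co, ", ", k,
                    ") has fewer than ", min_active,
                    " active electrodes: features set to 0"))
      }
      as_tibble(c(list(chip_id = ch, condition = co, window_index = k), vals))
    }
  )
  bind_rows(rows)
}
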