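#' Sliding-window segmentation of recordings
#'
#' Each (chip, condition) recording is cut into windows of length `window_s`
#' advancing by `window_s * (1 - overlap_pct / 100)`.  Windows are half-open
#' `[start, start + window_s)` and only fully contained windows are emitted,
#' so for a recording of length `D` there are
#' `floor((D - window_s) / step) + 1` of them.  Spike times are re-referenced
#' to the window start.  The (chip, condition, window) identity travels with
#' every window so that downstream cross-validation can group by chip.
#'
#' @param x A [spike_tbl()] holding one or more recordings.
#' @param window_s Window length in seconds (the study grid is 60, 120,
#'   240 s).
#' @param overlap_pct Percentage overlap between consecutive windows
#'   (0, 25, 50 or 75 in the study grid); must be in `[0, 100)`.
#' @return A tibble with one row per window: `chip_id`, `condition`,
#'   `window_index` (0-based), `start_s`, and a `spikes` list-column of
#'   tibbles with `electrode` and window-referenced `time_s`.  The attribute
#'   `window_s` records the window length.
#' @export
#' @examples
#' cfg <- synth_config(n_chips = 1, duration_s = 600, seed = 1)
#' segment_windows(generate_dataset(cfg), window_s = 240, overlap_pct = 75)
segment_windows <- function(x, window_s, overlap_pct = 0) {
  dur <- duration_s(x)
  if (window_s <= 0) abort("`window_s` must be positive")
  if (window_s > dur) abort("`window_s` exceeds the recording duration")
  if (overlap_pct < 0 || overlap_pct >= 100) {
    abort("`overlap_pct` must be in [0, 100)")
  }
  step <- window_s * (1 - overlap_pct / 100)
  n_win <- floor((dur - window_s) / step) + 1
  starts <- (seq_len(n_win) - 1) * step

  recs <- as_tibble(x) |> distinct(.data$chip_id, .data$condition)
  grid <- tidyr::crossing(recs, tibble(window_index = seq_len(n_win) - 1L,
                                       start_s = starts))
  sp <- as_tibble(x)
  grid$spikes <- purrr::pmap(
    list(grid$chip_id, grid$condition, grid$start_s),
    function(ch, co, s0) {
      sel <- sp$chip_id == ch & sp$condition == co &
        sp$time_s >= s0 & sp$time_s < s0 + window_s
      tibble(electrode = sp$electrode[sel], time_s = sp$time_s[sel] - s0)
    }
  )
  structure(grid, window_s = window_s, overlap_pct = overlap_pct,
            class = class(tibble()))
}

#' Binary binning of one window
#'
#' Converts the spikes of one window into an electrodes-by-bins occupancy
#' matrix: entry 1 when the electrode fired at least once in the bin, else 0.
#' Bin `j` spans `[j * bin_s, (j + 1) * bin_s)` (half-open, so a spike
#' exactly on a boundary belongs to the following bin) and a trailing partial
#' bin is discarded.  Only electrodes that fired in the window get a row —
#' those are the nodes of the connectivity graph.
#'
#' @param window_spikes Tibble with columns `electrode` and `time_s`
#'   (window-referenced), e.g. one element of the `spikes` column of
#'   [segment_windows()].
#' @param bin_s Bin width in seconds (study grid: 0.001, 0.01, 0.1).
#' @param window_s Window length in seconds; `n_bins = floor(window_s /
#'   bin_s)`.
#' @return A sparse 0/1 matrix (electrodes x bins) with electrode ids as row
#'   names and attribute `bin_s`.
#' @export
bin_binary <- function(window_spikes, bin_s, window_s) {
  if (bin_s <= 0) abort("`bin_s` must be positive")
  n_bins <- floor(window_s / bin_s)
  electrodes <- sort(unique(window_spikes$electrode))
  m <- length(electrodes)
  if (m == 0 || n_bins == 0) {
    out <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(m, n_bins))
    rownames(out) <- as.character(electrodes)
    attr(out, "bin_s") <- bin_s
    return(out)
  }
  bin <- floor(window_spikes$time_s / bin_s)
  keep <- bin < n_bins  # trailing partial bin dropped
  row <- match(window_spikes$electrode, electrodes)[keep]
  col <- bin[keep] + 1L
  ij <- unique(cbind(row, col))
  out <- Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2],
                              x = rep(1, nrow(ij)), dims = c(m, n_bins))
  rownames(out) <- as.character(electrodes)
  attr(out, "bin_s") <- bin_s
  out
}
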