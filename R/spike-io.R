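#' Build a validated spike table
#'
#' The canonical in-memory form of MEA spike data is a long tibble with one
#' row per spike and columns `chip_id`, `condition`, `electrode`, `time_s`.
#' `condition` is `"pre_drug"` (class 0, native network) or `"post_drug"`
#' (class 1, drug-exposed network); `electrode` is a 0-based index into the
#' chip's electrode grid.  The recording duration and the set of manually
#' excluded (noisy) electrodes are carried as attributes so that inactive
#' electrodes — present on the chip but without any spikes — are not lost.
#'
#' @param spikes Data frame with columns `chip_id`, `condition`, `electrode`,
#'   `time_s`.  May have zero rows.
#' @param duration_s Recording duration in seconds; every spike time must lie
#'   in `[0, duration_s]`.
#' @param n_electrodes Number of electrodes on the chip (default 60).
#' @param excluded_electrodes Integer vector of 0-based electrode indices to
#'   drop from all downstream analyses.
#'
#' @return A tibble of class `spike_tbl`, sorted by chip, condition,
#'   electrode and time, with attributes `duration_s`, `n_electrodes`
#'   and `excluded_electrodes`.
#' @export
#' @examples
#' spike_tbl(
#'   data.frame(chip_id = "chip1", condition = "pre_drug",
#'              electrode = 0L, time_s = c(0.5, 1.5)),
#'   duration_s = 600
#' )
spike_tbl <- function(spikes, duration_s, n_electrodes = 60L,
                      excluded_electrodes = integer()) {
  spikes <- as_tibble(spikes)
  needed <- c("chip_id", "condition", "electrode", "time_s")
  missing_cols <- setdiff(needed, names(spikes))
  if (length(missing_cols) > 0) {
    abort(paste0("spike table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!is.numeric(duration_s) || length(duration_s) != 1 || duration_s <= 0) {
    abort("`duration_s` must be a single positive number")
  }
  spikes$chip_id <- as.character(spikes$chip_id)
  spikes$condition <- as.character(spikes$condition)
  spikes$electrode <- as.integer(spikes$electrode)
  spikes$time_s <- as.numeric(spikes$time_s)
  assert_condition(spikes$condition)
  bad <- which(spikes$time_s < 0 | spikes$time_s > duration_s)
  if (length(bad) > 0) {
    abort(paste0("spike time out of [0, duration_s] at row ", bad[1],
                 " (t = ", spikes$time_s[bad[1]], ")"))
  }
  if (any(spikes$electrode < 0, na.rm = TRUE)) {
    abort("electrode indices must be non-negative (0-based)")
  }
  spikes <- arrange(spikes, .data$chip_id, .data$condition,
                    .data$electrode, .data$time_s)
  structure(
    spikes,
    duration_s = duration_s,
    n_electrodes = as.integer(n_electrodes),
    excluded_electrodes = as.integer(excluded_electrodes),
    class = c("spike_tbl", class(tibble()))
  )
}

#' @export
#' @rdname spike_tbl
#' @param x Object to query.
duration_s <- function(x) {
  d <- attr(x, "duration_s")
  if (is.null(d)) abort("object has no `duration_s` attribute; use spike_tbl()")
  d
}

#' Read and write spike tables
#'
#' The on-disk interchange format is a long CSV with header
#' `chip_id,condition,electrode,time_s` (UTF-8, `.` decimal separator, times
#' in seconds).  Electrodes absent from the file are inactive: they exist on
#' the chip but fired no spikes.  Reading validates ordering, sign and range
#' of the spike times and reports the first offending row.
#'
#' @param path File path.
#' @param duration_s Declared recording duration in seconds (default 600, a
#'   10-minute MEA recording).  Times beyond it are rejected.
#' @inheritParams spike_tbl
#' @return `read_spike_table()` returns a [spike_tbl()]; `write_spike_table()`
#'   returns `path` invisibly.
#' @export
read_spike_table <- function(path, duration_s = 600, n_electrodes = 60L,
                             excluded_electrodes = integer()) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    chip_id = readr::col_character(),
    condition = readr::col_character(),
    electrode = readr::col_integer(),
    time_s = readr::col_double()
  ))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(paste0("malformed spike table row ", probs$row[1], " in ", path))
  }
  if (anyNA(raw)) {
    abort(paste0("missing value in spike table row ",
                 which(!stats::complete.cases(raw))[1], " in ", path))
  }
  disorder <- raw |>
    mutate(.row = dplyr::row_number()) |>
    group_by(.data$chip_id, .data$condition, .data$electrode) |>
    filter(.data$time_s < dplyr::lag(.data$time_s, default = -Inf)) |>
    ungroup()
  if (nrow(disorder) > 0) {
    abort(paste0("unsorted spike times at row ", min(disorder$.row),
                 " in ", path))
  }
  spike_tbl(raw, duration_s = duration_s, n_electrodes = n_electrodes,
            excluded_electrodes = excluded_electrodes)
}

#' @rdname read_spike_table
#' @param x A spike table.
#' @export
write_spike_table <- function(x, path) {
  out <- as_tibble(x)[, c("chip_id", "condition", "electrode", "time_s")]
  readr::write_csv(out, path)
  invisible(path)
}

#' Raw voltage trace from one electrode
#'
#' @param samples Numeric vector of sampled voltages (arbitrary units).
#' @param sampling_rate_hz Sampling rate in Hz (25000 for the supported
#'   recording setup).
#' @param electrode_id 0-based electrode index.
#' @return An object of class `raw_trace`.
#' @export
raw_trace <- function(samples, sampling_rate_hz = 25000, electrode_id = 0L) {
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    abort("`sampling_rate_hz` must be positive")
  }
  if (length(samples) == 0) abort("`samples` must be non-empty")
  structure(
    list(samples = as.numeric(samples),
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         electrode_id = as.integer(electrode_id),
         blanked = logical(length(samples))),
    class = "raw_trace"
  )
}

#' Blank stimulation artifacts in a raw trace
#'
#' Portions of the signal around large positive peaks (stimulation or
#' movement artifacts) are set to zero: a 6 ms interval before through a
#' 25 ms interval after every sample exceeding `positive_threshold`.  The
#' continuous-time interval `[t_peak - pre_s, t_peak + post_s]` is mapped to
#' sample indices by rounding outward, so blanking is conservative.  The
#' operation is idempotent because blanked samples can no longer exceed the
#' (positive) threshold.
#'
#' @param trace A [raw_trace()].
#' @param positive_threshold Positive voltage threshold; chip-specific and
#'   supplied by the user.
#' @param pre_s,post_s Blanking interval around each peak, in seconds.
#' @return The trace with artifact regions zeroed; the logical `blanked`
#'   element records which samples were zeroed (cumulatively).
#' @export
remove_artifacts <- function(trace, positive_threshold,
                             pre_s = 0.006, post_s = 0.025) {
  stopifnot(inherits(trace, "raw_trace"))
  if (!is.numeric(positive_threshold) || positive_threshold <= 0) {
    abort("`positive_threshold` must be positive")
  }
  fs <- trace$sampling_rate_hz
  n <- length(trace$samples)
  peaks <- which(trace$samples > positive_threshold)
  if (length(peaks) > 0) {
    t_peak <- (peaks - 1) / fs
    lo <- pmax(0L, as.integer(floor((t_peak - pre_s) * fs)))
    hi <- pmin(n - 1L, as.integer(ceiling((t_peak + post_s) * fs)))
    mask <- logical(n)
    for (j in seq_along(lo)) mask[(lo[j] + 1L):(hi[j] + 1L)] <- TRUE
    trace$samples[mask] <- 0
    trace$blanked <- trace$blanked | mask
  }
  trace
}

#' Threshold-based spike detection
#'
#' Spikes are detected at negative-going crossings of a threshold set to
#' `-k_sd` times the standard deviation of the (artifact-free) signal.  The
#' spike time is the time of the first sample at or below threshold in each
#' crossing (the leading edge).  Crossings within `dead_time_s` of the
#' previously accepted spike are suppressed so one waveform is not counted
#' multiple times.
#'
#' @param trace A [raw_trace()], already artifact-cleaned.
#' @param k_sd Threshold multiplier (default 5).
#' @param dead_time_s Refractory dead time in seconds (default 1 ms).
#' @param exclude_blanked If `TRUE`, the SD is computed over non-blanked
#'   samples only; by default blanked zeros are included.
#' @return Sorted numeric vector of spike times in seconds.
#' @export
detect_spikes <- function(trace, k_sd = 5, dead_time_s = 0.001,
                          exclude_blanked = FALSE) {
  stopifnot(inherits(trace, "raw_trace"))
  x <- trace$samples
  ref <- if (exclude_blanked) x[!trace$blanked] else x
  s <- stats::sd(ref)
  if (!is.finite(s) || s == 0) {
    warn("zero-variance trace: no detection threshold definable")
    return(numeric())
  }
  thr <- -k_sd * s
  below <- x <= thr
  crossing <- below & !c(FALSE, below[-length(below)])
  idx <- which(crossing)
  if (length(idx) == 0) return(numeric())
  times <- (idx - 1) / trace$sampling_rate_hz
  kept <- times[1]
  last <- times[1]
  for (t in times[-1]) {
    if (t - last >= dead_time_s) {
      kept <- c(kept, t)
      last <- t
    }
  }
  kept
}

#' Active electrodes of a recording
#'
#' An electrode is active when it recorded at least `min_spikes` spikes and
#' was not manually excluded.  Only active electrodes become nodes of the
#' functional-connectivity graph.
#'
#' @param x A [spike_tbl()] (one chip/condition recording or several).
#' @param min_spikes Minimum spike count (default 1).
#' @return Sorted integer vector of 0-based active electrode indices.
#' @export
active_electrodes <- function(x, min_spikes = 1L) {
  excl <- attr(x, "excluded_electrodes") %||% integer()
  counts <- as_tibble(x) |>
    count(.data$electrode) |>
    filter(.data$n >= min_spikes, !(.data$electrode %in% excl))
  sort(counts$electrode)
}

# Split a multi-recording spike table into per-(chip, condition) tibbles,
# preserving attributes.  Returns a tibble with list-column `spikes`.
split_recordings <- function(x) {
  dur <- duration_s(x)
  ne <- attr(x, "n_electrodes") %||% 60L
  excl <- attr(x, "excluded_electrodes") %||% integer()
  as_tibble(x) |>
    group_by(.data$chip_id, .data$condition) |>
    tidyr::nest(spikes = c("electrode", "time_s")) |>
    ungroup() |>
    mutate(spikes = purrr::pmap(
      list(.data$spikes, .data$chip_id, .data$condition),
      function(sp, ch, co) {
        spike_tbl(tibble(chip_id = ch, condition = co,
                         electrode = sp$electrode, time_s = sp$time_s),
                  duration_s = dur, n_electrodes = ne,
                  excluded_electrodes = excl)
      }
    ))
}
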