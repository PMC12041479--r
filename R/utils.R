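#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Deterministic fan-out of a master seed to per-stage seeds.  A small FNV-1a
# style hash over the label keeps derived seeds reproducible across platforms
# and below 2^31 so they are valid R integer seeds.
derive_seed <- function(master, ...) {
  label <- paste(c(...), collapse = "/")
  h <- as.double(master %% 2147483647L)
  for (b in utf8ToInt(label)) {
    h <- (h * 31 + b) %% 2147483629
  }
  as.integer(h %% 2147483647)
}

# Condition levels used throughout: class 0 is the native (pre-drug) network,
# class 1 the drug-exposed one.
condition_levels <- function() c("pre_drug", "post_drug")

assert_condition <- function(x) {
  bad <- setdiff(unique(as.character(x)), condition_levels())
  if (length(bad) > 0) {
    abort(paste0(
      "`condition` must be one of ",
      paste(condition_levels(), collapse = ", "),
      "; found: ", paste(bad, collapse = ", ")
    ))
  }
  invisible(x)
}

#' Names of the feature panel
#'
#' The 17 scalar complex-network measures, the 8 community average-path-length
#' scalars (one per community-detection algorithm), and the Spike-Contrast
#' synchrony index, in the column order used by [compute_features()].
#'
#' @return Character vector of 26 feature names.
#' @export
feature_names <- function() {
  c(
    "assortativity", "knn", "apl", "bc", "cc", "complexity", "density",
    "diameter", "eccentricity", "ec", "efficiency", "ed", "hub_score",
    "k_core", "mean_degree", "smd", "transitivity",
    "afc", "aic", "alc", "alpc", "aebc", "aspc", "amc", "asc",
    "spike_contrast"
  )
}

# Key columns identifying a window row in a feature table.
key_cols <- function() c("chip_id", "condition", "window_index")
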