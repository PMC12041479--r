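#' Configuration for the paired spike-train simulator
#'
#' The simulator emulates the study design the workflow targets: paired
#' 600-second MEA recordings (pre- and post-drug) from several chips, with
#' background firing, network bursts, per-chip heterogeneity and a subset of
#' silent electrodes.  Each electrode fires homogeneous-Poisson background
#' spikes; network-burst events arrive as a second Poisson process, and at
#' each event every electrode participates independently with the
#' participation probability, emitting `spikes_per_burst` spikes centred on
#' the event time with Gaussian jitter.  The "drug" condition raises burst
#' rate and participation and tightens the jitter, reproducing the
#' hypersynchrony a GABA-A antagonist such as bicuculline induces.  A chip's
#' two conditions share one multiplicative log-normal random effect on rates,
#' mirroring the random-intercept structure assumed by the downstream linear
#' mixed model.
#'
#' @param n_chips Number of chips (default 9).
#' @param n_electrodes Electrodes per chip (default 60).
#' @param duration_s Recording duration in seconds (default 600).
#' @param bg_rate_hz Background firing rate per electrode (default 0.5 Hz).
#' @param burst_rate_hz Network-burst event rate, pre-drug (default 0.2 Hz).
#' @param burst_participation Per-electrode burst participation probability,
#'   pre-drug (default 0.4).
#' @param spikes_per_burst Spikes an electrode emits per joined burst
#'   (default 5).
#' @param burst_jitter_s SD of the Gaussian jitter around the burst time,
#'   pre-drug (default 50 ms).
#' @param chip_effect_sd SD of the log-normal chip random effect multiplying
#'   all rates (default 0.2).
#' @param drug_participation,drug_jitter_s,drug_burst_rate_hz Post-drug
#'   counterparts (defaults 0.9, 10 ms, 0.4 Hz): more bursts, broader
#'   participation, tighter synchrony.
#' @param silenced_fraction Fraction of electrodes silenced at random per
#'   chip, in both conditions (default 0.1), emulating electrodes not covered
#'   by neurons.
#' @param seed Master seed for the generator.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_chips = 9L, n_electrodes = 60L, duration_s = 600,
                         bg_rate_hz = 0.5, burst_rate_hz = 0.2,
                         burst_participation = 0.4, spikes_per_burst = 5L,
                         burst_jitter_s = 0.05, chip_effect_sd = 0.2,
                         drug_participation = 0.9, drug_jitter_s = 0.01,
                         drug_burst_rate_hz = 0.4, silenced_fraction = 0.1,
                         seed = 42L) {
  cfg <- list(
    n_chips = as.integer(n_chips), n_electrodes = as.integer(n_electrodes),
    duration_s = duration_s, bg_rate_hz = bg_rate_hz,
    burst_rate_hz = burst_rate_hz, burst_participation = burst_participation,
    spikes_per_burst = as.integer(spikes_per_burst),
    burst_jitter_s = burst_jitter_s, chip_effect_sd = chip_effect_sd,
    drug_participation = drug_participation, drug_jitter_s = drug_jitter_s,
    drug_burst_rate_hz = drug_burst_rate_hz,
    silenced_fraction = silenced_fraction, seed = as.integer(seed)
  )
  rates <- c("bg_rate_hz", "burst_rate_hz", "drug_burst_rate_hz")
  if (any(unlist(cfg[rates]) < 0)) abort("rates must be non-negative")
  probs <- c("burst_participation", "drug_participation", "silenced_fraction")
  if (any(unlist(cfg[probs]) < 0 | unlist(cfg[probs]) > 1)) {
    abort("probabilities must lie in [0, 1]")
  }
  if (cfg$duration_s <= 0) abort("`duration_s` must be positive")
  structure(cfg, class = "synth_config")
}

#' A null configuration: drug parameters equal to baseline
#'
#' Useful for calibration experiments — the two conditions are exchangeable
#' in distribution, so any detected "effect" is a false positive.
#'
#' @param ... Overrides passed to [synth_config()].
#' @export
null_config <- function(...) {
  synth_config(drug_participation = 0.4, drug_jitter_s = 0.05,
               drug_burst_rate_hz = 0.2, ...)
}

# One condition of one chip: Poisson background + jittered burst events.
simulate_condition <- function(cfg, chip_id, condition, multiplier,
                               silenced, burst_rate, participation, jitter) {
  dur <- cfg$duration_s
  live <- setdiff(seq_len(cfg$n_electrodes) - 1L, silenced)
  times <- vector("list", length(live))
  n_events <- stats::rpois(1, burst_rate * multiplier * dur)
  event_t <- sort(stats::runif(n_events, 0, dur))
  for (j in seq_along(live)) {
    n_bg <- stats::rpois(1, cfg$bg_rate_hz * multiplier * dur)
    t_bg <- stats::runif(n_bg, 0, dur)
    t_burst <- numeric()
    if (n_events > 0) {
      joined <- which(stats::runif(n_events) < participation)
      if (length(joined) > 0) {
        centre <- rep(event_t[joined], each = cfg$spikes_per_burst)
        t_burst <- centre + stats::rnorm(length(centre), 0, jitter)
        t_burst <- pmin(pmax(t_burst, 0), dur)
      }
    }
    tt <- sort(c(t_bg, t_burst))
    # collapse near-coincident spikes (0.1 ms resolution)
    if (length(tt) > 1) tt <- tt[c(TRUE, diff(tt) >= 1e-4)]
    times[[j]] <- tt
  }
  tibble(
    chip_id = chip_id,
    condition = condition,
    electrode = rep(live, lengths(times)),
    time_s = unlist(times) %||% numeric()
  )
}

#' Generate one paired pre/post-drug chip recording
#'
#' @param cfg A [synth_config()].
#' @param chip_index Chip number in `1..cfg$n_chips`.
#' @return A [spike_tbl()] holding both conditions of the chip.
#' @export
generate_chip_pair <- function(cfg, chip_index) {
  stopifnot(inherits(cfg, "synth_config"))
  if (chip_index < 1 || chip_index > cfg$n_chips) {
    abort("`chip_index` out of range")
  }
  chip_id <- sprintf("chip%d", chip_index)
  withr::with_seed(derive_seed(cfg$seed, "chip", chip_index), {
    multiplier <- exp(stats::rnorm(1, 0, cfg$chip_effect_sd))
    n_silent <- floor(cfg$silenced_fraction * cfg$n_electrodes)
    silenced <- sort(sample(seq_len(cfg$n_electrodes) - 1L, n_silent))
    pre <- simulate_condition(cfg, chip_id, "pre_drug", multiplier, silenced,
                              cfg$burst_rate_hz, cfg$burst_participation,
                              cfg$burst_jitter_s)
    post <- simulate_condition(cfg, chip_id, "post_drug", multiplier, silenced,
                               cfg$drug_burst_rate_hz, cfg$drug_participation,
                               cfg$drug_jitter_s)
  })
  spike_tbl(bind_rows(pre, post), duration_s = cfg$duration_s,
            n_electrodes = cfg$n_electrodes)
}

#' Generate a full paired dataset
#'
#' @param cfg A [synth_config()].
#' @return A [spike_tbl()] with `2 * n_chips` recordings (pre and post drug
#'   for every chip), fully reproducible from `cfg$seed`.
#' @export
#' @examples
#' cfg <- synth_config(n_chips = 2, duration_s = 60, seed = 1)
#' spikes <- generate_dataset(cfg)
#' dplyr::count(spikes, chip_id, condition)
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  pairs <- purrr::map(seq_len(cfg$n_chips),
                      function(i) as_tibble(generate_chip_pair(cfg, i)))
  spike_tbl(bind_rows(pairs), duration_s = cfg$duration_s,
            n_electrodes = cfg$n_electrodes)
}
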