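test_that("generator produces the configured pairing, reproducibly", {
  cfg <- synth_config(n_chips = 3, duration_s = 60, seed = 5)
  ds <- generate_dataset(cfg)
  recs <- dplyr::count(ds, chip_id, condition)
  expect_equal(nrow(recs), 6)  # 3 chips x 2 conditions
  expect_setequal(unique(recs$condition), c("pre_drug", "post_drug"))

  ds2 <- generate_dataset(cfg)
  expect_identical(as.data.frame(ds), as.data.frame(ds2))

  ds3 <- generate_dataset(synth_config(n_chips = 3, duration_s = 60, seed = 6))
  counts_a <- dplyr::count(ds, electrode)$n
  counts_b <- dplyr::count(ds3, electrode)$n
  expect_false(identical(counts_a, counts_b))
})

test_that("zero rates produce empty recordings", {
  cfg <- synth_config(n_chips = 1, duration_s = 30, bg_rate_hz = 0,
                      burst_rate_hz = 0, drug_burst_rate_hz = 0, seed = 2)
  expect_equal(nrow(generate_dataset(cfg)), 0)
})

test_that("spike times respect the recording window and train ordering", {
  cfg <- synth_config(n_chips = 2, duration_s = 45, seed = 9)
  ds <- generate_dataset(cfg)
  expect_true(all(ds$time_s >= 0 & ds$time_s <= 45))
  ord <- ds |>
    dplyr::group_by(chip_id, condition, electrode) |>
    dplyr::summarise(ok = !is.unsorted(time_s), .groups = "drop")
  expect_true(all(ord$ok))
})

test_that("a fraction of electrodes is silenced consistently across the pair", {
  cfg <- synth_config(n_chips = 4, duration_s = 60, seed = 3)
  ds <- generate_dataset(cfg)
  per_chip <- ds |>
    dplyr::group_by(chip_id, condition) |>
    dplyr::summarise(active = dplyr::n_distinct(electrode), .groups = "drop")
  # 10% of 60 electrodes silenced -> at most 54 can be active
  expect_true(all(per_chip$active <= 54))
  # silenced set is shared between conditions of a chip
  for (ch in unique(ds$chip_id)) {
    pre <- unique(ds$electrode[ds$chip_id == ch & ds$condition == "pre_drug"])
    post <- unique(ds$electrode[ds$chip_id == ch & ds$condition == "post_drug"])
    expect_setequal(setdiff(0:59, pre), setdiff(0:59, post))
  }
})

test_that("mean spike count per electrode matches the rate model", {
  # E[count] = duration * (bg + burst_rate * participation * spikes_per_burst)
  # * chip multiplier; average the multiplier out over many replicate chips
  cfg <- synth_config(n_chips = 50, n_electrodes = 20, duration_s = 60,
                      chip_effect_sd = 0.1, silenced_fraction = 0,
                      seed = 21)
  ds <- generate_dataset(cfg)
  pre <- ds[ds$condition == "pre_drug", ]
  # electrodes within a chip share the event process and the chip effect, so
  # aggregate to independent per-chip means before comparing
  per_chip <- pre |>
    dplyr::count(chip_id, electrode) |>
    dplyr::group_by(chip_id) |>
    dplyr::summarise(mean_count = sum(n) / cfg$n_electrodes)
  expected <- cfg$duration_s *
    (cfg$bg_rate_hz + cfg$burst_rate_hz * cfg$burst_participation *
       cfg$spikes_per_burst) * exp(cfg$chip_effect_sd^2 / 2)
  se <- sd(per_chip$mean_count) / sqrt(nrow(per_chip))
  expect_lt(abs(mean(per_chip$mean_count) - expected), 3 * se)
})

test_that("tight jitter and full participation drive synchrony toward 1", {
  vals <- vapply(1:10, function(s) {
    cfg <- synth_config(n_chips = 1, n_electrodes = 20, duration_s = 60,
                        bg_rate_hz = 0, drug_participation = 1,
                        drug_jitter_s = 0.001, drug_burst_rate_hz = 0.3,
                        silenced_fraction = 0, seed = 100 + s)
    ds <- generate_dataset(cfg)
    post <- ds[ds$condition == "post_drug", ]
    spike_contrast(post, duration_s = 60)$s_max
  }, numeric(1))
  expect_gte(mean(vals), 0.9)
})

test_that("null configuration makes the two conditions exchangeable", {
  # with drug_* equal to baseline, pre/post Spike-Contrast differences
  # should straddle zero rather than favour one condition
  diffs <- vapply(1:12, function(s) {
    cfg <- null_config(n_chips = 1, n_electrodes = 15, duration_s = 60,
                       silenced_fraction = 0, seed = 300 + s)
    ds <- generate_dataset(cfg)
    pre <- spike_contrast(ds[ds$condition == "pre_drug", ],
                          duration_s = 60)$s_max
    post <- spike_contrast(ds[ds$condition == "post_drug", ],
                           duration_s = 60)$s_max
    post - pre
  }, numeric(1))
  expect_gt(mean(sign(diffs) == 1), 0.1)
  expect_lt(mean(sign(diffs) == 1), 0.9)
})
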