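test_that("spike tables parse from CSV and reject malformed input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("chip_id,condition,electrode,time_s",
               "chip1,pre_drug,0,0.5",
               "chip1,pre_drug,0,1.5"), path)
  sts <- read_spike_table(path, duration_s = 600)
  expect_equal(nrow(sts), 2)
  expect_equal(active_electrodes(sts), 0L)
  expect_equal(sts$time_s, c(0.5, 1.5))

  writeLines("chip_id,condition,electrode,time_s", path)
  empty <- read_spike_table(path, duration_s = 600)
  expect_equal(nrow(empty), 0)
  expect_equal(active_electrodes(empty), integer())

  writeLines(c("chip_id,condition,electrode,time_s",
               "chip1,pre_drug,0,2.0",
               "chip1,pre_drug,0,1.0"), path)
  expect_error(read_spike_table(path, duration_s = 600), "unsorted.*row 2")

  writeLines(c("chip_id,condition,electrode,time_s",
               "chip1,pre_drug,0,-1.0"), path)
  expect_error(read_spike_table(path, duration_s = 600), "row")

  writeLines(c("chip_id,condition,electrode,time_s",
               "chip1,pre_drug,0,601.0"), path)
  expect_error(read_spike_table(path, duration_s = 600), "row")
})

test_that("write/read round-trips random spike sets bit-exactly", {
  withr::local_seed(42)
  for (i in 1:20) {
    sts <- rand_spike_set()
    path <- withr::local_tempfile(fileext = ".csv")
    write_spike_table(sts, path)
    back <- read_spike_table(path, duration_s = duration_s(sts),
                             n_electrodes = attr(sts, "n_electrodes"))
    expect_identical(as.data.frame(back), as.data.frame(sts))
    # and write(read(x)) reproduces the file byte-for-byte
    path2 <- withr::local_tempfile(fileext = ".csv")
    write_spike_table(back, path2)
    expect_identical(readLines(path), readLines(path2))
  }
})

test_that("artifact blanking zeroes the outward-rounded window around peaks", {
  fs <- 25000
  n <- fs  # 1 s of samples
  x <- rep(0.1, n)
  x[0.1 * fs + 1] <- 5  # single supra-threshold sample at t = 0.1 s
  tr <- raw_trace(x, fs)
  out <- remove_artifacts(tr, positive_threshold = 1)
  zeroed <- which(out$samples == 0) - 1L  # 0-based
  expect_equal(range(zeroed), c(2350, 3125))
  expect_equal(sum(out$samples == 0), 3125 - 2350 + 1)
  expect_true(all(out$samples[-(zeroed + 1L)] == 0.1))
})

test_that("artifact blanking handles no-peak, overlap-union and idempotence", {
  fs <- 1000
  x <- rnorm(2000, sd = 0.01)
  tr <- raw_trace(x, fs)
  expect_identical(remove_artifacts(tr, 1)$samples, x)

  # two peaks 10 ms apart: blanked regions overlap and union
  x2 <- rep(0, 2000)
  x2[c(501, 511)] <- 5
  out <- remove_artifacts(raw_trace(x2, fs), 1)
  z <- which(out$blanked) - 1L
  lo1 <- floor((500 / fs - 0.006) * fs); hi1 <- ceiling((500 / fs + 0.025) * fs)
  lo2 <- floor((510 / fs - 0.006) * fs); hi2 <- ceiling((510 / fs + 0.025) * fs)
  expect_setequal(z, union(lo1:hi1, lo2:hi2))

  again <- remove_artifacts(out, 1)
  expect_identical(again$samples, out$samples)
  expect_error(remove_artifacts(tr, 0), "positive")
})

test_that("spike detection finds leading-edge crossings with dead time", {
  fs <- 25000
  withr::local_seed(7)
  noise <- rnorm(fs, sd = 1)
  noise <- pmax(noise, -4.5)  # no excursion below -5*sd possible
  got <- detect_spikes(raw_trace(noise / sd(noise), fs))
  expect_length(got, 0)

  # flat trace with calibration noise plus one deep rectangular pulse
  base <- rnorm(fs, sd = 0.1)
  s_eff <- sd(base)
  x <- base
  pulse_at <- 5000L  # 0-based sample index of leading edge
  x[pulse_at + 1:25] <- -10 * s_eff
  tr <- raw_trace(x, fs)
  spikes <- detect_spikes(tr)
  expect_length(spikes, 1)
  expect_equal(spikes, pulse_at / fs, tolerance = 1e-12)

  # two pulses 0.5 ms apart with 1 ms dead time -> one spike
  x2 <- base
  x2[pulse_at + 1:5] <- -10 * s_eff
  x2[pulse_at + 13 + 1:5] <- -10 * s_eff  # 0.52 ms later
  expect_length(detect_spikes(raw_trace(x2, fs)), 1)
  expect_length(detect_spikes(raw_trace(x2, fs), dead_time_s = 0.0001), 2)

  expect_warning(got0 <- detect_spikes(raw_trace(rep(0, 100), fs)), "zero")
  expect_length(got0, 0)
})

test_that("spike count is non-increasing in dead time", {
  fs <- 10000
  withr::local_seed(11)
  x <- rnorm(fs, sd = 0.1)
  x[sample(fs, 50)] <- -2  # many deep excursions
  tr <- raw_trace(x, fs)
  counts <- vapply(c(0, 0.0005, 0.001, 0.005, 0.02),
                   function(dt) length(detect_spikes(tr, dead_time_s = dt)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("active electrodes honour min_spikes and exclusions", {
  sp <- tibble::tibble(
    chip_id = "c1", condition = "pre_drug",
    electrode = rep(c(0L, 1L, 2L), times = c(4, 5, 6)),
    time_s = seq(0.1, by = 0.1, length.out = 15)
  )
  sts <- spike_tbl(sp, duration_s = 10)
  expect_equal(active_electrodes(sts), c(0L, 1L, 2L))
  expect_equal(active_electrodes(sts, min_spikes = 5), c(1L, 2L))
  sts_ex <- spike_tbl(sp, duration_s = 10, excluded_electrodes = 1L)
  expect_equal(active_electrodes(sts_ex, min_spikes = 5), 2L)
})
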