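test_that("thresholding assembles maximal runs into half-hop-padded events", {
  expect_equal(nrow(threshold_and_assemble(rep(0.2, 938), 0.5)), 0L)

  scores <- rep(0, 938)
  scores[101:163] <- 0.9          # 0-based frames 100..162
  ev <- threshold_and_assemble(scores, 0.5)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$onset, 100 * 0.016 - 0.008)
  expect_equal(ev$offset, 162 * 0.016 + 0.008)
  expect_equal(c(ev$first_frame, ev$last_frame), c(100L, 162L))

  split <- rep(0, 938)
  split[10:20] <- 1; split[22:30] <- 1   # one sub-threshold frame between
  expect_equal(nrow(threshold_and_assemble(split, 0.5)), 2L)

  # 469-length sequences use the doubled hop
  s469 <- rep(0, 469); s469[11:20] <- 1
  ev469 <- threshold_and_assemble(s469, 0.5)
  expect_equal(ev469$onset, 10 * 0.032 - 0.016)
})

test_that("energy peaks locate the dominant bin with low-bin tie-breaks", {
  spec <- stft_logspec(tone_recording(250))
  expect_equal(energy_peak(2, 3, spec), 250)

  two <- lung_recording(0.4 * sin(2 * pi * 250 * (0:(N15 - 1)) / SR) +
                        0.2 * sin(2 * pi * 600 * (0:(N15 - 1)) / SR), SR)
  expect_equal(energy_peak(2, 3, stft_logspec(two)), 250)

  silent <- stft_logspec(lung_recording(numeric(N15), SR))
  expect_equal(energy_peak(1, 2, silent), 0)   # all-zero ties -> lowest bin

  expect_error(energy_peak(20, 21, spec), "overlaps no frame")
})

test_that("merging follows the gap and peak-difference rules", {
  spec <- fake_spectrogram(rep(19, 938))    # constant 296.875 Hz peak
  cfg <- postprocess_config()

  near_same <- data.frame(onset = c(1.0, 2.1), offset = c(1.8, 2.9))
  merged <- merge_events(near_same, spec, cfg)   # gap 0.3 < 0.5, dp = 0 < 25
  expect_equal(nrow(merged), 1L)
  expect_equal(c(merged$onset, merged$offset), c(1.0, 2.9))

  far_same <- data.frame(onset = c(1.0, 2.4), offset = c(1.8, 3.0))
  expect_equal(nrow(merge_events(far_same, spec, cfg)), 2L)  # gap 0.6 >= T

  # near in time but spectrally apart: first event peaks near 100 Hz,
  # second near 400 Hz
  bins <- rep(NA_integer_, 938)
  bins[seq_len(938) - 1 <= 113] <- 6    # ~93.75 Hz up to 1.8 s
  bins[seq_len(938) - 1 >= 131] <- 26   # ~406 Hz from 2.1 s
  spec2 <- fake_spectrogram(bins)
  apart <- data.frame(onset = c(1.0, 2.1), offset = c(1.8, 2.9))
  expect_equal(nrow(merge_events(apart, spec2, cfg)), 2L)
})

test_that("burst removal uses a strict duration threshold", {
  ev <- data.frame(onset = c(0, 1, 2), offset = c(0.05, 2.04 - 1, 2.06))
  out <- remove_bursts(ev)
  expect_equal(out$onset, c(0, 2))   # exactly 0.05 and 0.06 kept; 0.04 deleted
})

test_that("with zero thresholds postprocessing is the identity on assembled events", {
  set.seed(41)
  scores <- as.numeric(stats::runif(938) > 0.7)
  spec <- fake_spectrogram(sample(0:128, 938, replace = TRUE))
  cfg <- postprocess_config(threshold = 0.5, merge_gap_s = 0,
                            peak_diff_hz = 0, min_duration_s = 0)
  raw <- threshold_and_assemble(scores, 0.5)
  out <- postprocess_events(scores, spec, cfg)
  expect_equal(out$onset, raw$onset)
  expect_equal(out$offset, raw$offset)
})

test_that("merging never shrinks coverage; burst removal never adds events", {
  set.seed(42)
  for (rep in 1:25) {
    ev <- random_intervals(sample(1:8, 1), span = 14)
    spec <- fake_spectrogram(sample(0:40, 938, replace = TRUE))
    cfg <- postprocess_config()
    merged <- merge_events(ev, spec, cfg)
    cover <- function(e) sum(e$offset - e$onset)
    expect_gte(cover(merged) + 1e-12, cover(ev))
    expect_lte(nrow(remove_bursts(merged, cfg)), nrow(merged))
  }
})

test_that("merge and burst removal are idempotent", {
  set.seed(43)
  for (rep in 1:25) {
    ev <- random_intervals(sample(2:8, 1), span = 14)
    spec <- fake_spectrogram(sample(c(10, 11, 30), 938, replace = TRUE))
    cfg <- postprocess_config()
    once <- remove_bursts(merge_events(ev, spec, cfg), cfg)
    twice <- remove_bursts(merge_events(once, spec, cfg), cfg)
    expect_equal(twice$onset, once$onset)
    expect_equal(twice$offset, once$offset)
  }
})

test_that("the scan-to-fixed-point merger matches the brute-force oracle", {
  set.seed(44)
  for (rep in 1:250) {
    n <- sample(0:8, 1)
    ev <- random_intervals(n, span = sample(c(5, 10, 15), 1))
    # few distinct peak bins so that peak coincidences actually occur
    spec <- fake_spectrogram(sample(c(5, 6, 20, 60), 938, replace = TRUE))
    cfg <- postprocess_config(
      merge_gap_s = sample(c(0.2, 0.5, 1.0), 1),
      peak_diff_hz = sample(c(20, 40, 300), 1),
      min_duration_s = sample(c(0, 0.05, 0.2), 1)
    )
    got <- merge_events(ev, spec, cfg)
    got <- remove_bursts(got, cfg)
    want <- oracle_postprocess(ev, spec, cfg)
    expect_equal(got$onset, want$onset, tolerance = 1e-12)
    expect_equal(got$offset, want$offset, tolerance = 1e-12)
  }
})
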