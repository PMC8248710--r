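test_that("high-pass filter attenuates the stop band and passes the pass band", {
  rms <- function(x) sqrt(mean(x^2))
  hum <- tone_recording(60, amp = 1)
  out <- highpass(hum)
  expect_equal(length(out$samples), N15)
  expect_lt(20 * log10(rms(out$samples) / rms(hum$samples)), -20)
  breath <- tone_recording(500, amp = 1)
  out2 <- highpass(breath)
  expect_lt(abs(20 * log10(rms(out2$samples) / rms(breath$samples))), 1)
  silent <- lung_recording(numeric(N15), SR)
  expect_equal(highpass(silent)$samples, numeric(N15))
  expect_error(highpass(hum, cutoff_hz = 2500), "Nyquist")
})

test_that("a 15-s recording maps to a 938 x 129 spectrogram on the right axes", {
  spec <- stft_logspec(tone_recording(250))
  expect_equal(dim(spec$logmag), c(938L, 129L))
  expect_equal(dim(spec$power), c(938L, 129L))
  expect_equal(spec$freq_hz[1], 0)
  expect_equal(spec$freq_hz[2], 15.625)
  expect_equal(spec$freq_hz[129], 2000)
  expect_equal(spec$time_s[2] - spec$time_s[1], 0.016)
  expect_error(stft_logspec(lung_recording(numeric(1000), SR)), "938")
})

test_that("pure tones localize at their bin and silence sits at the log floor", {
  spec <- stft_logspec(tone_recording(250))
  am <- apply(spec$logmag, 1, which.max) - 1   # 0-based bin
  expect_gte(mean(am == 16), 0.95)             # 250 / 15.625 = 16
  spec2 <- stft_logspec(tone_recording(500))
  am2 <- apply(spec2$logmag, 1, which.max) - 1
  expect_gte(mean(am2 == 32), 0.95)
  silent <- stft_logspec(lung_recording(numeric(N15), SR))
  expect_true(all(silent$logmag == silent$logmag[1, 1]))
  expect_equal(silent$logmag[1, 1], 20 * log10(1e-10))
})

test_that("MFCC block has 60 aligned columns with flat deltas for a steady tone", {
  # 250 Hz completes an integer number of cycles per hop, so every frame
  # sees an identical waveform and the cepstra are exactly stationary
  mf <- mfcc_block(tone_recording(250))
  expect_equal(dim(mf), c(938L, 60L))
  # delta and acceleration vanish away from the edges
  expect_lt(max(abs(mf[50:888, 21:60])), 1e-8)
})

test_that("band energies partition the axis and track tone frequency", {
  spec <- stft_logspec(tone_recording(300))
  be <- band_energy(spec)
  expect_equal(dim(be), c(938L, 4L))
  # 300 Hz lies in band 2 (250-500 Hz)
  expect_true(all(be[, 2] >= pmax(be[, 1], be[, 3])))
  # full-range band dominates every sub-band
  expect_true(all(be[, 4] >= be[, 1] & be[, 4] >= be[, 2] & be[, 4] >= be[, 3]))
})

test_that("band energy is monotone under amplitude scaling (pre-normalization)", {
  r1 <- tone_recording(420, amp = 0.3)
  r2 <- lung_recording(r1$samples * 2.5, SR)
  b1 <- band_energy(stft_logspec(r1))
  b2 <- band_energy(stft_logspec(r2))
  expect_true(all(b2 >= b1))
})

test_that("assembled features are 938 x 193 in [0,1] with min-max columns", {
  fe <- extract_features(generate_recording(synth_config(seed = 4))$recording)
  expect_equal(dim(fe$values), c(938L, 193L))
  expect_gte(min(fe$values), 0)
  expect_lte(max(fe$values), 1)
  rng <- apply(fe$values, 2, function(col) c(min(col), max(col)))
  non_const <- rng[2, ] > rng[1, ]
  expect_true(all(rng[1, non_const] == 0))
  expect_true(all(rng[2, non_const] == 1))
})

test_that("constant columns normalize to zero and normalization is idempotent", {
  silent <- lung_recording(numeric(N15), SR)
  fe <- extract_features(silent)
  expect_true(all(fe$values == 0))
  m <- cbind(stats::runif(50), rep(3, 50), stats::rnorm(50))
  once <- lungsed:::minmax_columns(m)
  expect_equal(lungsed:::minmax_columns(once), once)
  expect_true(all(once[, 2] == 0))
})

test_that("frame-count mismatches are a hard error, never silent padding", {
  spec <- stft_logspec(tone_recording(250))
  mf <- mfcc_block(spec)
  be <- band_energy(spec)
  expect_error(assemble_features(spec, mf[1:900, ], be), "mismatch")
  expect_error(assemble_features(spec, mf, be[1:900, ]), "mismatch")
  expect_s3_class(assemble_features(spec, mf, be), "lung_features")
})

test_that("zero-phase filtering preserves event timing", {
  # an amplitude burst must stay centered after filtering
  x <- numeric(N15)
  idx <- 30000:31000
  x[idx] <- sin(2 * pi * 400 * (idx / SR))
  rec <- lung_recording(x, SR)
  out <- highpass(rec)
  centroid <- function(s) sum(seq_along(s) * s^2) / sum(s^2)
  expect_lt(abs(centroid(out$samples) - centroid(rec$samples)), 20)
})
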