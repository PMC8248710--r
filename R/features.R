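# Feature pipeline: 60,000-sample recording -> 938 x 193 normalized matrix.
# Framing convention: Hann window 256, hop 64, centered (the signal is
# zero-padded by 128 samples on each side), no FFT zero-padding beyond the
# window, giving 1 + floor(60000/64) = 938 frames of 129 bins
# (0..2000 Hz in steps of 4000/256 = 15.625 Hz).

N_FFT <- 256L
HOP <- 64L
N_FRAMES <- 938L
N_BINS <- 129L
BIN_HZ <- 4000 / 256           # 15.625 Hz
FRAME_S <- 64 / 4000           # 0.016 s
LOG_EPS <- 1e-10

frame_times <- function(n_frames = N_FRAMES) (seq_len(n_frames) - 1) * FRAME_S

freq_axis <- function() (seq_len(N_BINS) - 1) * BIN_HZ

# -- High-pass filter --------------------------------------------------------

# Butterworth high-pass as cascaded biquads. The analog low-pass prototype
# poles exp(i*pi*(2k+n-1)/(2n)) are high-pass transformed (s -> wc/s) and
# discretized by the bilinear transform with prewarped cutoff; each
# conjugate pole pair yields one second-order section with unit gain at
# Nyquist. Cascading sections keeps the order-10 design numerically stable
# where a single transfer-function realization is fragile.
butter_highpass_sos <- function(order, cutoff_hz, fs) {
  if (cutoff_hz >= fs / 2) stop("cutoff must be below Nyquist (", fs / 2, " Hz)")
  if (order %% 2 != 0) stop("even filter order required")
  K <- 2 * fs
  wc <- K * tan(pi * cutoff_hz / fs)
  k <- seq_len(order / 2)
  theta <- pi * (2 * k + order - 1) / (2 * order)
  p_lp <- complex(modulus = 1, argument = theta)   # left-half-plane, upper
  p_hp <- wc / p_lp
  lapply(seq_along(p_hp), function(i) {
    re <- Re(p_hp[i]); m <- Mod(p_hp[i])^2
    a0 <- K^2 - 2 * re * K + m
    list(
      b = c(K^2, -2 * K^2, K^2) / a0,
      a = c(1, (-2 * K^2 + 2 * m) / a0, (K^2 + 2 * re * K + m) / a0)
    )
  })
}

#' High-pass filter a recording
#'
#' Removes mains interference and most heart-sound energy with a 10th-order
#' Butterworth high-pass at 80 Hz, applied forward and backward
#' (zero-phase) so event onset times are not shifted. Realized as cascaded
#' second-order sections for numerical stability.
#'
#' @param rec a [lung_recording].
#' @param order filter order (even), default 10.
#' @param cutoff_hz cutoff frequency in Hz, default 80.
#' @return the filtered [lung_recording], same length and rate.
#' @export
highpass <- function(rec, order = 10, cutoff_hz = 80) {
  stopifnot(inherits(rec, "lung_recording"))
  sos <- butter_highpass_sos(order, cutoff_hz, rec$sample_rate)
  x <- rec$samples
  for (sec in sos) {
    x <- signal::filtfilt(sec$b, sec$a, x)
  }
  lung_recording(x, rec$sample_rate, id = rec$id, source = rec$source)
}

# -- STFT --------------------------------------------------------------------

# Periodic Hann window, as standard for STFT analysis.
hann_periodic <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

# Core framing + FFT; returns the one-sided magnitude (n_frames x 129).
stft_mag <- function(samples) {
  n <- length(samples)
  nf <- 1L + n %/% HOP
  padded <- c(numeric(N_FFT / 2), samples, numeric(N_FFT / 2))
  idx <- outer(seq_len(N_FFT), (seq_len(nf) - 1L) * HOP, `+`)
  frames <- matrix(padded[idx], nrow = N_FFT) * hann_periodic(N_FFT)
  spec <- stats::mvfft(frames)[seq_len(N_BINS), , drop = FALSE]
  t(Mod(spec))
}

#' Log-magnitude spectrogram of a 15-s recording
#'
#' Windows the signal with a 256-point Hann window at hop 64 (centered) and
#' returns the 938 x 129 log-magnitude spectrogram,
#' `20*log10(|X| + 1e-10)`. The linear power spectrogram `|X|^2` is kept
#' alongside for band-energy sums and event energy peaks, which are power
#' quantities computed before any normalization.
#'
#' @param rec a [lung_recording] with exactly 60,000 samples.
#' @return an object of class `lung_spectrogram` with elements `logmag`
#'   (938 x 129), `power` (938 x 129), `freq_hz` (129 bin centers) and
#'   `time_s` (938 frame centers).
#' @export
stft_logspec <- function(rec) {
  stopifnot(inherits(rec, "lung_recording"))
  n <- length(rec$samples)
  if (n != STANDARD_SAMPLES) {
    stop("unexpected signal length: ", n, " samples gives ", 1L + n %/% HOP,
         " frames (expected 60,000 samples / ", N_FRAMES, " frames)")
  }
  mag <- stft_mag(rec$samples)
  structure(
    list(logmag = 20 * log10(mag + LOG_EPS),
         power = mag^2,
         freq_hz = freq_axis(),
         time_s = frame_times(nrow(mag))),
    class = "lung_spectrogram"
  )
}

#' @export
print.lung_spectrogram <- function(x, ...) {
  cat(sprintf("<lung_spectrogram> %d frames x %d bins (0-%g Hz, hop %g s)\n",
              nrow(x$logmag), ncol(x$logmag), max(x$freq_hz), FRAME_S))
  invisible(x)
}

# -- MFCC --------------------------------------------------------------------

hz_to_mel <- function(f) {
  # Slaney scale: linear below 1 kHz, logarithmic above.
  ifelse(f < 1000, f / (200 / 3), 15 + log(f / 1000) / (log(6.4) / 27))
}
mel_to_hz <- function(m) {
  ifelse(m < 15, m * 200 / 3, 1000 * exp((m - 15) * log(6.4) / 27))
}

# Triangular mel filterbank (n_mels x n_bins), Slaney area normalization.
mel_filterbank <- function(n_mels = 40, fmin = 0, fmax = 4000) {
  edges <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2))
  f <- freq_axis()
  fb <- matrix(0, n_mels, length(f))
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; ce <- edges[m + 1]; hi <- edges[m + 2]
    up <- (f - lo) / (ce - lo)
    down <- (hi - f) / (hi - ce)
    w <- pmax(0, pmin(up, down))
    fb[m, ] <- w * 2 / (hi - lo)
  }
  fb
}

# Orthonormal DCT-II matrix (n_out x n_in).
dct_matrix <- function(n_out, n_in) {
  k <- seq_len(n_out) - 1
  n <- seq_len(n_in) - 1
  mat <- cos(pi / n_in * outer(k, n + 0.5))
  mat <- mat * sqrt(2 / n_in)
  mat[1, ] <- mat[1, ] / sqrt(2)
  mat
}

# Regression delta over +-N neighbours (width = 2N+1), edge-replicated.
delta_regression <- function(x, width = 9) {
  N <- (width - 1) %/% 2
  Tn <- nrow(x)
  padded <- rbind(x[rep(1, N), , drop = FALSE], x, x[rep(Tn, N), , drop = FALSE])
  denom <- 2 * sum((1:N)^2)
  out <- matrix(0, Tn, ncol(x))
  for (n in 1:N) {
    out <- out + n * (padded[(N + 1 + n):(N + Tn + n), , drop = FALSE] -
                      padded[(N + 1 - n):(N + Tn - n), , drop = FALSE])
  }
  out / denom
}

#' MFCC block: 20 static + 20 delta + 20 acceleration coefficients
#'
#' Computes mel-frequency cepstral coefficients on the same 256/64 framing
#' as the spectrogram: 40 mel bands spanning 0-4,000 Hz on the power
#' spectrogram, log compression, orthonormal DCT-II, first 20 coefficients
#' (including coefficient 0). Delta and acceleration coefficients use a
#' width-9 regression window, so the block is 60 columns per frame.
#'
#' @param x a [lung_recording] (60,000 samples) or a `lung_spectrogram`.
#' @param n_mfcc number of static coefficients, default 20.
#' @param delta_width regression window width, default 9.
#' @return a 938 x 60 matrix: columns 1-20 static, 21-40 delta, 41-60
#'   acceleration.
#' @export
mfcc_block <- function(x, n_mfcc = 20, delta_width = 9) {
  spec <- if (inherits(x, "lung_spectrogram")) x else stft_logspec(x)
  melspec <- spec$power %*% t(mel_filterbank())
  logmel <- 10 * log10(pmax(melspec, LOG_EPS))
  static <- logmel %*% t(dct_matrix(n_mfcc, ncol(logmel)))
  d1 <- delta_regression(static, delta_width)
  d2 <- delta_regression(d1, delta_width)
  out <- cbind(static, d1, d2)
  colnames(out) <- c(sprintf("mfcc%02d", seq_len(n_mfcc) - 1),
                     sprintf("mfcc_d%02d", seq_len(n_mfcc) - 1),
                     sprintf("mfcc_dd%02d", seq_len(n_mfcc) - 1))
  out
}

# -- Band energy -------------------------------------------------------------

BAND_EDGES <- list(c(0, 250), c(250, 500), c(500, 1000), c(0, 2000))

#' Per-frame spectral energy sums in four frequency bands
#'
#' Sums the power spectrogram over bins whose center frequency falls in
#' 0-250, 250-500, 500-1,000 and 0-2,000 Hz (half-open bands `[lo, hi)`,
#' except that the full-range band includes the topmost bin so it spans the
#' whole axis). Energy is the squared linear magnitude, computed before
#' normalization.
#'
#' @param spec a `lung_spectrogram`.
#' @return a 938 x 4 matrix of band energies.
#' @export
band_energy <- function(spec) {
  stopifnot(inherits(spec, "lung_spectrogram"))
  f <- spec$freq_hz
  out <- sapply(seq_along(BAND_EDGES), function(i) {
    lo <- BAND_EDGES[[i]][1]; hi <- BAND_EDGES[[i]][2]
    sel <- if (hi >= max(f)) f >= lo else f >= lo & f < hi
    rowSums(spec$power[, sel, drop = FALSE])
  })
  colnames(out) <- c("e0_250", "e250_500", "e500_1000", "e0_2000")
  out
}

# -- Assembly ----------------------------------------------------------------

#' Assemble and normalize the 938 x 193 feature matrix
#'
#' Concatenates the log spectrogram (129), the MFCC block (60) and the band
#' energies (4) and min-max scales every column independently to `[0, 1]`
#' within the recording. A constant column maps to all zeros.
#'
#' @param spec a `lung_spectrogram`.
#' @param mfcc a 938 x 60 MFCC block.
#' @param bands a 938 x 4 band-energy matrix.
#' @return an object of class `lung_features`: list with `values`
#'   (938 x 193, in `[0,1]`), `time_s` and the originating `spectrogram`.
#' @export
assemble_features <- function(spec, mfcc, bands) {
  stopifnot(inherits(spec, "lung_spectrogram"))
  nf <- nrow(spec$logmag)
  if (nrow(mfcc) != nf || nrow(bands) != nf) {
    stop("frame-count mismatch: spectrogram ", nf, ", MFCC ", nrow(mfcc),
         ", bands ", nrow(bands))
  }
  raw <- cbind(spec$logmag, mfcc, bands)
  values <- minmax_columns(raw)
  structure(
    list(values = values, time_s = spec$time_s, spectrogram = spec),
    class = "lung_features"
  )
}

minmax_columns <- function(m) {
  lo <- apply(m, 2, min)
  hi <- apply(m, 2, max)
  rng <- hi - lo
  # numerically constant columns (range at rounding-noise level) -> 0
  const <- rng <= 1e-9 * pmax(1, abs(lo), abs(hi))
  rng[const] <- Inf
  sweep(sweep(m, 2, lo, `-`), 2, rng, `/`)
}

#' @export
print.lung_features <- function(x, ...) {
  cat(sprintf("<lung_features> %d frames x %d features in [0,1]\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Full feature pipeline for one recording
#'
#' High-pass filters the signal, then computes the spectrogram, MFCC block
#' and band energies and assembles the normalized 938 x 193 feature matrix.
#'
#' @param rec a 60,000-sample [lung_recording].
#' @param hp_order,hp_cutoff_hz high-pass design parameters.
#' @return a `lung_features` object.
#' @export
extract_features <- function(rec, hp_order = 10, hp_cutoff_hz = 80) {
  filtered <- highpass(rec, order = hp_order, cutoff_hz = hp_cutoff_hz)
  spec <- stft_logspec(filtered)
  assemble_features(spec, mfcc_block(spec), band_energy(spec))
}
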