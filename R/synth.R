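# Synthetic annotated lung-sound generator. Emulates the statistical
# structure of the real corpus (event counts and mean durations, audible-
# exhalation probability, tonal CAS vs impulsive DAS character, background
# noise at a configurable SNR) so that every downstream stage is testable
# without any external download. It does not attempt physiological airway
# acoustics or device transfer functions.

#' Configuration for the synthetic lung-sound generator
#'
#' Defaults reproduce the corpus-level statistics of the real database:
#' mean inhalation duration 0.93 s, mean exhalation 0.96 s, mean CAS
#' (wheeze/stridor/rhonchus) duration 0.83 s, mean DAS (crackle period)
#' duration 0.89 s, and an audible-exhalation probability of 0.55 (the
#' ratio of exhalation to inhalation label counts). Event durations are
#' drawn from a log-normal truncated to `[0.2, 3]` s with log-sd
#' `dur_sigma`. Crackles are rendered as trains of damped impulses, each
#' shorter than `crackle_impulse_ms` (the single explosive sound of a
#' crackle is generally under 25 ms; labels cover the containing period).
#'
#' @param seed integer; fully determines the generated audio and labels.
#' @param n_cycles breath cycles per 15-s recording.
#' @param mean_I_dur,mean_E_dur,mean_CAS_dur,mean_DAS_dur mean event
#'   durations in seconds.
#' @param dur_sigma log-sd of the event duration distribution.
#' @param p_exhalation_audible probability that a cycle's exhalation is
#'   audible (and hence labeled and rendered).
#' @param cas_rate expected CAS events per recording (Poisson).
#' @param cas_class_mix probabilities of W, S, R for each CAS event.
#' @param das_rate expected DAS events (crackle trains) per recording.
#' @param crackle_impulse_ms duration of one crackle impulse, < 25 ms.
#' @param crackles_per_s impulse rate range within a DAS event.
#' @param snr_db signal-to-noise ratio of events over background, in dB.
#' @param noise_kind background noise: white, pink, 60-Hz hum, or
#'   ventilator-like periodic broadband bursts uncorrelated with labels.
#' @return a `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_cycles = 3.5,
                         mean_I_dur = 0.93,
                         mean_E_dur = 0.96,
                         dur_sigma = 0.25,
                         p_exhalation_audible = 0.55,
                         cas_rate = 1.4,
                         cas_class_mix = c(W = 8457, S = 686, R = 4740) / 13883,
                         mean_CAS_dur = 0.83,
                         das_rate = 1.6,
                         mean_DAS_dur = 0.89,
                         crackle_impulse_ms = 15,
                         crackles_per_s = c(5, 20),
                         snr_db = 15,
                         noise_kind = c("white", "pink", "hum60", "ventilator")) {
  noise_kind <- match.arg(noise_kind)
  stopifnot(mean_I_dur > 0, mean_E_dur > 0, mean_CAS_dur > 0, mean_DAS_dur > 0,
            crackle_impulse_ms < 25, crackle_impulse_ms > 0,
            p_exhalation_audible >= 0, p_exhalation_audible <= 1)
  structure(
    list(seed = as.integer(seed), n_cycles = n_cycles,
         mean_I_dur = mean_I_dur, mean_E_dur = mean_E_dur,
         dur_sigma = dur_sigma,
         p_exhalation_audible = p_exhalation_audible,
         cas_rate = cas_rate, cas_class_mix = cas_class_mix,
         mean_CAS_dur = mean_CAS_dur,
         das_rate = das_rate, mean_DAS_dur = mean_DAS_dur,
         crackle_impulse_ms = crackle_impulse_ms,
         crackles_per_s = crackles_per_s,
         snr_db = snr_db, noise_kind = noise_kind),
    class = "synth_config"
  )
}

# Truncated log-normal event duration with the configured mean.
rduration <- function(n, mean_s, sigma, lo = 0.2, hi = 3) {
  mu <- log(mean_s) - sigma^2 / 2
  d <- stats::rlnorm(n, mu, sigma)
  pmin(pmax(d, lo), hi)
}

# Raised-cosine attack/decay envelope over n samples.
ad_envelope <- function(n, attack = 0.25, decay = 0.3) {
  na <- max(1L, round(n * attack)); nd <- max(1L, round(n * decay))
  env <- rep(1, n)
  env[seq_len(na)] <- 0.5 - 0.5 * cos(pi * seq_len(na) / na)
  env[(n - nd + 1):n] <- 0.5 + 0.5 * cos(pi * seq_len(nd) / nd)
  env
}

# Band-limited noise burst (breath phase body).
noise_burst <- function(n, lo_hz, hi_hz, fs) {
  bf <- signal::butter(4, c(lo_hz, hi_hz) / (fs / 2), type = "pass")
  x <- signal::filter(bf, stats::rnorm(n + 200))
  as.numeric(x)[201:(n + 200)]
}

tone_freq_for_class <- function(class) {
  # Standard auscultation reading: rhonchus is low-pitched, stridor
  # high-pitched, wheeze in between.
  switch(class,
    W = stats::runif(1, 150, 1000),
    S = stats::runif(1, 500, 1500),
    R = stats::runif(1, 100, 200))
}

background_noise <- function(n, kind, fs) {
  switch(kind,
    white = stats::rnorm(n),
    pink = {
      w <- stats::rnorm(n)
      s <- stats::fft(w)
      f <- c(1, seq_len(n - 1))
      f <- pmin(f, n - f + 1)
      Re(stats::fft(s / sqrt(f), inverse = TRUE)) / n
    },
    hum60 = {
      t <- (seq_len(n) - 1) / fs
      sin(2 * pi * 60 * t) + 0.4 * sin(2 * pi * 120 * t) +
        0.2 * sin(2 * pi * 180 * t) + 0.15 * stats::rnorm(n)
    },
    ventilator = {
      # periodic broadband bursts, phase-anchored to the clock and thus
      # uncorrelated with the breath labels
      x <- 0.1 * stats::rnorm(n)
      period <- round(fs * stats::runif(1, 2.5, 3.5))
      burst_len <- round(fs * 0.3)
      starts <- seq(round(fs * stats::runif(1, 0, 2)), n - burst_len, by = period)
      for (s in starts) {
        idx <- s:(s + burst_len - 1)
        x[idx] <- x[idx] + noise_burst(burst_len, 300, 900, fs) *
          ad_envelope(burst_len, 0.3, 0.3)
      }
      x
    })
}

#' Generate one annotated synthetic 15-s recording
#'
#' Lays out breath cycles (inhalation, optional audible exhalation) along
#' 15 s, superimposes CAS events as harmonic tones (class-dependent center
#' frequency) and DAS events as trains of sub-25-ms damped impulses, and
#' adds background noise at the configured SNR. Every rendered acoustic
#' event carries exactly one label; the seed fully determines the output.
#'
#' @param config a [synth_config].
#' @return list with elements `recording` (a [lung_recording]) and
#'   `events` (a [lung_events] table).
#' @export
generate_recording <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  fs <- STANDARD_SR
  dur_s <- 15
  n <- STANDARD_SAMPLES
  # feasibility: each cycle needs at least its mean phase durations plus
  # minimal pauses
  min_cycle <- config$mean_I_dur +
    config$p_exhalation_audible * config$mean_E_dur + 0.5
  if (config$n_cycles * min_cycle > dur_s) {
    stop("overcrowded: ", config$n_cycles, " cycles of ~", round(min_cycle, 2),
         " s cannot fit into 15 s")
  }

  x <- numeric(n)
  onset <- numeric(); offset <- numeric(); cls <- character()
  add_event <- function(a, b, k) {
    onset <<- c(onset, a); offset <<- c(offset, b); cls <<- c(cls, k)
  }
  clip_idx <- function(a, b) (max(1L, round(a * fs) + 1L)):(min(n, round(b * fs)))

  # -- breath cycles ---------------------------------------------------------
  period <- dur_s / config$n_cycles
  t0 <- stats::runif(1, 0.1, 0.6)
  i_amp_base <- 0.35
  while (TRUE) {
    di <- rduration(1, config$mean_I_dur, config$dur_sigma)
    if (t0 + di > dur_s - 0.05) break
    idx <- clip_idx(t0, t0 + di)
    amp <- i_amp_base * stats::runif(1, 0.8, 1.2)
    x[idx] <- x[idx] + amp * noise_burst(length(idx), 100, 1200, fs) *
      ad_envelope(length(idx))
    add_event(t0, t0 + di, "I")
    te <- t0 + di + stats::runif(1, 0.15, 0.45)
    if (stats::runif(1) < config$p_exhalation_audible) {
      de <- rduration(1, config$mean_E_dur, config$dur_sigma)
      if (te + de < dur_s - 0.05) {
        idx <- clip_idx(te, te + de)
        x[idx] <- x[idx] + 0.5 * amp * noise_burst(length(idx), 100, 800, fs) *
          ad_envelope(length(idx), 0.35, 0.35)
        add_event(te, te + de, "E")
      }
    }
    t0 <- t0 + period * stats::runif(1, 0.85, 1.15)
    if (t0 >= dur_s - 0.3) break
  }

  # -- CAS: harmonic tones ---------------------------------------------------
  n_cas <- stats::rpois(1, config$cas_rate)
  for (k in seq_len(n_cas)) {
    cas_class <- sample(names(config$cas_class_mix), 1, prob = config$cas_class_mix)
    dc <- rduration(1, config$mean_CAS_dur, config$dur_sigma)
    a <- stats::runif(1, 0.2, dur_s - dc - 0.2)
    idx <- clip_idx(a, a + dc)
    f0 <- tone_freq_for_class(cas_class)
    tt <- (seq_along(idx) - 1) / fs
    tone <- sin(2 * pi * f0 * tt + stats::runif(1, 0, 2 * pi))
    if (2 * f0 < fs / 2) tone <- tone + 0.4 * sin(2 * pi * 2 * f0 * tt)
    if (3 * f0 < fs / 2) tone <- tone + 0.15 * sin(2 * pi * 3 * f0 * tt)
    x[idx] <- x[idx] + 0.25 * tone * ad_envelope(length(idx), 0.2, 0.2)
    add_event(a, a + dc, cas_class)
  }

  # -- DAS: crackle trains ---------------------------------------------------
  n_das <- stats::rpois(1, config$das_rate)
  imp_len <- round(fs * config$crackle_impulse_ms / 1000)
  for (k in seq_len(n_das)) {
    dd <- rduration(1, config$mean_DAS_dur, config$dur_sigma)
    a <- stats::runif(1, 0.2, dur_s - dd - 0.2)
    rate <- stats::runif(1, config$crackles_per_s[1], config$crackles_per_s[2])
    n_imp <- max(2L, stats::rpois(1, rate * dd))
    starts <- sort(stats::runif(n_imp, a, a + dd - config$crackle_impulse_ms / 1000))
    for (s in starts) {
      idx <- clip_idx(s, s + config$crackle_impulse_ms / 1000)
      tt <- (seq_along(idx) - 1) / fs
      fc <- stats::runif(1, 200, 800)
      x[idx] <- x[idx] + 0.45 * exp(-tt / 0.003) * sin(2 * pi * fc * tt)
    }
    add_event(a, a + dd, "D")
  }

  # -- background noise at the configured SNR --------------------------------
  noise <- background_noise(n, config$noise_kind, fs)
  sig_pow <- mean(x^2)
  if (sig_pow > 0) {
    target_noise_pow <- sig_pow / 10^(config$snr_db / 10)
    noise <- noise * sqrt(target_noise_pow / mean(noise^2))
  } else {
    noise <- noise * 0.01 / sqrt(mean(noise^2))
  }
  x <- x + noise
  peak <- max(abs(x))
  if (peak > 0.99) x <- x * 0.99 / peak

  rec <- lung_recording(x, fs, id = sprintf("synth_%08d", config$seed),
                        source = "synth")
  list(recording = rec, events = lung_events(onset, offset, cls))
}

#' Generate a dataset of synthetic recordings with a grouped manifest
#'
#' Writes `n` WAV + label-TSV pairs and a manifest CSV assigning each
#' recording to a synthetic subject/day group (contiguous blocks), the key
#' used for leakage-free grouped cross-validation. With
#' `manifest_only = TRUE` only the manifest is produced (no audio is
#' rendered), which is sufficient for dataset accounting.
#'
#' @param n number of recordings.
#' @param config a [synth_config]; recording `i` uses seed
#'   `config$seed + i - 1`.
#' @param out_dir output directory (created if needed).
#' @param recordings_per_group manifest group size, default 10.
#' @param manifest_only if TRUE, skip audio/label rendering.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return the manifest data frame (id, wav, labels, group, duration_s),
#'   with attribute `total_duration_min`.
#' @export
generate_dataset <- function(n, config = synth_config(), out_dir = NULL,
                             recordings_per_group = 10,
                             manifest_only = FALSE, overwrite = FALSE) {
  ids <- sprintf("synth_%05d", seq_len(n))
  groups <- sprintf("g%04d", ((seq_len(n) - 1) %/% recordings_per_group) + 1)
  manifest <- data.frame(
    id = ids,
    wav = if (manifest_only) NA_character_ else file.path(out_dir, paste0(ids, ".wav")),
    labels = if (manifest_only) NA_character_ else file.path(out_dir, paste0(ids, "_label.txt")),
    group = groups,
    duration_s = rep(15, n),
    stringsAsFactors = FALSE
  )
  attr(manifest, "total_duration_min") <- sum(manifest$duration_s) / 60
  if (manifest_only) return(manifest)

  stopifnot(!is.null(out_dir))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite) {
    stop("output directory ", out_dir, " is not empty (use overwrite = TRUE)")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n)) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    out <- generate_recording(cfg)
    write_wav(out$recording, manifest$wav[i])
    write_labels(out$events, manifest$labels[i])
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Total duration of a manifest in minutes
#'
#' @param manifest a manifest data frame from [generate_dataset()].
#' @return total duration in minutes.
#' @export
manifest_total_minutes <- function(manifest) sum(manifest$duration_s) / 60
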