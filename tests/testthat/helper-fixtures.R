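# Shared fixtures and independent oracles used across the suite.

SR <- 4000L
N15 <- 60000L

tone_recording <- function(freq_hz, amp = 0.5, n = N15, sr = SR, id = "tone") {
  t <- (seq_len(n) - 1) / sr
  lung_recording(amp * sin(2 * pi * freq_hz * t), sr, id = id)
}

# Write a raw PCM WAVE file with arbitrary channel count / rate, so the
# reader's rejections can be exercised (the package writer is mono-only).
write_raw_wav <- function(path, ints_by_channel, sample_rate = SR, bits = 16L) {
  n_ch <- length(ints_by_channel)
  n <- length(ints_by_channel[[1]])
  inter <- integer(n * n_ch)
  for (c in seq_len(n_ch)) inter[seq(c, n * n_ch, by = n_ch)] <- ints_by_channel[[c]]
  con <- file(path, "wb")
  on.exit(close(con))
  bytes_per <- bits / 8
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + bytes_per * n * n_ch), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(as.integer(n_ch), con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per * n_ch), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per * n_ch), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(bytes_per * n * n_ch), con, size = 4, endian = "little")
  writeBin(as.integer(inter), con, size = 2, endian = "little")
  path
}

# Synthetic spectrogram whose per-frame power peaks at a prescribed bin,
# for exercising energy peaks and merging without audio.
fake_spectrogram <- function(peak_bin_by_frame, n_bins = 129, peak_power = 10) {
  nf <- length(peak_bin_by_frame)
  power <- matrix(1e-6, nf, n_bins)
  for (i in seq_len(nf)) {
    if (!is.na(peak_bin_by_frame[i])) {
      power[i, peak_bin_by_frame[i] + 1] <- peak_power
    }
  }
  structure(
    list(logmag = 10 * log10(power + 1e-10), power = power,
         freq_hz = (seq_len(n_bins) - 1) * 15.625,
         time_s = (seq_len(nf) - 1) * 0.016),
    class = "lung_spectrogram"
  )
}

# -- brute-force merge oracle ------------------------------------------------
# Repeatedly rebuilds the full adjacency scan from scratch and merges the
# leftmost eligible pair (gap strictly below the threshold, recomputed
# energy-peak difference strictly below the threshold) until no pair is
# eligible, then deletes short events.
oracle_postprocess <- function(events, spec, config) {
  ev <- events[order(events$onset), , drop = FALSE]
  peaks <- vapply(seq_len(nrow(ev)), function(i) {
    energy_peak(ev$onset[i], ev$offset[i], spec)
  }, numeric(1))
  repeat {
    merged <- FALSE
    if (nrow(ev) >= 2) {
      for (i in seq_len(nrow(ev) - 1)) {
        gap <- ev$onset[i + 1] - ev$offset[i]
        if (gap < config$merge_gap_s &&
            abs(peaks[i + 1] - peaks[i]) < config$peak_diff_hz) {
          ev$offset[i] <- max(ev$offset[i], ev$offset[i + 1])
          ev <- ev[-(i + 1), , drop = FALSE]
          peaks <- peaks[-(i + 1)]
          peaks[i] <- energy_peak(ev$onset[i], ev$offset[i], spec)
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  keep <- (ev$offset - ev$onset) >= config$min_duration_s
  out <- ev[keep, c("onset", "offset"), drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random disjoint sorted intervals in [0, span].
random_intervals <- function(n, span = 15, min_len = 0.05) {
  if (n == 0) return(data.frame(onset = numeric(), offset = numeric()))
  cuts <- sort(stats::runif(2 * n, 0, span))
  on <- cuts[seq(1, 2 * n, 2)]; off <- cuts[seq(2, 2 * n, 2)]
  short <- off - on < min_len
  off[short] <- pmin(span, on[short] + min_len)
  data.frame(onset = on, offset = off)
}

# -- exhaustive event-matching oracle ---------------------------------------
# Enumerates all one-to-one assignments between predictions and truths,
# keeps one maximizing total JI, and derives TP (assigned pair with
# JI > 0.5), FP (prediction overlapping nothing), FN (the rest), plus
# ground-truth events overlapped by no prediction.
oracle_match <- function(pred, truth) {
  np <- nrow(pred); nt <- nrow(truth)
  ji <- function(i, j) {
    inter <- max(0, min(pred$offset[i], truth$offset[j]) -
                    max(pred$onset[i], truth$onset[j]))
    if (inter == 0) return(0)
    inter / (max(pred$offset[i], truth$offset[j]) -
             min(pred$onset[i], truth$onset[j]))
  }
  jim <- matrix(0, max(np, 1), max(nt, 1))
  if (np > 0 && nt > 0) {
    for (i in 1:np) for (j in 1:nt) jim[i, j] <- ji(i, j)
  }
  best <- list(total = -1, assign = rep(0L, np))
  recurse <- function(i, used, assign, total) {
    if (i > np) {
      if (total > best$total + 1e-12) best <<- list(total = total, assign = assign)
      return()
    }
    recurse(i + 1L, used, assign, total)  # i unassigned
    if (nt > 0) {
      for (j in which(!used)) {
        if (jim[i, j] > 0) {
          used2 <- used; used2[j] <- TRUE
          assign2 <- assign; assign2[i] <- j
          recurse(i + 1L, used2, assign2, total + jim[i, j])
        }
      }
    }
  }
  recurse(1L, rep(FALSE, max(nt, 1)), rep(0L, max(np, 1)), 0)
  assign <- best$assign[seq_len(np)]
  tp <- sum(vapply(seq_len(np), function(i) {
    assign[i] > 0 && jim[i, assign[i]] > 0.5
  }, logical(1)))
  best_ji <- if (np > 0 && nt > 0) apply(jim[seq_len(np), seq_len(nt), drop = FALSE], 1, max)
             else rep(0, np)
  fp <- sum(best_ji == 0)
  fn <- np - tp - fp
  missed <- if (nt > 0 && np > 0) {
    sum(apply(jim[seq_len(np), seq_len(nt), drop = FALSE], 2, max) == 0)
  } else nt
  list(tp = tp, fp = fp, fn = fn, missed = missed, fn_total = fn + missed)
}

# Mann-Whitney closed form for the AUC of pooled scores.
rank_auc <- function(scores, truth) {
  y <- as.integer(truth > 0)
  r <- rank(scores)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
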