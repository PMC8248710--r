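# Event postprocessing: threshold the per-frame score sequence into
# events, merge events split by short sub-threshold gaps when their
# spectral energy peaks agree, then delete burst events. Defaults: merge
# gap threshold T = 0.5 s, peak-frequency difference threshold P = 25 Hz,
# minimum event duration 0.05 s.

#' Postprocessing configuration
#'
#' @param threshold detection threshold on the per-frame score.
#' @param merge_gap_s maximum inter-event gap (seconds) eligible for
#'   merging; merging requires the gap to be strictly smaller.
#' @param peak_diff_hz maximum energy-peak frequency difference (Hz);
#'   merging requires the difference to be strictly smaller.
#' @param min_duration_s events strictly shorter than this are deleted.
#' @return a `postprocess_config` list.
#' @export
postprocess_config <- function(threshold = 0.5, merge_gap_s = 0.5,
                               peak_diff_hz = 25, min_duration_s = 0.05) {
  stopifnot(threshold >= 0, threshold <= 1, merge_gap_s >= 0,
            peak_diff_hz >= 0, min_duration_s >= 0)
  structure(list(threshold = threshold, merge_gap_s = merge_gap_s,
                 peak_diff_hz = peak_diff_hz, min_duration_s = min_duration_s),
            class = "postprocess_config")
}

#' Threshold a score sequence and assemble detected events
#'
#' Maximal runs of frames with score >= threshold become events; an
#' event spans from the first frame's center minus half a hop to the last
#' frame's center plus half a hop. CNN-fronted 469-length sequences use a
#' doubled hop so times remain in seconds of the original recording.
#'
#' @param scores numeric vector of per-frame scores in `[0, 1]`.
#' @param threshold detection threshold.
#' @param hop_s frame hop in seconds; 0.016 for 938-frame sequences,
#'   0.032 for 469-frame sequences (default picks by length).
#' @return data frame with `onset`, `offset`, `first_frame`, `last_frame`.
#' @export
threshold_and_assemble <- function(scores, threshold = 0.5, hop_s = NULL) {
  if (is.null(hop_s)) hop_s <- if (length(scores) == 469) 2 * FRAME_S else FRAME_S
  frames_to_intervals(as.numeric(scores >= threshold), hop_s = hop_s)
}

#' Spectral energy peak of an event
#'
#' Returns the bin-center frequency maximizing the mean pre-normalization
#' spectral energy (squared linear magnitude) over the event's frames;
#' ties break to the lowest bin.
#'
#' @param onset,offset event interval in seconds.
#' @param spec a `lung_spectrogram`.
#' @return peak frequency in Hz.
#' @export
energy_peak <- function(onset, offset, spec) {
  stopifnot(inherits(spec, "lung_spectrogram"))
  sel <- spec$time_s >= onset & spec$time_s <= offset
  if (!any(sel)) stop("event [", onset, ", ", offset, "] overlaps no frame")
  prof <- colMeans(spec$power[sel, , drop = FALSE])
  spec$freq_hz[which.max(prof)]   # which.max ties -> lowest bin
}

#' Merge events separated by short gaps with matching energy peaks
#'
#' Scans left to right over onset-sorted events: when the gap to the next
#' event is strictly smaller than `merge_gap_s` and the energy-peak
#' difference is strictly smaller than `peak_diff_hz`, the two are
#' replaced by one event spanning both; its peak is recomputed and the
#' scan resumes at the merged event's left neighbour, since the new peak
#' may enable a merge on either side. The scan therefore runs to a fixed
#' point: no adjacent pair of the result is mergeable.
#'
#' @param events data frame with `onset`, `offset` (sorted by onset) and
#'   optionally `peak_hz`.
#' @param spec a `lung_spectrogram` used to (re)compute energy peaks.
#' @param config a [postprocess_config].
#' @return merged events with `peak_hz`, sorted and non-overlapping.
#' @export
merge_events <- function(events, spec, config = postprocess_config()) {
  if (nrow(events) == 0) {
    return(data.frame(onset = numeric(), offset = numeric(), peak_hz = numeric()))
  }
  ev <- events[order(events$onset), , drop = FALSE]
  if (is.null(ev$peak_hz)) {
    ev$peak_hz <- vapply(seq_len(nrow(ev)), function(i) {
      energy_peak(ev$onset[i], ev$offset[i], spec)
    }, numeric(1))
  }
  onset <- ev$onset; offset <- ev$offset; peak <- ev$peak_hz
  i <- 1L
  while (i < length(onset)) {
    gap <- onset[i + 1] - offset[i]
    if (gap < config$merge_gap_s && abs(peak[i + 1] - peak[i]) < config$peak_diff_hz) {
      offset[i] <- max(offset[i], offset[i + 1])
      peak[i] <- energy_peak(onset[i], offset[i], spec)
      onset <- onset[-(i + 1)]; offset <- offset[-(i + 1)]; peak <- peak[-(i + 1)]
      i <- max(i - 1L, 1L)   # the new peak may unlock the left neighbour
    } else {
      i <- i + 1L
    }
  }
  data.frame(onset = onset, offset = offset, peak_hz = peak)
}

#' Delete burst events
#'
#' Removes events whose duration is strictly shorter than
#' `min_duration_s` (default 0.05 s); an event of exactly the minimum
#' duration is kept. Applied after merging.
#'
#' @param events data frame with `onset`, `offset`.
#' @param config a [postprocess_config].
#' @return the filtered events, order preserved.
#' @export
remove_bursts <- function(events, config = postprocess_config()) {
  keep <- (events$offset - events$onset) >= config$min_duration_s
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full postprocessing of a prediction sequence
#'
#' Threshold, assemble, merge (when a spectrogram is supplied) and delete
#' bursts.
#'
#' @param scores per-frame scores.
#' @param spec a `lung_spectrogram`, or NULL to skip peak-based merging.
#' @param config a [postprocess_config].
#' @return data frame of detected events (`onset`, `offset`, `peak_hz`
#'   when merging was applied).
#' @export
postprocess_events <- function(scores, spec = NULL,
                               config = postprocess_config()) {
  ev <- threshold_and_assemble(scores, config$threshold)
  ev <- ev[, c("onset", "offset")]
  if (!is.null(spec)) {
    ev <- merge_events(ev, spec, config)
  }
  remove_bursts(ev, config)
}
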