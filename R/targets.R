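# Frame-level target construction: event intervals -> binary sequences
# aligned with the 938-frame (or 469-frame, CNN-fronted) model output.

#' Convert event labels to a per-frame binary target sequence
#'
#' Frame `i` (0-based) has center time `i * 0.016` s and is labeled 1 iff
#' that center lies inside any event of the task's class(es); CAS pools the
#' W, S and R labels. Membership is by center-point inclusion with closed
#' interval endpoints, which reproduces event spans to within one hop.
#'
#' @param events a [lung_events] table (raw classes).
#' @param task one of `"I"`, `"E"`, `"CAS"`, `"DAS"`.
#' @param n_frames output length, default 938.
#' @return an integer vector of 0/1 of length `n_frames` with attributes
#'   `task` and `time_s`.
#' @export
events_to_frames <- function(events, task = c("I", "E", "CAS", "DAS"),
                             n_frames = N_FRAMES) {
  task <- match.arg(task)
  ev <- task_events(events, task)
  centers <- frame_times(n_frames)
  y <- integer(n_frames)
  if (nrow(ev) > 0) {
    for (k in seq_len(nrow(ev))) {
      y[centers >= ev$onset[k] & centers <= ev$offset[k]] <- 1L
    }
  }
  structure(y, task = task, time_s = centers)
}

#' Downsample a 938-frame target to the CNN-fronted 469-frame grid
#'
#' The convolutional front end halves the time axis; targets are pooled
#' pairwise with `max`, so a half-rate frame is positive if either of its
#' constituent full-rate frames is. This preserves events as short as one
#' frame, which plain subsampling would drop.
#'
#' @param y a binary vector of even length.
#' @return a binary vector of length `length(y) / 2`.
#' @export
downsample_targets <- function(y) {
  n <- length(y)
  if (n %% 2 != 0) stop("even-length target sequence required, got ", n)
  out <- pmax(y[seq(1, n, by = 2)], y[seq(2, n, by = 2)])
  structure(as.integer(out), task = attr(y, "task"))
}

#' Reassemble a binary frame sequence into time intervals
#'
#' Maximal runs of positive frames become intervals spanning from the first
#' frame's center minus half a hop to the last frame's center plus half a
#' hop, so frame and event representations are mutually consistent.
#'
#' @param y binary vector.
#' @param hop_s frame hop in seconds (default 0.016).
#' @return data frame with `onset`, `offset` and the frame index range.
#' @export
frames_to_intervals <- function(y, hop_s = FRAME_S) {
  r <- rle(as.integer(y) > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(
    onset = pmax(0, (starts[keep] - 1) * hop_s - hop_s / 2),
    offset = (ends[keep] - 1) * hop_s + hop_s / 2,
    first_frame = starts[keep] - 1L,
    last_frame = ends[keep] - 1L
  )
}
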