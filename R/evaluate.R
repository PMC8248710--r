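# Evaluation: segment-level classification metrics on the per-frame grid,
# event-level detection with the Jaccard-index matching rule, ROC/AUC, and
# the MAPE-versus-threshold curve for event counts.

#' Frame-wise confusion counts
#'
#' @param pred binary prediction vector.
#' @param truth binary target vector of the same length.
#' @return a `segment_confusion` list with `tp`, `tn`, `fp`, `fn`.
#' @export
segment_confusion <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("length mismatch: ", length(pred), " predictions vs ",
         length(truth), " targets")
  }
  p <- as.integer(pred > 0); y <- as.integer(truth > 0)
  structure(list(tp = sum(p == 1 & y == 1), tn = sum(p == 0 & y == 0),
                 fp = sum(p == 1 & y == 0), fn = sum(p == 0 & y == 1)),
            class = "segment_confusion")
}

#' Classification metrics from confusion counts
#'
#' Standard definitions; ratios with zero denominator are reported as
#' `NA` (undefined) and are excluded from any macro average.
#'
#' @param conf a `segment_confusion` (or list with tp/tn/fp/fn).
#' @return list with accuracy, ppv, sensitivity, specificity, f1.
#' @export
confusion_metrics <- function(conf) {
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  tp <- conf$tp; tn <- conf$tn; fp <- conf$fp; fn <- conf$fn
  ppv <- safe_div(tp, tp + fp)
  sens <- safe_div(tp, tp + fn)
  f1 <- if (is.na(ppv) || is.na(sens) || (ppv + sens) == 0) {
    if (!is.na(ppv) && !is.na(sens)) NA_real_ else NA_real_
  } else 2 * ppv * sens / (ppv + sens)
  list(
    accuracy = safe_div(tp + tn, tp + tn + fp + fn),
    ppv = ppv,
    sensitivity = sens,
    specificity = safe_div(tn, tn + fp),
    f1 = f1
  )
}

#' ROC curve and AUC from pooled frame scores
#'
#' Sweeps sensitivity and 1-specificity over all distinct score values and
#' integrates by the trapezoidal rule. Frames are pooled across the
#' evaluated recordings.
#'
#' @param scores numeric score vector (pooled frames).
#' @param truth binary target vector.
#' @return a `lung_roc` list with `fpr`, `tpr`, `thresholds`, `auc`.
#' @export
roc_auc <- function(scores, truth) {
  y <- as.integer(truth > 0)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) stop("AUC undefined: single-class truth")
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  last <- c(ss[-1] != ss[-length(ss)], TRUE)   # last index of each tie group
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(fpr = fpr, tpr = tpr,
                 thresholds = c(Inf, ss[last]), auc = auc),
            class = "lung_roc")
}

#' @export
print.lung_roc <- function(x, ...) {
  cat(sprintf("<lung_roc> AUC = %.4f (%d operating points)\n",
              x$auc, length(x$fpr)))
  invisible(x)
}

#' Plot a ROC curve
#'
#' @param x a `lung_roc`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.lung_roc <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlab = "1 - specificity",
                 ylab = "sensitivity",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

interval_ji <- function(a1, a2, b1, b2) {
  inter <- max(0, min(a2, b2) - max(a1, b1))
  if (inter == 0) return(0)
  union <- max(a2, b2) - min(a1, b1)
  inter / union
}

#' Match detected events to ground truth with the Jaccard-index rule
#'
#' Each detected event's Jaccard index (interval intersection over union)
#' is computed against its best-overlapping ground-truth event; matching
#' is one-to-one, greedy by descending JI, so each ground-truth event is
#' credited to at most one detection. A detection with JI > 0.5 is a TP;
#' with 0 < JI <= 0.5 an FN; with JI = 0 an FP. A TN event cannot be
#' defined. Ground-truth events overlapped by no detection at all count as
#' additional (missed) FNs for sensitivity.
#'
#' @param pred data frame of detected events (`onset`, `offset`).
#' @param truth data frame of ground-truth events (`onset`, `offset`).
#' @return a `match_outcome` list: per-prediction `ji` and `category`,
#'   per-truth `matched`, and counts `tp`, `fn`, `fp`, `missed_truth`,
#'   `fn_total`.
#' @export
match_events <- function(pred, truth) {
  np <- nrow(pred); nt <- nrow(truth)
  ji_mat <- matrix(0, np, nt)
  if (np > 0 && nt > 0) {
    for (i in seq_len(np)) {
      for (j in seq_len(nt)) {
        ji_mat[i, j] <- interval_ji(pred$onset[i], pred$offset[i],
                                    truth$onset[j], truth$offset[j])
      }
    }
  }
  best_ji <- if (nt > 0 && np > 0) apply(ji_mat, 1, max) else rep(0, np)
  category <- ifelse(best_ji > 0.5, "TP", ifelse(best_ji > 0, "FN", "FP"))
  # one-to-one credit assignment, greedy by descending JI
  matched_truth <- rep(FALSE, nt)
  if (np > 0 && nt > 0) {
    pairs <- which(ji_mat > 0.5, arr.ind = TRUE)
    if (nrow(pairs) > 0) {
      pairs <- pairs[order(-ji_mat[pairs]), , drop = FALSE]
      used_pred <- rep(FALSE, np)
      for (k in seq_len(nrow(pairs))) {
        i <- pairs[k, 1]; j <- pairs[k, 2]
        if (!used_pred[i] && !matched_truth[j]) {
          used_pred[i] <- TRUE; matched_truth[j] <- TRUE
        }
      }
      # a TP prediction must hold a credited truth; demote double claims
      for (i in which(category == "TP")) {
        if (!used_pred[i]) category[i] <- "FN"
      }
    }
  }
  overlapped_truth <- if (np > 0 && nt > 0) apply(ji_mat, 2, max) > 0 else rep(FALSE, nt)
  tp <- sum(category == "TP"); fn <- sum(category == "FN")
  fp <- sum(category == "FP"); missed <- sum(!overlapped_truth)
  structure(list(ji = best_ji, category = category,
                 matched = matched_truth,
                 tp = tp, fn = fn, fp = fp,
                 n_pred = np, n_truth = nt,
                 missed_truth = missed, fn_total = fn + missed),
            class = "match_outcome")
}

#' Event-detection metrics from a match outcome
#'
#' PPV is the fraction of detections credited as TPs (FN- and
#' FP-categorized detections both count against precision); sensitivity is
#' the fraction of ground-truth events credited to a TP detection, so
#' every uncredited ground-truth event acts as a false negative of recall.
#' F1 is their harmonic mean.
#'
#' @param outcome a `match_outcome`, or a list of them (counts pooled).
#' @return list with tp, fp, fn, n_pred, n_truth, ppv, sensitivity, f1.
#' @export
event_f1 <- function(outcome) {
  if (inherits(outcome, "match_outcome")) outcome <- list(outcome)
  tp <- sum(vapply(outcome, `[[`, numeric(1), "tp"))
  fp <- sum(vapply(outcome, `[[`, numeric(1), "fp"))
  fn <- sum(vapply(outcome, `[[`, numeric(1), "fn"))
  n_pred <- if (!is.null(outcome[[1]]$n_pred)) {
    sum(vapply(outcome, `[[`, numeric(1), "n_pred"))
  } else tp + fp + fn
  n_truth <- sum(vapply(outcome, `[[`, numeric(1), "n_truth"))
  ppv <- if (n_pred == 0) NA_real_ else tp / n_pred
  sens <- if (n_truth == 0) NA_real_ else tp / n_truth
  f1 <- if (is.na(ppv) || is.na(sens) || ppv + sens == 0) NA_real_ else
    2 * ppv * sens / (ppv + sens)
  list(tp = tp, fp = fp, fn = fn, n_pred = n_pred, n_truth = n_truth,
       ppv = ppv, sensitivity = sens, f1 = f1)
}

#' MAPE of per-recording event counts versus detection threshold
#'
#' For each threshold the score sequences are postprocessed into events;
#' the absolute percentage error of the detected event count against the
#' ground-truth count is averaged over recordings with at least one
#' ground-truth event.
#'
#' @param score_list list of per-recording score vectors.
#' @param truth_list list of per-recording ground-truth event data frames.
#' @param thresholds thresholds to sweep.
#' @param spec_list optional list of spectrograms enabling peak-based
#'   merging during postprocessing.
#' @param config a [postprocess_config] (its threshold field is swept).
#' @return a `lung_mape` data frame with `threshold` and `mape_pct`.
#' @export
mape_curve <- function(score_list, truth_list,
                       thresholds = seq(0.1, 0.9, by = 0.1),
                       spec_list = NULL, config = postprocess_config()) {
  stopifnot(length(score_list) == length(truth_list))
  n_truth <- vapply(truth_list, nrow, integer(1))
  eval_rec <- which(n_truth > 0)
  if (length(eval_rec) == 0) stop("no recording has ground-truth events")
  out <- data.frame(threshold = thresholds, mape_pct = NA_real_)
  for (k in seq_along(thresholds)) {
    cfg <- config; cfg$threshold <- thresholds[k]
    ape <- vapply(eval_rec, function(i) {
      det <- postprocess_events(score_list[[i]],
                                if (!is.null(spec_list)) spec_list[[i]],
                                cfg)
      abs(nrow(det) - n_truth[i]) / n_truth[i]
    }, numeric(1))
    out$mape_pct[k] <- 100 * mean(ape)
  }
  structure(out, class = c("lung_mape", "data.frame"))
}

#' Plot a MAPE curve
#'
#' @param x a `lung_mape` data frame.
#' @param ... passed to [graphics::plot()].
#' @export
plot.lung_mape <- function(x, ...) {
  graphics::plot(x$threshold, x$mape_pct, type = "b", xlab = "threshold",
                 ylab = "MAPE (%)", main = "Event-count MAPE", ...)
  invisible(x)
}

#' Segment metrics for a set of recordings
#'
#' Computes per-recording confusion metrics and reports both the macro
#' average (mean over recordings, undefined ratios excluded) and pooled
#' micro metrics.
#'
#' @param pred_list list of binary prediction vectors.
#' @param truth_list list of binary target vectors.
#' @return list with `macro`, `micro` and the per-recording table.
#' @export
segment_metrics <- function(pred_list, truth_list) {
  stopifnot(length(pred_list) == length(truth_list))
  per <- lapply(seq_along(pred_list), function(i) {
    confusion_metrics(segment_confusion(pred_list[[i]], truth_list[[i]]))
  })
  per_df <- do.call(rbind, lapply(per, as.data.frame))
  macro <- as.list(colMeans(per_df, na.rm = TRUE))
  pooled <- segment_confusion(unlist(pred_list), unlist(truth_list))
  list(macro = macro, micro = confusion_metrics(pooled),
       per_recording = per_df)
}
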