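test_that("segment confusion counts frames correctly", {
  c1 <- segment_confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unlist(c1[c("tp", "tn", "fp", "fn")]), c(tp = 2, tn = 2, fp = 0, fn = 0))
  c2 <- segment_confusion(c(0, 0, 1, 1), c(1, 1, 0, 0))
  expect_equal(c2$tp, 0); expect_equal(c2$tn, 0)
  c3 <- segment_confusion(c(1, 0, 1, 0), c(1, 1, 0, 0))
  expect_equal(unlist(c3[c("tp", "fn", "fp", "tn")]), c(tp = 1, fn = 1, fp = 1, tn = 1))
  expect_error(segment_confusion(c(1, 0), c(1, 0, 0)), "mismatch")
})

test_that("metrics use standard definitions with NA for 0/0 ratios", {
  m <- confusion_metrics(list(tp = 8, fp = 2, fn = 2, tn = 8))
  expect_equal(m$ppv, 0.8)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$f1, 0.8)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$specificity, 0.8)

  z <- confusion_metrics(list(tp = 0, fp = 0, fn = 0, tn = 0))
  expect_true(all(is.na(unlist(z))))

  p <- confusion_metrics(list(tp = 1, fp = 0, fn = 0, tn = 0))
  expect_equal(p$f1, 1)
  expect_true(is.na(p$specificity))
})

test_that("ROC/AUC behaves at the extremes and rejects single-class truth", {
  y <- c(rep(1, 5), rep(0, 5))
  expect_equal(roc_auc(as.numeric(y), y)$auc, 1.0)
  expect_equal(roc_auc(1 - y, y)$auc, 0.0)
  expect_error(roc_auc(stats::runif(5), rep(1, 5)), "single-class")
})

test_that("independent uniform scores give AUC 1/2", {
  set.seed(55)
  y <- rbinom(10000, 1, 0.3)
  s <- stats::runif(10000)
  expect_lt(abs(roc_auc(s, y)$auc - 0.5), 0.02)
})

test_that("trapezoidal AUC equals the rank-statistic closed form", {
  set.seed(56)
  for (rep in 1:40) {
    n <- sample(c(50, 200, 1000), 1)
    y <- rbinom(n, 1, stats::runif(1, 0.1, 0.9))
    if (length(unique(y)) < 2) next
    # include heavy ties to exercise tie handling
    s <- if (rep %% 2 == 0) sample(seq(0, 1, 0.1), n, replace = TRUE)
         else stats::runif(n) + y * stats::runif(1, 0, 1)
    expect_equal(roc_auc(s, y)$auc, rank_auc(s, y), tolerance = 1e-9)
  }
})

test_that("the Jaccard-index rule assigns TP, FN and FP categories", {
  p1 <- data.frame(onset = 0, offset = 1)
  t1 <- data.frame(onset = 0, offset = 1)
  m1 <- match_events(p1, t1)
  expect_equal(m1$category, "TP")
  expect_equal(m1$ji, 1)

  t2 <- data.frame(onset = 0.8, offset = 1.8)
  m2 <- match_events(p1, t2)
  expect_equal(m2$ji, 0.2 / 1.8, tolerance = 1e-12)
  expect_equal(m2$category, "FN")

  t3 <- data.frame(onset = 3, offset = 4)
  m3 <- match_events(data.frame(onset = 2, offset = 3), t3)
  expect_equal(m3$ji, 0)
  expect_equal(m3$category, "FP")
  expect_equal(m3$missed_truth, 1)

  # boundary: JI of exactly 0.5 is an FN, just above is a TP
  exact <- match_events(data.frame(onset = 0, offset = 0.5),
                        data.frame(onset = 0, offset = 1))
  expect_equal(exact$ji, 0.5)
  expect_equal(exact$category, "FN")
  tp <- match_events(data.frame(onset = 0, offset = 0.75),
                     data.frame(onset = 0, offset = 1))
  expect_equal(tp$category, "TP")                 # JI = 0.75
})

test_that("event F1 combines PPV with missed-truth-aware sensitivity", {
  # 10 detections: 8 TPs, one FN by JI, one FP; 10 ground truths
  out <- list(tp = 8, fp = 1, fn = 1, n_pred = 10, n_truth = 10)
  class(out) <- "match_outcome"
  f <- event_f1(out)
  expect_equal(f$ppv, 0.8)
  expect_equal(f$sensitivity, 0.8)
  expect_equal(f$f1, 0.8)

  perfect <- match_events(data.frame(onset = c(1, 5), offset = c(2, 6)),
                          data.frame(onset = c(1, 5), offset = c(2, 6)))
  expect_equal(event_f1(perfect)$f1, 1)

  none <- match_events(data.frame(onset = numeric(), offset = numeric()),
                       data.frame(onset = 1, offset = 2))
  expect_equal(event_f1(none)$sensitivity, 0)
})

test_that("greedy matching agrees with the exhaustive max-JI oracle", {
  set.seed(57)
  for (rep in 1:250) {
    pred <- random_intervals(sample(0:6, 1), span = 10)
    truth <- random_intervals(sample(0:6, 1), span = 10)
    got <- match_events(pred, truth)
    want <- oracle_match(pred, truth)
    expect_equal(got$tp, want$tp)
    expect_equal(got$fp, want$fp)
    expect_equal(got$fn, want$fn)
    expect_equal(got$fn_total, want$fn_total)
  }
})

test_that("MAPE of event counts responds to threshold", {
  scores <- rep(0, 938)
  scores[c(101:163, 301:363, 501:563, 701:763)] <- 0.9
  truth4 <- data.frame(onset = c(1.6, 4.8, 8.0, 11.2),
                       offset = c(2.6, 5.8, 9.0, 12.2))
  flat <- mape_curve(list(scores), list(truth4),
                     thresholds = c(0.3, 0.5, 0.7))
  expect_equal(flat$mape_pct, c(0, 0, 0))

  # a threshold above every score detects nothing: 100% error
  high <- mape_curve(list(scores), list(truth4), thresholds = 0.95)
  expect_equal(high$mape_pct, 100)

  # 3 detected vs 4 true events -> 25%
  scores3 <- rep(0, 938)
  scores3[c(101:163, 301:363, 501:563)] <- 0.9
  m3 <- mape_curve(list(scores3), list(truth4), thresholds = 0.5)
  expect_equal(m3$mape_pct, 25)
})

test_that("segment metrics are invariant to recording order", {
  set.seed(58)
  preds <- lapply(1:6, function(i) rbinom(100, 1, 0.3))
  truths <- lapply(1:6, function(i) rbinom(100, 1, 0.3))
  a <- segment_metrics(preds, truths)
  perm <- c(4, 2, 6, 1, 5, 3)
  b <- segment_metrics(preds[perm], truths[perm])
  expect_equal(a$macro, b$macro)
  expect_equal(a$micro, b$micro)
})

test_that("oracle scores yield event F1 = 1 on well-separated synthetic events", {
  # seeds chosen so every same-task event pair is > 0.6 s apart
  cfg <- synth_config(seed = 71, cas_rate = 1, das_rate = 1)
  out <- generate_recording(cfg)
  fe <- extract_features(out$recording)
  for (task in c("I", "E", "CAS", "DAS")) {
    ev <- task_events(out$events, task)
    if (nrow(ev) == 0) next
    gaps <- if (nrow(ev) > 1) ev$onset[-1] - head(ev$offset, -1) else 1
    if (any(gaps < 0.6)) next
    y <- events_to_frames(out$events, task)
    det <- postprocess_events(as.numeric(y), fe$spectrogram, postprocess_config())
    f <- event_f1(match_events(det, ev[, c("onset", "offset")]))
    expect_equal(f$f1, 1, label = paste("task", task))
  }
})
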