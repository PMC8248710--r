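---
title: "Detecting breath phases and adventitious sounds in lung recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting breath phases and adventitious sounds in lung recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungsed)
```

## The problem

Auscultation of the chest yields a sequence of breath phases — inhalations
(I) and exhalations (E) — over which abnormal *adventitious* sounds may be
superimposed: continuous adventitious sounds (CAS: wheezes, stridor,
rhonchi, which are tonal) and discontinuous adventitious sounds (DAS:
crackles, which are trains of very short transients, each explosive sound
typically under 25 ms). Detecting the *onset and offset* of every such
event in a recording — not merely classifying whole recordings — enables
quantitative respiratory monitoring: respiratory rate, inspiratory
duration, wheeze occupation rate, and so on.

`lungsed` implements a complete detection framework for 15-second,
4 kHz, 16-bit mono recordings: feature extraction, a zoo of twelve
recurrent-network detectors, event postprocessing, and two-level
evaluation (per-time-frame "segment" metrics and per-event metrics under
a Jaccard-index matching rule), together with a seeded synthetic
lung-sound generator so the whole pipeline is testable without any
external data.

## Signal representation

Recordings are high-pass filtered (10th-order Butterworth, 80 Hz cutoff)
to suppress mains hum and most heart-sound energy. The filter is applied
forward and backward (zero phase), so labeled event boundaries are not
shifted; it is realized as cascaded second-order sections because a
10th-order transfer function with a cutoff at 0.04 of the sampling rate
is numerically fragile in direct form.

The short-time Fourier transform uses a 256-point Hann window with hop
64 and centered framing, so a 60,000-sample recording yields exactly
`1 + floor(60000/64) = 938` frames of 129 bins (0–2,000 Hz in steps of
15.625 Hz; frame period 16 ms). Three feature blocks are concatenated
per frame:

* the 129-bin log-magnitude spectrogram, `20*log10(|X| + 1e-10)`;
* 60 MFCC values — 20 static cepstra (40 mel bands spanning 0–4,000 Hz
  on the mel scale, DCT-II, coefficient 0 included), plus width-9
  regression deltas and delta-deltas;
* 4 band-energy sums of the power spectrogram over 0–250, 250–500,
  500–1,000 and 0–2,000 Hz.

This gives a 938 × 193 matrix; each column is independently min–max
scaled to [0, 1] *within the recording*. Per-recording scaling needs no
corpus pass and makes each recording self-contained; the alternative
(corpus-level statistics) would couple feature values to the training
set. Columns that are numerically constant (range at rounding-noise
level) map to zero rather than being stretched to full scale.

A note on the mel range: the filterbank is specified over 0–4,000 Hz
although the Nyquist frequency is 2,000 Hz; filters centered above
2 kHz receive no spectral support and contribute constant floor values,
which the min–max step then zeroes. The parameters are kept as stated
for comparability rather than "corrected".

```{r features}
rec <- generate_recording(synth_config(seed = 1))$recording
fe <- extract_features(rec)
dim(fe$values)
```

## Targets

Ground-truth events (classes I, E, W, S, R, D; CAS is the pooled union
of W/S/R) are converted to per-frame binary sequences: frame *i* (center
time `i * 0.016` s) is positive iff its center lies inside an event of
the task's class(es). Centers are compared with closed interval
endpoints, which reproduces the canonical worked example (an event
[1.0, 2.0] s covers frames 63…125) and recovers event spans to within
one hop. For the CNN-fronted models, whose output has 469 half-rate
frames, targets are pooled pairwise with `max`, so an event only one
frame long survives the rate reduction.

## The detector zoo

All twelve variants share one architecture, reconstructed so that every
published trainable-parameter count is matched exactly:

* optional convolutional front end: Conv2D(32, 3×5, same) →
  batch-norm → ReLU → Conv2D(64, 3×11, same) → ReLU → 2×2 max-pool on
  the 938 × 193 × 1 feature "image", flattened to a 469 × 6,208
  sequence;
* two stacked recurrent layers (LSTM or GRU), 128 units each —
  bidirectional models use 128 units per direction, and the simplified
  (SIMP) bidirectional models halve that to 64 per direction so their
  parameter budget is comparable to the unidirectional models;
* a time-distributed Dense(32, ReLU) and Dense(1, sigmoid) head giving
  one score per frame.

The GRU uses separate input and recurrent bias vectors (the convention
whose per-layer count is `3*(dH + H² + 2H)`); the LSTM uses a single
bias with forget-gate bias 1. Output length is 938 frames, or 469 with
the CNN front end.

```{r zoo}
for (s in list(model_spec("lstm"), model_spec("gru"),
               model_spec("gru", bidirectional = TRUE),
               model_spec("gru", bidirectional = TRUE, simplified = TRUE))) {
  m <- build_model(s)
  cat(sprintf("%-12s %9s parameters\n", s$name,
              format(count_parameters(m), big.mark = ",")))
}
```

The networks are implemented natively in R (BLAS-backed matrix algebra;
input projections are computed for all frames in one multiplication, so
only the small recurrence runs in an interpreted loop). Training is
minibatch Adam on per-frame binary cross-entropy — the natural loss for
a per-frame sigmoid sequence labeler — with the benchmark schedule:
initial learning rate 1e-4, step decay ×0.2 when the validation loss
has not strictly decreased for 10 epochs, stop after 50 non-improving
epochs, restore the best-validation weights. Improvement is measured on
validation loss with zero tolerance, and the decay and stop counters
run independently. Batch size defaults to 32 with per-epoch shuffling
under the run seed; with a fixed seed a CPU run is bit-reproducible.

## Postprocessing

Thresholded score runs become events spanning from the first frame
center minus half a hop to the last center plus half a hop. Two
consecutive detections are merged when the gap between them is strictly
less than T = 0.5 s *and* their spectral energy peaks differ by
strictly less than P = 25 Hz — the motivation being that one breath
phase is often split by a brief dip in the score, while genuinely
distinct events usually differ spectrally. An event's energy peak is
the bin-center frequency maximizing mean pre-normalization spectral
power over its frames (ties to the lowest bin; normalization would
distort per-column scales, so the raw power spectrogram is used). After
a merge the peak is recomputed and the scan resumes at the left
neighbour, so merging runs to a fixed point; this matches a brute-force
"merge the leftmost eligible pair until none remains" oracle by
construction. Finally, burst events strictly shorter than 0.05 s are
deleted ("shorter than" is read as a strict inequality, so an event of
exactly 0.05 s survives). The same postprocessor is applied to all four
tasks; it can be disabled per task by zeroing the thresholds, which
makes it the identity on assembled events.

## Evaluation

*Segment* metrics compare the thresholded 938-frame (or 469-frame)
prediction with the target frame-by-frame: accuracy, PPV, sensitivity,
specificity and F1 per recording, reported both macro-averaged (0/0
ratios are undefined and excluded, so recordings without events of a
class do not bias the average) and pooled. ROC curves sweep all
distinct score thresholds over pooled frames and AUC is the trapezoidal
integral, which the tests verify against the Mann–Whitney rank
statistic to 1e-9.

*Event* detection uses the Jaccard index (interval
intersection-over-union) between a detection and its best-overlapping
ground-truth event: JI > 0.5 makes a detection a true positive (each
truth creditable to at most one detection, greedily by descending JI);
0 < JI ≤ 0.5 a false negative; JI = 0 a false positive; a true-negative
event is undefined. Precision is TP over all detections and sensitivity
is TP over all ground-truth events, so entirely missed events count
against recall; on the canonical example (10 detections with 8 TPs, one
FN-by-JI, one FP, against 10 ground truths) this yields F1 = 0.8. The
matcher is verified against an exhaustive maximum-total-JI assignment
oracle; for disjoint event lists the credited TP set is provably unique,
which is why the greedy and exhaustive procedures agree.

The MAPE curve evaluates event *counts*: for each threshold, the mean
over recordings of |detected − true| / true, as a percentage, over
recordings with at least one true event. Event count rather than
duration is used because the count is what respiratory-rate estimation
consumes.

## The synthetic generator

The generator emulates the corpus statistics of the real database so
that detection is learnable but not trivial:

| quantity | default | origin |
|---|---|---|
| mean inhalation duration | 0.93 s | corpus mean |
| mean exhalation duration | 0.96 s | corpus mean |
| mean CAS duration | 0.83 s | corpus mean |
| mean DAS duration | 0.89 s | corpus mean |
| audible-exhalation probability | 0.55 | exhalation/inhalation label ratio |
| breath cycles per 15 s | 3.5 | inhalation labels per recording |
| crackle impulse length | 15 ms | "generally less than 25 ms" |
| SNR | 15 dB | chosen: clearly audible events over noise |

Durations are drawn from a log-normal truncated to [0.2, 3] s with
log-sd 0.25 — positive, right-skewed, plausible for breath sounds; only
means are published, so the spread is a free knob, not a corpus claim.
Inhalations are 100–1,200 Hz noise bursts under an attack–decay
envelope; exhalations similar at half amplitude, emitted with the
audible-exhalation probability; CAS events are harmonic tones with
class-dependent fundamentals (rhonchus ≤ 200 Hz, wheeze 150–1,000 Hz,
stridor ≥ 500 Hz, following standard auscultation descriptions);
DAS events are trains of 5–20 damped impulses per second, each under
25 ms, with the containing period labeled, as in the real annotation
protocol. Background noise (white, pink, 60 Hz hum with harmonics, or
ventilator-like periodic broadband bursts uncorrelated with the labels)
is scaled to the configured SNR. Every rendered event carries exactly
one label, and the seed fully determines audio and labels.

What the generator does **not** emulate: real airway acoustics, device
transfer functions, annotator noise and omissions, overlapping
same-class events, unusual breathing patterns, or the heavy
class imbalance and low SNR of ward recordings. Passing tests on
synthetic data therefore demonstrates that the pipeline's machinery is
correct and that the models can learn the task structure — not that the
published benchmark scores would be reproduced on real data.

## Scaled-down study sizes

The full published benchmark (twelve models × four tasks over 9,765
recordings, grouped fivefold cross-validation, GPU training) is out of
desk-scale reach by design; this package ships the complete pipeline
plus a reduced workflow exercised by its acceptance tests:

* synthetic recovery: a SIMP BiGRU trained on 200 synthetic recordings
  (30 validation, 30 test, grouped blocks) for 6 epochs at learning
  rate 1e-3 reaches held-out inhalation segment AUC ≥ 0.9 and event
  F1 ≥ 0.8 — the scaled-down run uses a larger learning rate and far
  fewer epochs than the full-scale schedule because the synthetic task
  is much easier and the budget much smaller;
* an end-to-end demo (`run_pipeline()`) over 50 recordings with
  fivefold grouping that writes a metric report reproducibly.

```{r pipeline, eval = FALSE}
cfg <- default_run_config(
  seed = 7, task = "I", n_recordings = 50,
  model = list(cell = "gru", bidirectional = TRUE, simplified = TRUE),
  train = list(initial_lr = 1e-3, max_epochs = 5, batch_size = 16)
)
res <- run_pipeline(cfg, out_dir = "run_out")
res$metrics$auc
```

## Numerical and design notes

* 16-bit samples are scaled by 1/32768 (symmetric convention), and
  durations are always validated by sample count, never header
  metadata.
* The stethoscope truncation protocol drops the final 0.8 s of a
  15.8-s file; the long-recording protocol keeps the first 15 s;
  neither resamples.
* Band membership is by bin-center frequency in half-open bands
  [lo, hi), except the full-range band, which spans the whole axis —
  this avoids double counting at the shared 250/500/1,000 Hz edges.
* MFCCs are computed from the filtered signal, with the same framing as
  the spectrogram.
* Fold assignment shuffles groups under the seed and then fills the
  currently smallest fold largest-group-first: a group ("subject-day")
  never spans folds, which is the leakage rule the benchmark's
  cross-validation mandates.
* CAS and DAS detectors are meant to be trained only on recordings
  containing such events; the pipeline trains one independent detector
  per task.

## Known limitations

* The exact kernel geometry of the published convolutional front end is
  reconstructed from parameter counts; any front end with the same
  count and output shape is observationally equivalent at that level of
  evidence.
* Training at full published scale (hundreds of epochs over thousands
  of recordings) is possible but slow in a native-R implementation;
  the package targets correctness, reproducibility and desk-scale
  studies rather than GPU throughput.
* The synthetic corpus is a calibration instrument, not a clinical
  simulator; conclusions about real-world detection quality require the
  real database.
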