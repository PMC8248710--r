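Package: lungsed
Title: Lung Sound Event Detection with Recurrent Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete framework for detecting inhalation, exhalation,
    continuous adventitious sound (CAS, i.e. wheeze/stridor/rhonchus) and
    discontinuous adventitious sound (DAS, i.e. crackle) events in 15-second
    auscultation recordings sampled at 4 kHz. Provides WAVE and event-label
    input/output with the standard truncation protocols, a seeded synthetic
    lung-sound generator for fully reproducible testing, spectrogram/MFCC/
    band-energy feature extraction producing the canonical 938 x 193 feature
    matrix, a zoo of twelve recurrent detectors (LSTM/GRU, bidirectional and
    simplified bidirectional variants, with an optional convolutional front
    end) implemented natively with seeded, CPU-deterministic training, event
    postprocessing (gap/peak-frequency merging and burst removal), and
    segment-level and event-level evaluation including ROC/AUC, F1 with the
    Jaccard-index matching rule, and MAPE curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
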