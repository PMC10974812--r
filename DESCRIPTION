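Package: plantsense
Title: Emotion Classification from Plant Electrophysiology Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for classifying human emotions from the
    electrical signal of a nearby plant. Provides a seeded synthetic-session
    generator (plant voltage recording, per-second facial-emotion label
    stream and video schedule), two data-preparation tracks (z-normalized
    sliding windows with MFCC extraction and downsampling, and raw
    one-second segments), seven classifier families built from declarative
    hyperparameter specifications (MLP, bidirectional LSTM, MFCC-CNN,
    MFCC-ResNet, random forest, 1-D CNN and a raw-signal bidirectional
    LSTM), a grid-search harness with five-fold cross-validation and early
    stopping, class-imbalance handling, and an evaluation layer with
    confusion matrices, weighted metrics and valence-arousal quadrant
    aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
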