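Package: beatformer
Title: Hybrid Convolutional-Transformer Classification of ECG Heartbeats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Heartbeat-level arrhythmia classification for single-lead ECG
    using a hybrid architecture: a 1-D convolutional front end for local
    P-QRS-T morphology, a BERT-style transformer encoder for global context,
    cross-modal attention with gated fusion of the two feature streams, and
    a focal-loss training loop with learning-rate warm-up. Includes WFDB
    record/annotation reading, band-pass filtering and beat segmentation,
    the AAMI five-class annotation mapping, a synthetic heartbeat generator
    with configurable class imbalance for fully self-contained experiments,
    and confusion-matrix based per-class evaluation. All network layers are
    implemented natively with explicit forward and backward passes, so the
    whole pipeline runs on a single CPU with no external deep-learning
    runtime.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
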