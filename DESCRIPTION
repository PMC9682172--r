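Package: emgtransfer
Title: Subject- and Task-Transfer Learning for Surface EMG Hand-Movement
    Intention Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decoding hand-movement intention from multichannel
    surface electromyography (sEMG). Provides band-pass/notch filtering, cue
    segmentation, threshold-based onset detection and sliding-window
    extraction; fifteen handcrafted time- and frequency-domain window
    features (amplitude statistics, zero crossings, slope-sign changes,
    Hjorth parameters, sample entropy, cepstral coefficients) with four
    reference classical classifiers (KNN, linear SVM, MLP, LDA); two compact
    convolutional networks for raw multichannel windows (Cnet1D, Cnet2D)
    trained with Adam, batch normalization, randomized ReLU, dropout and
    early stopping; a parallel-feature subject-transfer architecture
    (PFCnet) that concatenates frozen target- and source-trained feature
    extractors under a fresh classifier; a three-stage task-transfer suite
    for combined wrist-rotation/hand-function movements (a zero-shot
    synergy decision rule, a Siamese few-shot similarity classifier, and
    staged fine-tuning of a 6-unit sigmoid head); a synergy-structured
    synthetic sEMG generator for offline experiments; and the accuracy /
    Friedman / pairwise-Wilcoxon / Holm evaluation pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    signal,
    MASS,
    class,
    e1071
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
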