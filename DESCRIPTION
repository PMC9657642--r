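Package: seizefeat
Title: Classifier-Free Seizure Detection from Multichannel Scalp EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects epileptic seizure epochs in multichannel scalp EEG
    without a trained classifier. A zero-phase filter cascade (35 Hz FIR
    low-pass, power-line notch, recursive DC-removal notch) denoises each
    channel; the channel average is rectified, band-limited to the seizure
    band (0.1-4.1 Hz) and collapsed into a single normalized moving-RMS
    "feature signal" in which seizures appear as baseline discontinuities.
    Candidate epochs are found by peak prominence, half-prominence width
    (0.4-1.8 s) and in-band power rules, reported as interval sets and
    binary masks, and traced back to the originating channels and cortical
    lobe via a median-threshold amplitude rule. Includes EDF and annotation
    I/O, a seeded synthetic EEG generator with ground truth, and an
    evaluation suite computing sensitivity, specificity, precision,
    accuracy, F-measure, G-mean and false positives per hour.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Software, SignalProcessing, Electrophysiology
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'filters.R'
    'edf.R'
    'annotations.R'
    'preprocess.R'
    'feature.R'
    'detect.R'
    'localize.R'
    'evaluate.R'
    'simulate.R'
    'pipeline.R'
    'seizefeat-package.R'
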