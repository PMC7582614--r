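Package: ppgbp
Title: Cuffless Blood Pressure Estimation from Photoplethysmogram Morphology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for estimating systolic and diastolic
    blood pressure from the photoplethysmogram (PPG) alone. Provides
    frequency-domain denoising, per-cycle fiducial point detection (onset,
    systolic peak, slope extrema, dicrotic notch, offset), extraction of 59
    morphological features from the PPG and its first and second derivatives,
    a distribution-similarity index (gamma) for feature screening, a fully
    connected neural-network regressor trained with the Nadam optimizer, and
    device-grading statistics (AAMI verdict, BHS cumulative-error grades,
    Pearson correlation, Bland-Altman limits of agreement). A synthetic
    waveform generator with known fiducial ground truth and a configurable
    morphology-to-pressure mapping makes every stage testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
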