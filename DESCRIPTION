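Package: alphashift
Title: Resting-State EEG Alpha-Power-Shift Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies slowing and anteriorization of the resting alpha
    rhythm in multichannel scalp EEG. Implements Hann-tapered
    overlapping-epoch spectral estimation with per-channel power
    normalization, the low/high alpha power-shift statistic (log2 ratio of
    6-9 Hz over 10-11 Hz relative power), group-level ANCOVA with planned
    contrasts, assumption checks and Hedges' g effect sizes with bootstrap
    confidence intervals, scalp-map interpolation and Freedman-Lane
    permutation inference with max-statistic family-wise error control,
    cross-validated linear discriminant classification of seizure-control
    status, and a synthetic EEG cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
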