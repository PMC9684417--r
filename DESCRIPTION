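Package: sagwo
Title: Fetal ECG Extraction by Sequential Analysis with Grey Wolf Optimisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-invasive fetal electrocardiogram (fECG) extraction from
    multichannel abdominal recordings. Each maternal beat is modelled as
    independently scaled P-wave, QRS-complex and T-wave sections of an
    averaged template; the per-beat scaling vector is optimised by a Grey
    Wolf Optimizer and the fitted template is subtracted, leaving the fetal
    component. Includes preprocessing (baseline-wander and powerline
    removal), PCA-based component selection, maternal and fetal QRS
    detection, the usual beat-detection statistics (ACC/SE/PPV/F1 under a
    +/- 50 ms matching tolerance), NICHD-style fetal heart rate features,
    kurtosis/skewness signal quality indices, and a synthetic
    abdominal-ECG generator with ground-truth annotations and per-cycle
    scalings so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
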