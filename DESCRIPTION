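Package: eegage
Title: Brain Age Prediction from Resting-State EEG with a Stacked-Tensor
    Convolutional Regressor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts chronological age from raw multichannel resting-state
    scalp EEG. Provides a synthetic EEG cohort generator with age-dependent
    band power, EDF and binary session store input/output, zero-phase
    filtering, overlapping segmentation with artifact rejection, stochastic
    segment augmentation (noise, channel dropout, amplitude scaling, time
    warp, time reversal), a four-block convolutional regressor on a
    channel-rolled stacked tensor trained with absolute or relative
    (log-ratio) loss under cross-subject cross-validation, session-level
    prediction and evaluation, differential-evolution optimization of age
    group boundaries under a class-balance constraint, integrated-gradients
    channel attribution with smoothing, and a band-power/age Spearman
    correlation screen with false discovery rate correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
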