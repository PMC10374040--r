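Package: pausetrack
Title: Cortical Tracking of Speech Envelopes with Inserted Silent Pauses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying how silent pauses
    inserted between words in continuous speech change cortical tracking of the
    speech envelope. Implements speech-envelope extraction (Hilbert transform,
    zero-phase FIR band-passing into delta and theta bands, resampling to an
    analysis rate), pause/onset/non-onset segmentation of the envelope,
    backward multivariate temporal response function (decoder) estimation by
    Tikhonov-regularised lagged regression with a second-difference smoothness
    penalty, leave-one-out cross-validated envelope reconstruction with a
    lambda grid search, permutation-null significance testing with mismatched
    envelope/EEG pairings, and nonparametric group comparisons. A synthetic
    data generator produces speech-like envelopes with configurable inserted
    pauses and multichannel EEG from known onset/sustained response kernels
    plus 1/f noise, so the whole pipeline is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    withr,
    generics,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
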