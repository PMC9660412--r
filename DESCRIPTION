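Package: eegseize
Title: Seizure-Onset Classification in EEG with Wavelet Subbands and a
    Medium-Weight Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and classifying onset epileptic seizures in
    multichannel scalp EEG. Recordings are segmented into short overlapping
    windows, decomposed with a five-level discrete wavelet filter bank into the
    conventional delta/theta/alpha/beta/gamma subbands, and classified with
    light-, medium- or heavy-weight convolutional networks trained with
    stochastic pooling, a squared-error cost and RMSprop. Includes a seeded
    synthetic EEG generator (1/f background plus rhythmic seizure and onset
    events), EDF and CHB-MIT-style annotation input/output, repeated stratified
    k-fold evaluation with ROC/AUC and paired t-tests, and correlation-map
    interpretability linking network units to subband spectral amplitude.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
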