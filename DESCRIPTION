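Package: recmicro
Title: Recurrence-Microstate Entropy Analysis of Multichannel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify brain complexity from multichannel EEG with
    recurrence-microstate entropy and to compare it across behavioral
    conditions. Provides a deterministic synthetic-EEG cohort generator
    (alpha/beta rhythms, 1/f background, pedaling-locked periodicity, step
    artifacts), the standard conditioning chain (Butterworth band-pass,
    mains band-stop, segmentation into equal pieces), a fast sampled
    estimator of maximum recurrence-microstate entropy, random-intercept
    linear models with within-subject permutation inference, EDF export and
    ingest, and an end-to-end reproducible pipeline with tabular and
    graphical summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    lme4,
    signal,
    withr,
    readr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
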