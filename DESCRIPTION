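Package: rhythmtag
Title: Frequency-Tagged EEG Analysis of Neural Entrainment to Rhythm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for EEG frequency-tagging studies of neural entrainment
    to musical rhythm. Synthesizes rhythmic tone-sequence stimuli and their
    amplitude-envelope spectra, derives beat and meter frequencies of
    interest, simulates multi-channel infant-style EEG cohorts with known
    ground truth, and implements the full analysis chain: zero-phase
    band-pass filtering, resampling, artifact attenuation, common-average
    referencing, epoch averaging, steady-state evoked-potential (SS-EP)
    amplitude extraction with neighbour-bin noise subtraction, transient
    event-related potential (ERP) area-under-curve measures, and the
    group-level statistics (paired t with Bonferroni correction,
    mixed-design ANOVA with Greenhouse-Geisser correction, Pearson
    correlation) used to compare musically trained and untrained cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2,
    signal,
    car,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
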