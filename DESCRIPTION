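Package: gipca
Title: Bootstrap-Enhanced Principal Component Analysis of Gait-Initiation Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the unsupervised classification of gait-initiation
    kinetics from force-plate recordings. Extracts the eleven standard
    gait-initiation variables (anticipatory postural adjustment durations,
    centre-of-pressure shifts, centre-of-mass velocities at the heel-off,
    toe-off and heel-contact events, foot-lift time and the vertical force
    peak at heel contact) from raw force and moment time series, reduces the
    feature table by principal component analysis, bootstraps the per-group
    mean scores to obtain tight confidence ellipses, quantifies cluster
    separation with a Jaccard overlap coefficient, and classifies
    participants with a two-component Gaussian mixture model fitted by
    expectation-maximization. Includes a seeded synthetic-data generator for
    cohorts and force-plate trials so the full analysis chain can be
    exercised and validated without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
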