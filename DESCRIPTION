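Package: mxpolarity
Title: Quantitative Analysis and Modeling of Switchable Front-Rear Polarity
    in Rod-Shaped Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the MglA/MglB/RomR front-rear polarity module of
    Myxococcus xanthus. Implements a six-dimensional ordinary differential
    equation model of polar protein fractions with genotype conditions,
    old-pole bias, steady-state classification, linear stability analysis,
    bifurcation scans and least-squares fitting to per-strain mean
    localization tables; a fluorescence image quantification pipeline
    (Gaussian-mixture background estimation, Laplacian-of-Gaussian spot
    filtering, polar search regions, per-cell polar fractions and asymmetry);
    cell tracking with old/new and leading/lagging pole identities, polarity
    inversion statistics and polar-fraction autocorrelation; statistical tests
    including the two-dimensional two-sample Kolmogorov-Smirnov test of Fasano
    and Franceschini; and synthetic-data generators with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    mclust,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
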