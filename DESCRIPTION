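Package: emmetrics
Title: Ocular Biometry of Emmetropia and Ametropia via Bigaussian Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the biometric analysis of emmetropia and ametropia in
    adult eyes. Implements a paraxial ray-transfer model of the eye (corneal
    thick-lens power, Bennett crystalline-lens power, whole-eye cardinal
    points, axial power), bigaussian (two-component Gaussian) modelling of the
    refractive-error distribution and of multivariate ocular biometry,
    covariance-ellipse classification of eyes into Regulated and Dysregulated
    subgroups, a seeded synthetic-cohort generator with population-calibrated
    moments and correlations, and the descriptive analyses (summary tables,
    Bonferroni-corrected correlation matrices, refraction-binned overlap
    summaries, alignment regressions, biometric uniqueness counts, relative
    scaling profiles) needed to study how corneal power, lens power and axial
    length jointly produce the refractive state of an eye.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
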