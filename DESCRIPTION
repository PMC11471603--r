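Package: frailmslt
Title: Multi-State Frailty Dynamics and Healthy Life Expectancy over the
    Life Course
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying healthy longevity in ageing cohorts with a
    deficit-accumulation frailty index and continuous-time multi-state
    models. Builds the Rockwood frailty index from 38 health deficits and
    codes robust/frailty/dead states; constructs childhood and adult
    socioeconomic indices with chained-equations imputation and the nine
    life-course trajectories; fits a three-state Markov model with
    log-linear age, gender and SES effects to interval-censored panel data
    with exactly dated deaths; and converts fitted intensities into annual
    transition probabilities, state occupancy on a 0.1-year grid, and
    total/robust/frailty life expectancies with parametric-bootstrap
    confidence intervals. Includes a calibrated cohort simulator so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    deSolve,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
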