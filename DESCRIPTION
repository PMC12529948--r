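Package: estroEDA
Title: Effect-Directed Analysis Toolkit for Estrogenic Leachate Drivers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computational pipeline for effect-directed analysis (EDA) of
    estrogenic elastomer leachates: nontarget LC-HRMS feature prioritization
    (blank subtraction, enrichment-factor and fraction intersection, intensity
    filtering), exact-mass and adduct m/z arithmetic with spectral-library
    matching and Schymanski-style confidence levels, four-parameter logistic
    dose-response modelling of yeast estrogen screen plates with EC10/EC50 and
    estradiol-equivalent estimation, standard-addition quantification with
    Fieller-type confidence intervals and S/N-based LOD/LOQ, two-state
    redox-couple speciation kinetics (linear and exponential-plateau fits,
    mass-balance diagnostics, Henderson-Hasselbalch speciation), and an
    effect-balance calculation with Gaussian propagation of 95% confidence
    intervals. Includes a synthetic-data module that generates every pipeline
    input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    minpack.lm
Suggests: testthat (>= 3.0.0), jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
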