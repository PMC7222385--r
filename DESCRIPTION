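Package: uaekin
Title: Weibull-Arrhenius Kinetics of Ultrasound-Assisted Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models solid-liquid extraction kinetics of bioactive compounds
    (total phenolics, flavonoids, antioxidant activity) under conventional
    and ultrasound-assisted aqueous extraction. Implements the Weibull
    extraction-yield model with an Arrhenius temperature dependence of the
    scale parameter, fitted simultaneously across multi-temperature yield
    curves by bounded Levenberg-Marquardt least squares with
    covariance-based standard errors and confidence intervals. Also provides
    calorimetric estimation of effective ultrasonic power and acoustic power
    density from initial temperature-rise traces, equilibrium-yield
    temperature regressions, mean-relative-error model evaluation, and a
    synthetic-data generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
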