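Package: mditrate
Title: Bayesian Insulin Dose Titration and In-Silico Trials for Multiple
    Daily Injection Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision support engine for basal-bolus insulin therapy on
    multiple daily injections: a real-time meal and correction bolus
    calculator with insulin-on-board tracking, a weekly Bayesian titration
    algorithm that fits a compartmental glucoregulatory model to flash
    glucose monitoring data and blends optimal with current therapy by
    statistical confidence, safety attenuation and clinical review rules,
    continuous glucose monitoring outcome metrics, trial biostatistics
    (power, ANCOVA treatment effects, proportion tests), and a seeded
    virtual-patient cohort generator with a two-arm in-silico randomized
    trial runner.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
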