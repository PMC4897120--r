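Package: mmtwin
Title: Multimutation Age-of-Onset Model and Twin Concordance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements a genetic multimutation model of age of onset for
    autism spectrum disorder: the susceptible prevalence function and its
    incidence-rate density, monozygote and dizygote twin pairwise
    concordance curves with their inversions, expected concordance over
    cohort age distributions, biological clock-rate calibration between
    cohorts, nonlinear least-squares fitting of cumulative
    age-of-first-diagnosis counts, and a seeded synthetic twin-cohort
    generator with registry-style ascertainment for validating the
    analytic theory by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
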