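Package: plmad
Title: Periodic Leg Movement Detection from Polysomnographic Leg EMG
Version: 0.1.0
Authors@R:
    person("PLMAD", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Automatic detection and scoring of leg movements (LM) and
    periodic leg movements (PLM) from polysomnographic leg EMG recordings.
    Implements recursive-least-squares adaptive cancellation of cardiac
    interference, a two-pass noise-floor-riding variable amplitude threshold
    detector with an optional low-frequency SNR boost, fragmentary-myoclonus
    screening by area-under-the-curve, respiratory-event exclusion windows,
    PLM run classification with AASM-style inter-movement-interval rules, and
    subject-level metrics (PLMS/h, PLMW/h, periodicity index, night ratios,
    PLM-locked heart-rate responses). Includes minimal EDF input/output and a
    seeded synthetic polysomnogram generator with exact ground-truth labels
    so the whole pipeline is testable without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
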