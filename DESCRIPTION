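Package: epiclock
Title: Leukocyte Epigenetic Age Acceleration and Prospective Cancer Incidence
Version: 0.1.0
Authors@R:
    person("Dario", "Venturi", email = "dario.venturi@example.org",
           role = c("aut", "cre"))
Description: Estimates DNA-methylation age from Illumina 450k beta values
    using linear epigenetic clocks (the 3-CpG Weidner clock and the
    single-CpG ELOVL2 and FHL2 clocks are built in; Horvath- and
    Hannum-style clocks load from coefficient files), computes
    control-anchored epigenetic age acceleration with and without
    adjustment for estimated blood cell counts, compares prospective
    cancer cases against age-matched control subgroups with the
    Wilcoxon-Mann-Whitney test, and relates acceleration to cancer
    incidence through Kaplan-Meier estimation and the log-rank test.
    Ships a synthetic prospective case-control cohort generator so the
    whole pipeline is testable without access to a real methylation
    series, and a command-line driver with reproducible hierarchical
    seeding.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
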