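Package: ctconcord
Title: Concordance of Tumor Tissue and Circulating Tumor DNA Alterations
    with Survival Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Harmonizes paired tumor-tissue and circulating tumor DNA
    (ctDNA) panel reports to a date-resolved comparable gene universe,
    scores gene-level and mutation(locus)-level concordance per patient,
    summarizes per-gene concordance across a cohort, and quantifies the
    prognostic effect of concordance counts on overall survival with
    univariate, multivariable, threshold, time-gap sensitivity, and
    covariate-omission Cox proportional-hazards analyses. Ships a
    synthetic paired-assay cohort generator (gene prevalence, ctDNA
    shedding, blood-private alterations, VAF, Weibull
    proportional-hazards survival) so the whole pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
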