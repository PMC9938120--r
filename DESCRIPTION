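Package: dsrtools
Title: Drug Sensitivity and Resistance Testing Analytics for
    Patient-Derived Cancer Cells
Version: 1.0.0
Authors@R:
    person("DSRT", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for ex vivo drug sensitivity and
    resistance testing (DSRT) of patient-derived cancer cells: plate
    normalization of luminescence viability screens with DMSO and
    benzethonium controls, constrained four-parameter logistic
    dose-response fitting, drug sensitivity scores (DSS1/DSS3 partial
    AUC), selective DSS against healthy-control profiles, target
    addiction scores (TAS) with permutation significance, highest
    single agent (HSA) synergy scoring of dose-combination matrices,
    and cohort-level subtype statistics (Welch t, ANOVA, Spearman
    correlations, Ward clustering, PCA, moderated-t differential drug
    sensitivity).  A synthetic-screen generator with recorded ground
    truth makes every stage testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
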