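Package: spectrosurv
Title: Prognostic Survival Modelling from Infrared Microspectroscopy of Tumour Tissue
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for outcome-driven prognostic modelling of
    hyperspectral infrared (FTIR) images of tumour tissue cores. Provides a
    synthetic-data generator for spectral cubes with planted class effects and
    exponential survival outcomes; plain-text cube/mask/cohort input-output;
    spectral preprocessing (mask co-registration at the amide-I band,
    EMSC-style linear interferent correction for paraffin, atmosphere,
    thickness and baseline, quality filtering, fingerprint-region extraction);
    outcome-only risk stratification by maximising the log-rank statistic over
    survival-time cut-offs; principal-component logistic-regression
    classification with patient-level bootstrap out-of-bag evaluation and
    median-probability patient scores; and survival analysis (Kaplan-Meier
    with exponential Greenwood confidence bands, univariate Cox proportional
    hazards, and reverse score-threshold analysis).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    EBImage,
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
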