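Package: methylprog
Title: Differential DNA Methylation and Prognosis Across Melanoma Progression Stages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for Infinium-450K-style beta-value methylomes
    sampled across the nevus, primary-melanoma and metastasis stages of
    melanoma progression. Implements probe-level quality control with
    detection-p masking, an ANOVA pre-screen with Ward clustering, the
    difference-of-group-median-betas (DGMB) differential-methylation procedure
    with Mann-Whitney refinement and Benjamini-Hochberg adjustment, crossing of
    stage-wise hit lists into development- and progression-specific gene sets,
    CpG island/shore/shelf/open-sea and gene-feature compartment profiling
    with Fisher enrichment, integration of methylation calls with external
    differential-expression tables, a survivor methylation signature, IHC
    H-score computation, and Kaplan-Meier, log-rank and Cox evaluation of
    dichotomized prognostic biomarkers. A seeded synthetic-data generator
    plants stage-specific and prognostic probes with known ground truth so
    every stage has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
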