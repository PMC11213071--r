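Package: t21immune
Title: Immune Dysregulation Analysis for Trisomy 21 Cohort and Trial Data
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical pipeline for cohort- and trial-level analysis of
    immune dysregulation in Down syndrome (trisomy 21, T21). Implements
    autoantibody positivity calling from bead-array reactivities (per-sample
    MAD normalization with control-percentile thresholds), Fisher's-exact
    over-representation screens with Benjamini-Hochberg correction, multiplex
    immunoassay panel preprocessing and mixed-model differential abundance,
    composite interferon (IFN) and cytokine scores standardized against a
    euploid reference, beta regression of immune-cell cluster frequencies with
    a logit link, and paired nonparametric endpoint evaluation for trial time
    courses. A seeded synthetic-cohort generator emulates the statistical
    structure of all input modalities so every stage is testable without
    access to restricted participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lmerTest,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    glmmTMB,
    optparse
Config/testthat/edition: 3
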