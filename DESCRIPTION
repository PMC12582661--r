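Package: pebri
Title: Personalized Reference Intervals and Reference Change Values via
    Parametric Empirical Bayes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a parametric empirical Bayes (PEB) framework for
    personalized reference intervals (RI_per) and reference change values
    (RCV) in laboratory medicine.  Individual homeostatic set points are
    estimated by shrinking the observed individual mean toward the
    population mean, which corrects serial-result thresholds for
    regression toward the mean.  PEB parameters (population mean and SD
    plus the intraclass correlation B1) can be estimated from routine
    laboratory information system (LIS) data -- via a central-peak
    Box-Cox-normal population fit and robust regression of sequential
    result pairs -- or from a designed biological-variation study via
    nested ANOVA with a four-level outlier-exclusion cascade.  Includes
    flagging evaluation against population intervals, result-pair RCVs
    and dynamically updated personalized intervals, comparator RCV
    methods, and a synthetic-cohort generator reproducing the assumed
    two-level hierarchical model with realistic laboratory artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    nortest,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
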