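Package: hgsref
Title: LMS Reference Standards and Health Benefit Zones for Adolescent
    Handgrip Strength
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs age- and sex-specific normative reference standards
    for absolute handgrip strength in adolescents using the LMS
    (Lambda-Mu-Sigma) method with the Box-Cox Cole-Green (BCCG)
    distribution.  Provides the BCCG quantile, z-score and density
    functions, penalized-likelihood estimation of smooth age-dependent
    L, M and S curves, percentile reference tables and centile curves,
    five-tier Health Benefit Zone cut-off tables and population
    classification, back-generation cross-validation scored by a signed
    MAPE, and a seeded synthetic cohort generator that emulates a
    stratified school survey of 12-16 year olds.  Ships the published
    South Punjab reference parameters so every table can be rebuilt from
    its printed L, M and S values.
License: MIT
Encoding: UTF-8
Imports:
    splines,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
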