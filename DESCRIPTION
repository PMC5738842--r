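Package: harmonisr
Title: Retrospective Harmonisation of Multi-Study Questionnaire Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for retrospective harmonisation of questionnaire and
    covariate data pooled from multiple epidemiological studies. Provides
    per-study data dictionaries with uniform variable-group tagging, a
    declarative rule language for deriving harmonised variables at multiple
    resolutions (category collapse, threshold binning, source preference,
    inference rules, reasoned wave exclusions), an engine that applies rules
    to study-wave tables and pools the results, auditable provenance reports
    mirroring published harmonisation documentation, and a synthetic
    multi-study data generator that reproduces category marginals exactly.
    Ships a fully reproducible worked example harmonising school-travel mode
    and duration across three heterogeneous child-cohort studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringi,
    tibble,
    tidyr,
    tools,
    utils,
    stats,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
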