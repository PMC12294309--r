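Package: abit
Title: Scoring Engine for the Awake Bruxism Identification Tool
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Awake Bruxism Identification Tool (ABIT) for
    children aged 8 to 12: per-component scoring of parents' reports,
    child self-reports, the analog 7-day ecological momentary assessment
    (EMA) painting diary and the clinical examination; composition of the
    components into the composite AB Spectrum with identification categories;
    test-retest reliability statistics (Cronbach's alpha, two-way
    single-measure intraclass correlation coefficients, Lin's concordance
    correlation coefficient with confidence interval); and a seeded
    synthetic-cohort generator with known ground truth for exercising the
    whole pipeline. Includes CSV/JSON-lines cohort input and output and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
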