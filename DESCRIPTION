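Package: domiscore
Title: Multi-Criteria Scoring of Housing Impact on Occupant Health
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scoring engine for the Domiscore, a multi-criteria instrument
    that rates a dwelling's impact on occupant health and well-being from
    ordinal variables grouped in thematic categories. Each variable is
    scored 0 (most favorable) to 3 (most unfavorable); a thematic score is
    the worst score in its category (aspiration-level aggregation); the
    global score is the sum of thematic scores, with a penalty for blank
    categories and extra points for vulnerable occupants, segmented into
    four traffic-light equivalence classes. Includes versioned grid
    definitions, a vulnerability-penalty matrix, risk-alert detection, a
    reproducible synthetic-assessment generator, and territory-level
    housing-stock summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
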