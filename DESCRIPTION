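Package: epicore
Title: Core Microbiome Identification for Host-Associated Amplicon Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies core bacterial amplicon sequence variants (ASVs) on a
    host from sample-by-ASV count tables using three complementary
    definitions: a frequency (occupancy) threshold on host samples, indicator
    value (IndVal) analysis of the host against environmental samples with
    permutation tests, and a two-step per-sampling-event indicator tally.
    Includes the supporting count-table filtering, rarefaction,
    host-specificity and host-range classification, seasonal summaries,
    Bray-Curtis dissimilarity with one-factor PERMANOVA, and a synthetic
    host/environment community generator with planted core taxa for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    vegan,
    biomformat
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
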